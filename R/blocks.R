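#' Define a life-course block structure
#'
#' A block structure assigns every variable of a cohort to one of `Q`
#' chronologically ordered life-stage blocks and gives it a role
#' (`endogenous`, `exogenous` or `forced`) and a measurement type
#' (`continuous`, `binary` or `categorical`). The structure determines the
#' candidate edge set of the structural equation model: each endogenous
#' variable in block `q` is regressed on all variables of blocks
#' `1..q-1`, on the exogenous variables of its own block, and on all
#' forced covariates (e.g. sex), which enter every regression without
#' selection.
#'
#' Endogenous variables must be continuous; within a block, endogenous
#' variables are never covariates for each other, so the candidate graph is
#' acyclic by construction. Categorical variables are expanded into
#' reference-coded binary indicator columns (reference = first declared
#' level) named `<variable>.<level>`.
#'
#' @param blocks ordered list; each element a list with `name` and character
#'   vectors `endogenous` and `exogenous` (either may be empty).
#' @param variables named list; each element a list with `type` (one of
#'   `"continuous"`, `"binary"`, `"categorical"`), optional `levels`
#'   (categorical only), optional logicals `forced` and `no_impute`.
#' @return an object of class `blsem_blocks`.
#' @examples
#' bs <- block_structure(
#'   blocks = list(
#'     list(name = "b1", endogenous = character(), exogenous = c("x")),
#'     list(name = "b2", endogenous = c("y"), exogenous = character())
#'   ),
#'   variables = list(
#'     x = list(type = "continuous"),
#'     y = list(type = "continuous")
#'   )
#' )
#' candidate_edges(bs)
#' @export
block_structure <- function(blocks, variables) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("`blocks` must be a non-empty ordered list", call. = FALSE)
  blocks <- lapply(seq_along(blocks), function(q) {
    b <- blocks[[q]]
    if (is.null(b$name)) b$name <- paste0("block", q)
    b$endogenous <- as.character(b$endogenous %||% character())
    b$exogenous <- as.character(b$exogenous %||% character())
    b[c("name", "endogenous", "exogenous")]
  })

  declared <- unlist(lapply(blocks, function(b) c(b$endogenous, b$exogenous)))
  if (anyDuplicated(declared)) {
    stop("duplicate variable name(s) in block lists: ",
         paste(unique(declared[duplicated(declared)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(variables) || is.null(names(variables)))
    stop("`variables` must be a named list of variable specifications",
         call. = FALSE)
  missing_spec <- setdiff(declared, names(variables))
  if (length(missing_spec))
    stop("no type specification for variable(s): ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  orphan <- setdiff(names(variables), declared)
  if (length(orphan))
    stop("variable(s) not assigned to any block: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  vars <- list()
  for (q in seq_along(blocks)) {
    b <- blocks[[q]]
    for (nm in c(b$endogenous, b$exogenous)) {
      spec <- variables[[nm]]
      type <- spec$type %||% "continuous"
      if (!type %in% c("continuous", "binary", "categorical"))
        stop("variable `", nm, "`: unknown type `", type, "`", call. = FALSE)
      forced <- isTRUE(spec$forced)
      endo <- nm %in% b$endogenous
      if (endo && type != "continuous")
        stop("variable `", nm, "` is endogenous but declared ", type,
             "; the model only supports continuous outcomes", call. = FALSE)
      if (endo && forced)
        stop("variable `", nm, "` cannot be both endogenous and forced",
             call. = FALSE)
      if (forced && q != 1L)
        stop("forced covariate `", nm, "` must belong to the first block",
             call. = FALSE)
      levels <- NULL
      if (type == "categorical") {
        levels <- as.character(spec$levels %||% character())
        if (length(levels) < 2L)
          stop("categorical variable `", nm,
               "` needs at least two declared levels", call. = FALSE)
        if (anyDuplicated(levels))
          stop("categorical variable `", nm, "` has duplicated levels",
               call. = FALSE)
      }
      vars[[nm]] <- list(
        name = nm, block = q,
        role = if (endo) "endogenous" else if (forced) "forced" else "exogenous",
        type = type, levels = levels,
        no_impute = isTRUE(spec$no_impute)
      )
    }
  }

  bs <- structure(
    list(blocks = blocks, variables = vars, Q = length(blocks),
         schema_version = 1L),
    class = "blsem_blocks"
  )
  bs$columns <- .model_columns(bs)
  bs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Modelling columns after categorical expansion, in deterministic order:
# per block, endogenous first then exogenous, both in declared order;
# categorical levels expanded in declared order (reference level dropped).
.model_columns <- function(bs) {
  rows <- list()
  for (q in seq_along(bs$blocks)) {
    b <- bs$blocks[[q]]
    for (nm in c(b$endogenous, b$exogenous)) {
      v <- bs$variables[[nm]]
      if (v$type == "categorical") {
        for (lev in v$levels[-1L]) {
          rows[[length(rows) + 1L]] <- data.frame(
            column = paste0(nm, ".", lev), source = nm, block = q,
            role = v$role, type = "binary", level = lev,
            forced = v$role == "forced", no_impute = v$no_impute,
            stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          column = nm, source = nm, block = q, role = v$role,
          type = v$type, level = NA_character_,
          forced = v$role == "forced", no_impute = v$no_impute,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.blsem_blocks <- function(x, ...) {
  cat("Life-course block structure:", x$Q, "blocks,",
      length(x$variables), "variables (",
      nrow(x$columns), "model columns )\n")
  for (q in seq_along(x$blocks)) {
    b <- x$blocks[[q]]
    cat(sprintf("  [%d] %s: %d endogenous, %d exogenous\n",
                q, b$name, length(b$endogenous), length(b$exogenous)))
  }
  nf <- sum(x$columns$forced)
  if (nf) cat("  forced covariate columns:",
              paste(x$columns$column[x$columns$forced], collapse = ", "), "\n")
  invisible(x)
}

#' Load a block-structure configuration file
#'
#' Reads a YAML or JSON configuration describing the life-stage blocks and
#' variable roles/types, validates it and returns a [block_structure()].
#' The format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' The schema (version 1) has three top-level keys: `schema_version`,
#' `blocks` (ordered list of `{name, endogenous: [...], exogenous: [...]}`)
#' and `variables` (map of `name -> {type, levels?, forced?, no_impute?}`).
#'
#' @param path path to a YAML or JSON configuration file.
#' @return a `blsem_blocks` object.
#' @seealso [write_block_config()] for the inverse operation. A commented
#'   example lives at
#'   `system.file("extdata", "example_blocks.yaml", package = "blsem")`.
#' @export
load_block_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$blocks))
    stop("configuration error: missing required field `blocks`", call. = FALSE)
  if (is.null(cfg$variables))
    stop("configuration error: missing required field `variables`",
         call. = FALSE)
  sv <- cfg$schema_version %||% 1L
  if (!identical(as.integer(sv), 1L))
    stop("configuration error: unsupported schema_version `", sv, "`",
         call. = FALSE)
  block_structure(cfg$blocks, cfg$variables)
}

#' Serialise a block structure back to a configuration file
#'
#' @param bs a `blsem_blocks` object.
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_block_config <- function(bs, path) {
  stopifnot(inherits(bs, "blsem_blocks"))
  vars <- lapply(bs$variables, function(v) {
    out <- list(type = v$type)
    if (!is.null(v$levels)) out$levels <- v$levels
    if (v$role == "forced") out$forced <- TRUE
    if (v$no_impute) out$no_impute <- TRUE
    out
  })
  cfg <- list(schema_version = 1L, blocks = bs$blocks, variables = vars)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Candidate edge set implied by the chronological block ordering
#'
#' For each endogenous response in block `q` the candidate covariates are,
#' in deterministic order: all forced covariates, then for each earlier
#' block its endogenous then exogenous columns in declared order, then the
#' exogenous (non-forced) columns of block `q` itself. Endogenous variables
#' never predict other endogenous variables of the same block and edges
#' never point backwards in time, so the candidate graph is a DAG.
#'
#' @param bs a `blsem_blocks` object.
#' @return an object of class `blsem_candidates`: a list with one element
#'   per endogenous response holding `response`, `block`, `candidates`
#'   (ordered character vector of model columns) and `forced` (logical
#'   mask over `candidates`).
#' @export
candidate_edges <- function(bs) {
  stopifnot(inherits(bs, "blsem_blocks"))
  cols <- bs$columns
  forced_cols <- cols$column[cols$forced]
  out <- list()
  for (q in seq_len(bs$Q)) {
    resp <- cols$column[cols$block == q & cols$role == "endogenous"]
    if (!length(resp)) next
    prior <- cols$column[cols$block < q & !cols$forced]
    own_exo <- cols$column[cols$block == q & cols$role == "exogenous"]
    cand <- c(forced_cols, prior, own_exo)
    for (k in resp) {
      out[[k]] <- list(
        response = k, block = q, candidates = cand,
        forced = cand %in% forced_cols
      )
    }
  }
  structure(out, class = "blsem_candidates")
}

#' @export
print.blsem_candidates <- function(x, ...) {
  cat("Candidate edge set:", length(x), "responses,",
      sum(vapply(x, function(e) length(e$candidates), 1L)),
      "candidate edges\n")
  for (e in x)
    cat(sprintf("  %s (block %d): %d candidates\n",
                e$response, e$block, length(e$candidates)))
  invisible(x)
}

# igraph check that the candidate graph admits a topological order
.assert_acyclic <- function(bs) {
  ce <- candidate_edges(bs)
  edges <- unlist(lapply(ce, function(e) rbind(e$candidates, e$response)))
  if (is.null(edges)) return(invisible(TRUE))
  g <- igraph::make_graph(edges, directed = TRUE)
  if (!igraph::is_dag(g))
    stop("candidate graph is cyclic; invalid block structure", call. = FALSE)
  invisible(TRUE)
}

#' Validate a cohort data table against a block structure
#'
#' Checks that every declared variable is present, that continuous columns
#' are numeric, and reports per-variable missingness, type violations
#' (binary values outside \{0, 1\}, categorical values outside the declared
#' levels) and constant observed columns. Wholly missing columns are a hard
#' error, as is a non-numeric continuous column (reported with the first
#' offending row).
#'
#' @param bs a `blsem_blocks` object.
#' @param table a data frame with one row per subject; missing cells `NA`.
#' @return an object of class `blsem_validation`: list with `missing_frac`
#'   (named numeric), `issues` (data frame with columns `variable`, `issue`,
#'   `detail`) and `ok` (TRUE when `issues` is empty).
#' @export
validate_data <- function(bs, table) {
  stopifnot(inherits(bs, "blsem_blocks"), is.data.frame(table))
  vars <- names(bs$variables)
  absent <- setdiff(vars, names(table))
  if (length(absent))
    stop("data table lacks declared column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  issues <- list()
  add_issue <- function(variable, issue, detail = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      variable = variable, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  missing_frac <- setNames(numeric(length(vars)), vars)

  for (nm in vars) {
    v <- bs$variables[[nm]]
    col <- table[[nm]]
    miss <- is.na(col)
    missing_frac[nm] <- mean(miss)
    if (all(miss))
      stop("column `", nm, "` is wholly missing", call. = FALSE)
    obs <- col[!miss]
    if (v$type == "continuous") {
      if (!is.numeric(col)) {
        bad <- which(!miss & is.na(suppressWarnings(as.numeric(col))))
        row <- if (length(bad)) bad[1L] else which(!miss)[1L]
        stop("continuous column `", nm, "` contains a non-numeric value ",
             "(first at row ", row, ")", call. = FALSE)
      }
      if (length(unique(obs)) == 1L)
        add_issue(nm, "constant", "observed values are all identical")
    } else if (v$type == "binary") {
      if (!all(obs %in% c(0, 1)))
        add_issue(nm, "type_violation",
                  paste0("binary column contains value(s) ",
                         paste(unique(obs[!obs %in% c(0, 1)]), collapse = ", ")))
      else if (length(unique(obs)) == 1L)
        add_issue(nm, "constant", "observed values are all identical")
    } else {
      bad <- setdiff(unique(as.character(obs)), v$levels)
      if (length(bad))
        add_issue(nm, "type_violation",
                  paste0("categorical value(s) outside declared levels: ",
                         paste(bad, collapse = ", ")))
    }
    if (missing_frac[nm] > 0)
      add_issue(nm, "missing", sprintf("%.4f of cells missing", missing_frac[nm]))
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(variable = character(), issue = character(),
               detail = character(), stringsAsFactors = FALSE)
  hard <- issues$issue %in% "type_violation"
  structure(
    list(missing_frac = missing_frac, issues = issues,
         ok = !any(hard)),
    class = "blsem_validation")
}

#' @export
print.blsem_validation <- function(x, ...) {
  cat("Data validation:", if (x$ok) "no type violations" else "PROBLEMS FOUND", "\n")
  miss <- x$missing_frac[x$missing_frac > 0]
  if (length(miss)) {
    cat("Missingness:\n")
    for (nm in names(miss)) cat(sprintf("  %s: %.1f%%\n", nm, 100 * miss[nm]))
  }
  viol <- x$issues[x$issues$issue != "missing", , drop = FALSE]
  if (nrow(viol)) {
    cat("Issues:\n")
    for (i in seq_len(nrow(viol)))
      cat(sprintf("  %s [%s]: %s\n", viol$variable[i], viol$issue[i],
                  viol$detail[i]))
  }
  invisible(x)
}

#' Expand categorical columns into reference-coded indicators
#'
#' Replaces each declared categorical column by binary indicator columns
#' `<variable>.<level>` for every non-reference level (reference = first
#' declared level), and coerces binary columns to numeric 0/1. The result
#' has exactly the model columns of `bs$columns`, in that order.
#'
#' @param bs a `blsem_blocks` object.
#' @param table validated data frame.
#' @return data frame of model columns.
#' @export
expand_categoricals <- function(bs, table) {
  stopifnot(inherits(bs, "blsem_blocks"))
  out <- list()
  for (i in seq_len(nrow(bs$columns))) {
    ci <- bs$columns[i, ]
    src <- table[[ci$source]]
    if (!is.na(ci$level)) {
      x <- as.numeric(as.character(src) == ci$level)
      x[is.na(src)] <- NA_real_
    } else if (ci$type == "binary") {
      x <- as.numeric(src)
    } else {
      x <- as.numeric(src)
    }
    out[[ci$column]] <- x
  }
  as.data.frame(out, optional = TRUE)
}

# Drop rows with a missing value in any `no_impute` column; returns the
# reduced model table and the number of dropped rows.
.drop_no_impute <- function(bs, mtab) {
  cols <- bs$columns$column[bs$columns$no_impute]
  if (!length(cols)) return(list(table = mtab, dropped = 0L))
  bad <- Reduce(`|`, lapply(cols, function(cn) is.na(mtab[[cn]])))
  list(table = mtab[!bad, , drop = FALSE], dropped = sum(bad))
}
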