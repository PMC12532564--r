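#' Threshold the MPPI matrix into an estimated DAG
#'
#' Includes a directed edge `j -> k` whenever the marginal posterior
#' probability of inclusion of covariate `j` in the regression of `k` is
#' at least `tau` (default 0.5; more conservative thresholds such as 0.8
#' or 0.9 can be requested). Forced covariates are adjustment variables,
#' not discovered structure, and are excluded. The result is acyclic by
#' construction since every candidate edge respects the chronological
#' block ordering.
#'
#' @param mppi a `blsem_mppi` data frame from [compute_mppi()], or a
#'   `blsem_chain` (the MPPI matrix is then computed internally).
#' @param tau inclusion threshold in (0, 1].
#' @param chain optional `blsem_chain`; recorded as the DAG's provenance
#'   (required for [effect_decomposition()]).
#' @return an object of class `blsem_dag`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `mppi`, `beta_mean`), `tau` and `run_seed`.
#' @export
threshold_dag <- function(mppi, tau = 0.5, chain = NULL) {
  if (inherits(mppi, "blsem_chain")) {
    chain <- mppi
    mppi <- compute_mppi(chain)
  }
  stopifnot(inherits(mppi, "data.frame"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("`tau` must be a probability in (0, 1]", call. = FALSE)
  keep <- !mppi$forced & mppi$mppi >= tau
  edges <- data.frame(
    from = mppi$candidate[keep], to = mppi$response[keep],
    mppi = mppi$mppi[keep], beta_mean = mppi$beta_mean[keep],
    stringsAsFactors = FALSE, row.names = NULL)
  nodes <- unique(c(mppi$candidate[!mppi$forced], mppi$response))
  structure(list(nodes = nodes, edges = edges, tau = tau,
                 run_seed = if (!is.null(chain)) chain$config$seed),
            class = "blsem_dag")
}

#' @export
print.blsem_dag <- function(x, ...) {
  cat("Estimated DAG (MPPI >=", x$tau, "):", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Enumerate all MPPI-qualified directed paths between two variables
#'
#' Every simple directed path from `exposure` to `outcome` in the
#' thresholded DAG, in deterministic lexicographic order of the node
#' sequences. A path of length 1 is the direct edge.
#'
#' @param dag a `blsem_dag`.
#' @param exposure,outcome node names.
#' @return list of character vectors (node sequences, inclusive).
#' @export
enumerate_paths <- function(dag, exposure, outcome) {
  stopifnot(inherits(dag, "blsem_dag"))
  for (nd in c(exposure, outcome))
    if (!nd %in% dag$nodes)
      stop("unknown node `", nd, "`", call. = FALSE)
  if (identical(exposure, outcome))
    stop("exposure and outcome must differ", call. = FALSE)
  succ <- split(dag$edges$to, dag$edges$from)
  succ <- lapply(succ, function(s) sort(unique(s)))
  paths <- list()
  walk <- function(node, trail) {
    if (identical(node, outcome)) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    for (nxt in succ[[node]])
      if (!nxt %in% trail) walk(nxt, c(trail, nxt))
  }
  walk(exposure, exposure)
  paths
}

# Model-averaged coefficient draws for edge from -> to; zero draws where
# the indicator is off.
.edge_draws <- function(chain, from, to) {
  e <- chain$candidates[[to]]
  if (is.null(e))
    stop("`", to, "` is not an endogenous response", call. = FALSE)
  pos <- match(from, e$candidates)
  if (is.na(pos))
    stop("`", from, "` is not a candidate covariate for `", to, "`",
         call. = FALSE)
  chain$beta[[to]][, pos]
}

.summ_draws <- function(x) {
  q <- unname(quantile(x, c(0.025, 0.5, 0.975), type = 7))
  c(mean = mean(x), median = q[2], lower = q[1], upper = q[3])
}

#' Posterior decomposition of direct, indirect and total effects
#'
#' For each stored posterior draw the direct effect is the model-averaged
#' coefficient of the exposure in the outcome's regression (zero in draws
#' where the indicator is off); each indirect path effect is the product
#' of that draw's coefficients along the edges of an MPPI-qualified path;
#' the total indirect effect is the sum over qualifying paths of length
#' at least 2; and the total effect is direct plus total indirect. Each
#' quantity is summarised by its posterior mean, median and equal-tailed
#' 95% credible interval, in SD units of the outcome.
#'
#' Identification of these as causal mediation effects relies on the
#' standard assumptions: correct chronological ordering, linearity, no
#' exposure-mediator interaction and no unmeasured confounding.
#'
#' @param chain the fitted `blsem_chain`.
#' @param dag a `blsem_dag` built from the same run.
#' @param exposure,outcome variable (model column) names.
#' @param conditional if `TRUE`, restrict to draws in which every edge on
#'   every qualifying path has its indicator on, instead of using
#'   model-averaged draws.
#' @return an object of class `blsem_effect`: list with `exposure`,
#'   `outcome`, `n_paths`, `paths`, summaries `direct`, `indirect`,
#'   `total` (named vectors: mean, median, lower, upper), `per_path`
#'   (data frame), and the per-draw vectors in `draws`.
#' @export
effect_decomposition <- function(chain, dag, exposure, outcome,
                                 conditional = FALSE) {
  stopifnot(inherits(chain, "blsem_chain"), inherits(dag, "blsem_dag"))
  if (!is.null(dag$run_seed) &&
      !identical(dag$run_seed, chain$config$seed))
    stop("DAG and chain come from different runs", call. = FALSE)
  paths <- enumerate_paths(dag, exposure, outcome)
  nd <- chain$config$n_draws

  direct <- tryCatch(.edge_draws(chain, exposure, outcome),
                     error = function(e) rep(0, nd))
  keep <- rep(TRUE, nd)
  path_eff <- list()
  for (pth in paths) {
    eff <- rep(1, nd)
    for (i in seq_len(length(pth) - 1L)) {
      eff <- eff * .edge_draws(chain, pth[i], pth[i + 1L])
      if (conditional) {
        e <- chain$candidates[[pth[i + 1L]]]
        pos <- match(pth[i], e$candidates)
        keep <- keep & chain$gamma[[pth[i + 1L]]][, pos] == 1L
      }
    }
    path_eff[[paste(pth, collapse = " -> ")]] <- eff
  }
  if (conditional) {
    if (!any(keep))
      stop("no draws with all path edges included; cannot condition",
           call. = FALSE)
    direct <- direct[keep]
    path_eff <- lapply(path_eff, function(x) x[keep])
  }
  indirect_paths <- path_eff[vapply(paths, length, 1L) > 2L]
  indirect <- if (length(indirect_paths))
    Reduce(`+`, indirect_paths) else rep(0, length(direct))
  total <- direct + indirect

  per_path <- if (length(path_eff)) {
    do.call(rbind, lapply(names(path_eff), function(nm) {
      s <- .summ_draws(path_eff[[nm]])
      data.frame(path = nm, length = length(strsplit(nm, " -> ")[[1]]) - 1L,
                 mean = s["mean"], median = s["median"],
                 lower = s["lower"], upper = s["upper"],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  } else {
    data.frame(path = character(), length = integer(), mean = numeric(),
               median = numeric(), lower = numeric(), upper = numeric())
  }

  structure(list(
    exposure = exposure, outcome = outcome,
    n_paths = length(paths), paths = paths,
    direct = .summ_draws(direct), indirect = .summ_draws(indirect),
    total = .summ_draws(total), per_path = per_path,
    draws = list(direct = direct, indirect = indirect, total = total),
    units = "sd", conditional = conditional
  ), class = "blsem_effect")
}

#' @export
print.blsem_effect <- function(x, digits = 3, ...) {
  cat("Effect decomposition:", x$exposure, "->", x$outcome,
      sprintf("(%s units)\n", x$units))
  cat("  [assumes no unmeasured confounding and no",
      "exposure-mediator interaction]\n")
  fmt <- function(s) sprintf("%s (%s, %s)",
                             signif(s["mean"], digits),
                             signif(s["lower"], digits),
                             signif(s["upper"], digits))
  cat("  direct:        ", fmt(x$direct), "\n")
  cat("  total indirect:", fmt(x$indirect), "\n")
  cat("  total:         ", fmt(x$total), "\n")
  cat("  paths:         ", x$n_paths, "\n")
  invisible(x)
}

#' Convert an effect estimate to the original measurement scales
#'
#' SD-unit effects are mapped back to the variables' original scales. For
#' a continuous exposure both conversions are reported: per original unit
#' of the exposure (multiply by `SD(outcome)/SD(exposure)`) and per 1-SD
#' change (multiply by `SD(outcome)`). For a binary exposure the effect is
#' per 0-to-1 change, so only the `SD(outcome)` conversion applies.
#'
#' @param effect a `blsem_effect`.
#' @param scale a `blsem_scale` data frame covering exposure and outcome.
#' @return the effect object with an added `original_scale` element
#'   holding `per_unit` and `per_sd` summaries for direct, indirect and
#'   total effects.
#' @export
destandardize <- function(effect, scale) {
  stopifnot(inherits(effect, "blsem_effect"))
  si <- function(v) {
    i <- match(v, scale$column)
    if (is.na(i)) stop("no scale information for `", v, "`", call. = FALSE)
    i
  }
  io <- si(effect$outcome); ie <- si(effect$exposure)
  sd_out <- if (scale$scaled[io]) scale$scale[io] else 1
  exp_cont <- scale$scaled[ie]
  sd_exp <- if (exp_cont) scale$scale[ie] else 1
  conv <- function(s, f) {
    out <- s * f
    names(out) <- names(s)
    out
  }
  per_sd <- lapply(effect[c("direct", "indirect", "total")], conv,
                   f = sd_out)
  per_unit <- if (exp_cont)
    lapply(effect[c("direct", "indirect", "total")], conv,
           f = sd_out / sd_exp)
  else per_sd
  effect$original_scale <- list(
    per_sd = per_sd, per_unit = per_unit,
    exposure_continuous = exp_cont,
    sd_outcome = sd_out, sd_exposure = sd_exp)
  effect
}

#' Subgraph of all qualifying paths between an exposure and an outcome
#'
#' The union of nodes and edges lying on at least one MPPI-qualified
#' directed path from `exposure` to `outcome` (the per-exposure pathway
#' diagram).
#'
#' @inheritParams enumerate_paths
#' @return a `blsem_dag` restricted to the pathway union.
#' @export
subgraph <- function(dag, exposure, outcome) {
  stopifnot(inherits(dag, "blsem_dag"))
  paths <- enumerate_paths(dag, exposure, outcome)
  nodes <- unique(unlist(paths))
  ekeys <- unique(unlist(lapply(paths, function(p) {
    if (length(p) < 2L) return(NULL)
    paste(p[-length(p)], p[-1L], sep = "\r")
  })))
  edges <- dag$edges
  keep <- paste(edges$from, edges$to, sep = "\r") %in% ekeys
  structure(list(nodes = if (is.null(nodes)) character() else sort(nodes),
                 edges = edges[keep, , drop = FALSE],
                 tau = dag$tau, run_seed = dag$run_seed),
            class = "blsem_dag")
}

#' Export an estimated DAG to DOT or GraphML
#'
#' Edge attributes carry the MPPI and the posterior-mean standardised
#' coefficient scaled by 1000.
#'
#' @param dag a `blsem_dag`.
#' @param path output file; format chosen by `format`.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_dag <- function(dag, path, format = c("dot", "graphml")) {
  stopifnot(inherits(dag, "blsem_dag"))
  format <- match.arg(format)
  if (format == "dot") {
    lines <- c("digraph blsem {", "  rankdir=LR;")
    for (nd in dag$nodes)
      lines <- c(lines, sprintf("  \"%s\";", nd))
    for (i in seq_len(nrow(dag$edges))) {
      e <- dag$edges[i, ]
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%.3g\", mppi=%.3f, beta1000=%.3g];",
        e$from, e$to, e$beta_mean * 1000, e$mppi, e$beta_mean * 1000))
    }
    writeLines(c(lines, "}"), path)
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(dag$nodes), name = dag$nodes)
    if (nrow(dag$edges)) {
      g <- igraph::add_edges(
        g, as.vector(rbind(match(dag$edges$from, dag$nodes),
                           match(dag$edges$to, dag$nodes))),
        mppi = dag$edges$mppi, beta1000 = dag$edges$beta_mean * 1000)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Tabulate effect decompositions for many exposures
#'
#' Builds a results table (one row per exposure) with direct, total
#' indirect and total effects and their 95% credible intervals in SD
#' units of the outcome, optionally scaled by 1000, plus the qualifying
#' path count.
#'
#' @param chain a `blsem_chain`.
#' @param dag a `blsem_dag` from the same run.
#' @param outcome outcome variable name.
#' @param exposures character vector; default: every model column with at
#'   least one qualifying path to the outcome.
#' @param scale_by multiply reported effects by this factor (e.g. 1000).
#' @return data frame of class `blsem_effects_table`; attribute
#'   `"per_path"` holds the long-format per-path breakdown.
#' @export
effects_table <- function(chain, dag, outcome, exposures = NULL,
                          scale_by = 1) {
  stopifnot(inherits(chain, "blsem_chain"))
  if (is.null(exposures)) {
    cand <- setdiff(dag$nodes, outcome)
    exposures <- cand[vapply(cand, function(v)
      length(enumerate_paths(dag, v, outcome)) > 0L, TRUE)]
  }
  rows <- list(); longs <- list()
  for (ex in exposures) {
    eff <- effect_decomposition(chain, dag, ex, outcome)
    f <- function(s) s * scale_by
    has_ind <- any(vapply(eff$paths, length, 1L) > 2L)
    rows[[ex]] <- data.frame(
      exposure = ex,
      direct = f(eff$direct[["mean"]]),
      direct_lower = f(eff$direct[["lower"]]),
      direct_upper = f(eff$direct[["upper"]]),
      indirect = if (has_ind) f(eff$indirect[["mean"]]) else NA_real_,
      indirect_lower = if (has_ind) f(eff$indirect[["lower"]]) else NA_real_,
      indirect_upper = if (has_ind) f(eff$indirect[["upper"]]) else NA_real_,
      total = f(eff$total[["mean"]]),
      total_lower = f(eff$total[["lower"]]),
      total_upper = f(eff$total[["upper"]]),
      n_paths = eff$n_paths,
      stringsAsFactors = FALSE, row.names = NULL)
    if (nrow(eff$per_path)) {
      pp <- eff$per_path
      pp$exposure <- ex
      pp[c("mean", "median", "lower", "upper")] <-
        pp[c("mean", "median", "lower", "upper")] * scale_by
      longs[[ex]] <- pp
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_path") <- if (length(longs)) do.call(rbind, longs)
  attr(out, "scale_by") <- scale_by
  class(out) <- c("blsem_effects_table", "data.frame")
  out
}
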