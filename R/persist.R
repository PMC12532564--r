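#' Persist a fitted chain to a run directory
#'
#' Writes a documented, version-stamped on-disk layout: `meta.json`
#' (run configuration, scaling metadata, missing-cell index),
#' `blocks.json` (the block structure), and one CSV per parameter group
#' (`alpha`, `sigma2`, `pi`, `r2`, per-response `beta_*`/`gamma_*`,
#' `imputed`, and the observed model table).
#'
#' @param chain a `blsem_chain`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "blsem_chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    layout_version = 1L,
    config = chain$config,
    n = chain$n, n_dropped = chain$n_dropped,
    ridge_count = chain$ridge_count,
    responses = names(chain$candidates),
    candidates = lapply(chain$candidates, function(e)
      list(block = e$block, candidates = e$candidates,
           forced = e$forced)),
    scale = chain$scale,
    missing_cells = chain$missing_cells)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_block_config(chain$bs, file.path(dir, "blocks.json"))
  wc <- function(x, f) write.csv(as.data.frame(x), file.path(dir, f),
                                 row.names = FALSE)
  wc(chain$alpha, "alpha.csv"); wc(chain$sigma2, "sigma2.csv")
  wc(chain$pi, "pi.csv"); wc(chain$r2, "r2.csv")
  for (k in names(chain$candidates)) {
    if (!length(chain$candidates[[k]]$candidates)) next
    wc(chain$beta[[k]], paste0("beta_", k, ".csv"))
    wc(chain$gamma[[k]], paste0("gamma_", k, ".csv"))
  }
  if (!is.null(chain$imputed)) wc(chain$imputed, "imputed.csv")
  wc(chain$observed, "observed.csv")
  invisible(dir)
}

#' Reload a chain persisted by [save_chain()]
#'
#' @param dir run directory.
#' @return a `blsem_chain`.
#' @export
load_chain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.integer(meta$layout_version), 1L))
    stop("unsupported chain layout version", call. = FALSE)
  bs <- load_block_config(file.path(dir, "blocks.json"))
  rc <- function(f) {
    df <- read.csv(file.path(dir, f), check.names = FALSE)
    as.matrix(df)
  }
  responses <- meta$responses
  candidates <- lapply(responses, function(k) {
    e <- meta$candidates[[k]]
    list(response = k, block = e$block,
         candidates = as.character(e$candidates),
         forced = as.logical(e$forced))
  })
  names(candidates) <- responses
  class(candidates) <- "blsem_candidates"
  beta <- list(); gamma <- list()
  for (k in responses) {
    if (length(candidates[[k]]$candidates)) {
      beta[[k]] <- rc(paste0("beta_", k, ".csv"))
      gamma[[k]] <- rc(paste0("gamma_", k, ".csv"))
      storage.mode(gamma[[k]]) <- "integer"
    } else {
      beta[[k]] <- matrix(0, meta$config$n_draws, 0)
      gamma[[k]] <- matrix(0L, meta$config$n_draws, 0)
    }
  }
  scale <- as.data.frame(meta$scale)
  class(scale) <- c("blsem_scale", "data.frame")
  mc <- meta$missing_cells
  has_imp <- !is.null(mc) && length(mc) && nrow(as.data.frame(mc)) > 0
  structure(list(
    bs = bs, scale = scale, candidates = candidates,
    beta = beta, gamma = gamma, alpha = rc("alpha.csv"),
    sigma2 = rc("sigma2.csv"), pi = rc("pi.csv"), r2 = rc("r2.csv"),
    imputed = if (has_imp) rc("imputed.csv"),
    missing_cells = if (has_imp) as.data.frame(mc),
    observed = read.csv(file.path(dir, "observed.csv"),
                        check.names = FALSE),
    n = meta$n, n_dropped = meta$n_dropped,
    ridge_count = meta$ridge_count,
    config = meta$config
  ), class = "blsem_chain")
}
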