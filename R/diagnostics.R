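# Effective sample size by Geyer's initial positive sequence estimator.
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || var(x) == 0) return(as.numeric(n))
  ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # pair consecutive autocorrelations (Geyer): stop at first negative pair
  s <- 0
  t <- 2L
  while (t < length(ac)) {
    pair <- ac[t] + ac[t + 1L]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- n / (1 + 2 * s)
  min(max(ess, 1), n)
}

# Split-chain potential scale reduction factor on a single chain.
.split_rhat <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  a <- x[seq_len(half)]
  b <- x[seq.int(n - half + 1L, n)]
  m <- 2; len <- half
  mns <- c(mean(a), mean(b))
  vrs <- c(var(a), var(b))
  W <- mean(vrs)
  B <- len * var(mns)
  if (W == 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Bayesian R-squared for one endogenous response
#'
#' Per stored draw `d`, `R2(d) = V_fit(d) / (V_fit(d) + sigma2_k(d))`,
#' where `V_fit(d)` is the sample variance over subjects of the fitted
#' values of response `k` computed on the completed (observed + currently
#' imputed) standardised data at that draw. Draws lie in `[0, 1)` and are
#' summarised by the posterior mean, median and equal-tailed 95% credible
#' interval.
#'
#' @param chain a `blsem_chain`.
#' @param response response name or index.
#' @return list with `draws` and `summary` (mean, median, lower, upper).
#' @export
bayes_r2 <- function(chain, response) {
  stopifnot(inherits(chain, "blsem_chain"))
  if (chain$config$n_draws < 1L) stop("empty chain", call. = FALSE)
  if (is.numeric(response)) response <- colnames(chain$r2)[response]
  if (!response %in% colnames(chain$r2))
    stop("unknown response `", response, "`", call. = FALSE)
  draws <- chain$r2[, response]
  list(draws = draws, summary = .summ_draws(draws))
}

#' Posterior and convergence summary of a fitted chain
#'
#' Tabulates, for every regression coefficient (model-averaged draws),
#' intercept, residual variance and per-response Bayesian R-squared:
#' posterior mean, median, equal-tailed 95% credible interval, effective
#' sample size and a split-chain potential-scale-reduction statistic
#' (values above 1.1 are flagged). Inclusion indicators are monitored
#' through MPPI stability: the absolute difference between the first- and
#' second-half MPPI of each candidate edge (flagged above 0.05).
#'
#' @param chain a `blsem_chain`.
#' @return an object of class `blsem_summary`: list with `parameters`
#'   (data frame), `r2` (data frame), `mppi_stability` (data frame) and
#'   `flags` (character vector of flagged parameter names).
#' @export
summarize_chain <- function(chain) {
  stopifnot(inherits(chain, "blsem_chain"))
  nd <- chain$config$n_draws
  if (nd < 1L) stop("empty chain", call. = FALSE)

  rows <- list()
  add <- function(name, response, kind, x) {
    s <- .summ_draws(x)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, response = response, kind = kind,
      mean = s[["mean"]], median = s[["median"]],
      lower = s[["lower"]], upper = s[["upper"]], sd = sd(x),
      ess = .ess(x), rhat = .split_rhat(x),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  for (k in names(chain$candidates)) {
    e <- chain$candidates[[k]]
    for (j in seq_along(e$candidates))
      add(paste0("beta[", e$candidates[j], "->", k, "]"), k, "beta",
          chain$beta[[k]][, j])
    add(paste0("alpha[", k, "]"), k, "alpha", chain$alpha[, k])
    add(paste0("sigma2[", k, "]"), k, "sigma2", chain$sigma2[, k])
    add(paste0("r2[", k, "]"), k, "r2", chain$r2[, k])
  }
  pars <- do.call(rbind, rows)

  r2 <- do.call(rbind, lapply(colnames(chain$r2), function(k) {
    s <- .summ_draws(chain$r2[, k])
    data.frame(response = k, mean = s[["mean"]], median = s[["median"]],
               lower = s[["lower"]], upper = s[["upper"]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  half <- nd %/% 2L
  stab <- do.call(rbind, lapply(names(chain$candidates), function(k) {
    e <- chain$candidates[[k]]
    if (!length(e$candidates)) return(NULL)
    g <- chain$gamma[[k]]
    d <- abs(colMeans(g[seq_len(half), , drop = FALSE]) -
               colMeans(g[seq.int(nd - half + 1L, nd), , drop = FALSE]))
    data.frame(response = k, candidate = e$candidates,
               mppi_half_diff = unname(d), flagged = unname(d) > 0.05,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  flags <- c(pars$parameter[!is.na(pars$rhat) & pars$rhat > 1.1],
             if (!is.null(stab))
               paste0("mppi[", stab$candidate[stab$flagged], "->",
                      stab$response[stab$flagged], "]"))
  structure(list(parameters = pars, r2 = r2, mppi_stability = stab,
                 flags = flags),
            class = "blsem_summary")
}

#' @export
print.blsem_summary <- function(x, ...) {
  cat("Chain summary:", nrow(x$parameters), "parameters\n")
  cat("Bayesian R-squared by response:\n")
  for (i in seq_len(nrow(x$r2)))
    cat(sprintf("  %s: %.3f (%.3f, %.3f)\n", x$r2$response[i],
                x$r2$mean[i], x$r2$lower[i], x$r2$upper[i]))
  if (length(x$flags))
    cat("Flagged (convergence):", length(x$flags), "parameter(s)\n")
  else cat("No convergence flags\n")
  invisible(x)
}
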