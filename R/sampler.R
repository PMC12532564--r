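.default_priors <- function(priors = list()) {
  modifyList(list(tau2 = 10, a0 = 0.01, b0 = 0.01, pi_a = 1, pi_b = 1,
                  k0 = 0.01, nu0_extra = 2), priors)
}

#' Initialise the Gibbs sampler state
#'
#' Builds the mutable state of the blockwise sampler: the standardised,
#' initially completed data matrix, per-response coefficient/indicator
#' vectors, residual variances, prior inclusion probabilities, and the
#' latent normal/probit model over the exogenous columns used for
#' imputation. Initialisation: all selectable indicators 0 (forced
#' covariates 1), coefficients 0, residual variance = sample variance of
#' the response, missing continuous cells at the observed-column mean
#' (0 on the standardised scale) and missing binary cells at the observed
#' modal category.
#'
#' @param table raw data frame (one row per subject, `NA` missing).
#' @param bs a `blsem_blocks` object.
#' @param priors named list overriding any of `tau2`, `a0`, `b0`, `pi_a`,
#'   `pi_b` (see Details of [run_chain()]).
#' @param select logical; `FALSE` fixes every inclusion indicator at 1
#'   (no selection), e.g. for conjugate-posterior checks.
#' @param scan `"systematic"` (candidate order) or `"random"` scan order
#'   for the indicator sweep.
#' @param predictive_only logical; impute missing endogenous cells from
#'   their own regression's posterior predictive only, ignoring downstream
#'   likelihood contributions.
#' @return an object of class `blsem_state`.
#' @export
sem_init <- function(table, bs, priors = list(), select = TRUE,
                     scan = c("systematic", "random"),
                     predictive_only = FALSE) {
  stopifnot(inherits(bs, "blsem_blocks"))
  scan <- match.arg(scan)
  priors <- .default_priors(priors)

  rep <- validate_data(bs, table)
  if (!rep$ok)
    stop("data table fails validation; see validate_data() report",
         call. = FALSE)
  mtab <- expand_categoricals(bs, table)
  dn <- .drop_no_impute(bs, mtab)
  mtab <- dn$table
  if (dn$dropped > 0)
    message("dropped ", dn$dropped,
            " row(s) with missing values in no-impute variables")
  std <- standardize(mtab, bs)
  X <- as.matrix(std$table)
  n <- nrow(X)
  cols <- bs$columns
  p_all <- nrow(cols)

  missing <- lapply(seq_len(p_all), function(j) which(is.na(X[, j])))
  names(missing) <- cols$column

  # initial fill: standardised mean (0) for continuous, modal category for
  # binary columns
  for (j in seq_len(p_all)) {
    mj <- missing[[j]]
    if (!length(mj)) next
    if (cols$type[j] == "binary") {
      obs <- X[-mj, j]
      X[mj, j] <- as.numeric(mean(obs) >= 0.5)
    } else {
      X[mj, j] <- 0
    }
  }

  ce <- candidate_edges(bs)
  K <- length(ce)
  colpos <- setNames(seq_len(p_all), cols$column)
  candidx <- lapply(ce, function(e) unname(colpos[e$candidates]))
  respidx <- vapply(ce, function(e) unname(colpos[e$response]), 1L)
  forced <- lapply(ce, function(e) if (select) e$forced else
    rep(TRUE, length(e$forced)))

  gamma <- lapply(ce, function(e) as.integer(
    if (select) e$forced else rep(TRUE, length(e$forced))))
  beta <- lapply(ce, function(e) numeric(length(e$candidates)))
  alpha <- setNames(numeric(K), names(ce))
  sigma2 <- vapply(seq_len(K), function(k) {
    y <- X[, respidx[k]]
    max(var(y), 1e-6)
  }, 1)
  names(sigma2) <- names(ce)
  pi <- setNames(rep(0.5, K), names(ce))

  # latent normal/probit joint over exogenous (incl. forced) columns
  exoidx <- which(cols$role != "endogenous")
  exo <- NULL
  if (length(exoidx)) {
    pe <- length(exoidx)
    Z <- X[, exoidx, drop = FALSE]
    isbin <- cols$type[exoidx] == "binary"
    for (jj in seq_len(pe))
      if (isbin[jj]) Z[, jj] <- ifelse(X[, exoidx[jj]] >= 0.5, 0.5, -0.5)
    exo <- list(
      idx = exoidx, isbin = isbin, Z = Z,
      mu = colMeans(Z), Sigma = diag(pe),
      m0 = rep(0, pe), k0 = priors$k0, nu0 = pe + priors$nu0_extra,
      S0 = diag(pe))
  }

  structure(list(
    X = X, bs = bs, scale = std$scale, ce = ce, candidx = candidx,
    respidx = respidx, forced = forced, gamma = gamma, beta = beta,
    alpha = alpha, sigma2 = sigma2, pi = pi, priors = priors,
    scan = scan, select = select, predictive_only = predictive_only,
    missing = missing, exo = exo, n = n, n_dropped = dn$dropped,
    ridge_count = 0L, observed = mtab
  ), class = "blsem_state")
}

#' Update one blockwise regression by a full-conditional sweep
#'
#' One spike-and-slab Gibbs update for response `k`: each selectable
#' inclusion indicator is resampled from its full conditional with the
#' coefficient integrated out analytically under the conjugate normal
#' slab, the active coefficient vector is then redrawn jointly from its
#' multivariate normal full conditional, followed by conjugate updates of
#' the intercept, the residual variance (inverse gamma) and the prior
#' inclusion probability (beta). Forced covariates are skipped in the
#' indicator sweep.
#'
#' @param state a `blsem_state`.
#' @param k response name or index.
#' @return the updated state.
#' @export
update_regression <- function(state, k) {
  stopifnot(inherits(state, "blsem_state"))
  if (is.character(k)) k <- match(k, names(state$ce))
  if (is.na(k) || k < 1L || k > length(state$ce))
    stop("unknown response", call. = FALSE)
  idx <- state$candidx[[k]]
  y <- state$X[, state$respidx[k]]
  if (!all(is.finite(y)))
    stop("non-finite values in response `", names(state$ce)[k], "`",
         call. = FALSE)
  p <- length(idx)
  pr <- state$priors
  if (p == 0L) {
    # intercept-only response
    n <- state$n
    r <- y - state$alpha[k]
    a <- mean(y) + rnorm(1) * sqrt(state$sigma2[k] / n)
    ssr <- sum((y - a)^2)
    state$alpha[k] <- a
    state$sigma2[k] <- 1 / rgamma(1, pr$a0 + n / 2, rate = pr$b0 + ssr / 2)
    return(state)
  }
  Xk <- state$X[, idx, drop = FALSE]
  if (!all(is.finite(Xk)))
    stop("non-finite values in design for response `",
         names(state$ce)[k], "`", call. = FALSE)
  xtx <- colSums(Xk * Xk)
  scan <- if (state$scan == "random") sample.int(p) - 1L else seq_len(p) - 1L
  up <- .update_regression_cpp(
    Xk, y, state$gamma[[k]], state$beta[[k]], state$alpha[k],
    state$sigma2[k], state$pi[k], as.integer(state$forced[[k]]), xtx,
    as.integer(scan), pr$tau2, pr$a0, pr$b0, pr$pi_a, pr$pi_b)
  state$gamma[[k]] <- as.integer(up$gamma)
  state$beta[[k]] <- as.numeric(up$beta)
  state$alpha[k] <- up$alpha
  state$sigma2[k] <- up$sigma2
  state$pi[k] <- up$pi
  state$ridge_count <- state$ridge_count + up$n_ridge
  state
}

#' One full Gibbs sweep
#'
#' Sweeps over all blockwise regressions ([update_regression()]) in
#' chronological response order, then performs the imputation updates for
#' missing endogenous and exogenous cells. With no missing cells the
#' imputation sub-steps leave the data matrix untouched. The result is a
#' deterministic function of the state and R's RNG stream.
#'
#' @param state a `blsem_state`.
#' @return the updated state.
#' @export
gibbs_step <- function(state) {
  stopifnot(inherits(state, "blsem_state"))
  for (k in seq_along(state$ce)) state <- update_regression(state, k)
  state <- update_missing_endogenous(state)
  state <- update_missing_exogenous(state)
  state
}

.bayes_r2_now <- function(state) {
  vapply(seq_along(state$ce), function(k) {
    idx <- state$candidx[[k]]
    fit <- if (length(idx))
      drop(state$X[, idx, drop = FALSE] %*% state$beta[[k]]) + state$alpha[k]
    else rep(state$alpha[k], state$n)
    vf <- var(fit)
    vf / (vf + state$sigma2[k])
  }, 1)
}

#' Run the blockwise spike-and-slab Gibbs sampler
#'
#' Estimates all blockwise regressions jointly by MCMC with built-in
#' missing-data imputation, returning the stored posterior draws of every
#' coefficient, inclusion indicator, intercept, residual variance, prior
#' inclusion probability, per-response Bayesian R-squared and every
#' imputed cell.
#'
#' Priors: coefficients carry a spike-and-slab prior (point mass at zero,
#' normal slab `N(0, tau2 * sigma2_k)`, default `tau2 = 10`); residual
#' variances `sigma2_k ~ IG(a0, b0)` with default `a0 = b0 = 0.01`; the
#' per-response prior inclusion probability `pi_k ~ Beta(pi_a, pi_b)`,
#' default uniform. Forced covariates are always included. Continuous
#' variables are standardised internally, so reported coefficients are in
#' SD units (per 1-SD change of continuous predictors, per 0-to-1 change
#' of binary predictors).
#'
#' @inheritParams sem_init
#' @param iterations total MCMC iterations.
#' @param burn_in discarded initial iterations (`iterations > burn_in`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed (mandatory; the run is fully reproducible
#'   from it).
#' @param progress print a progress line every 10% of iterations.
#' @return an object of class `blsem_chain`; see [compute_mppi()],
#'   [summarize_chain()], [bayes_r2()], [threshold_dag()].
#' @examples
#' \donttest{
#' spec <- nfbc_like_spec(n = 300)
#' sim <- simulate_cohort(spec, seed = 1)
#' fit <- run_chain(sim$data, spec$bs, iterations = 200, burn_in = 100,
#'                  thin = 1, seed = 1)
#' head(compute_mppi(fit))
#' }
#' @export
run_chain <- function(table, bs, iterations = 20000, burn_in = 5000,
                      thin = 5, seed, priors = list(), select = TRUE,
                      scan = c("systematic", "random"),
                      predictive_only = FALSE, progress = FALSE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  if (!is.numeric(iterations) || !is.numeric(burn_in) ||
      iterations <= burn_in)
    stop("`iterations` must exceed `burn_in`", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  scan <- match.arg(scan)

  set.seed(as.integer(seed))
  state <- sem_init(table, bs, priors = priors, select = select,
                    scan = scan, predictive_only = predictive_only)
  K <- length(state$ce)
  rnames <- names(state$ce)
  n_draws <- floor((iterations - burn_in) / thin)

  beta_draws <- lapply(state$ce, function(e)
    matrix(NA_real_, n_draws, length(e$candidates),
           dimnames = list(NULL, e$candidates)))
  gamma_draws <- lapply(state$ce, function(e)
    matrix(NA_integer_, n_draws, length(e$candidates),
           dimnames = list(NULL, e$candidates)))
  alpha_draws <- matrix(NA_real_, n_draws, K, dimnames = list(NULL, rnames))
  sigma2_draws <- alpha_draws
  pi_draws <- alpha_draws
  r2_draws <- alpha_draws
  miss_cells <- do.call(rbind, lapply(names(state$missing), function(cn) {
    rows <- state$missing[[cn]]
    if (!length(rows)) return(NULL)
    data.frame(column = cn, row = rows, stringsAsFactors = FALSE)
  }))
  n_miss <- if (is.null(miss_cells)) 0L else nrow(miss_cells)
  imp_draws <- if (n_miss) matrix(
    NA_real_, n_draws, n_miss,
    dimnames = list(NULL, paste0(miss_cells$column, ":", miss_cells$row)))
  else NULL
  mcidx <- if (n_miss)
    cbind(miss_cells$row, match(miss_cells$column, colnames(state$X)))

  d <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_step(state)
    if (it > burn_in && (it - burn_in) %% thin == 0 && d < n_draws) {
      d <- d + 1L
      for (k in seq_len(K)) {
        beta_draws[[k]][d, ] <- state$beta[[k]]
        gamma_draws[[k]][d, ] <- state$gamma[[k]]
      }
      alpha_draws[d, ] <- state$alpha
      sigma2_draws[d, ] <- state$sigma2
      pi_draws[d, ] <- state$pi
      r2_draws[d, ] <- .bayes_r2_now(state)
      if (n_miss) imp_draws[d, ] <- state$X[mcidx]
    }
    if (progress && it %% max(1L, iterations %/% 10L) == 0L)
      message("iteration ", it, "/", iterations)
  }

  structure(list(
    bs = bs, scale = state$scale, candidates = state$ce,
    beta = beta_draws, gamma = gamma_draws, alpha = alpha_draws,
    sigma2 = sigma2_draws, pi = pi_draws, r2 = r2_draws,
    imputed = imp_draws, missing_cells = miss_cells,
    observed = state$observed, n = state$n, n_dropped = state$n_dropped,
    ridge_count = state$ridge_count,
    config = list(iterations = iterations, burn_in = burn_in, thin = thin,
                  seed = as.integer(seed), priors = state$priors,
                  select = select, scan = scan,
                  predictive_only = predictive_only,
                  n_draws = n_draws)
  ), class = "blsem_chain")
}

#' @export
print.blsem_chain <- function(x, ...) {
  cat("Bayesian life-course SEM chain:\n")
  cat("  ", length(x$candidates), "responses,",
      sum(vapply(x$candidates, function(e) length(e$candidates), 1L)),
      "candidate edges\n")
  cat("  ", x$config$n_draws, "stored draws (iterations",
      x$config$iterations, ", burn-in", x$config$burn_in, ", thin",
      x$config$thin, ", seed", x$config$seed, ")\n")
  cat("  ", x$n, "subjects;",
      if (is.null(x$missing_cells)) 0 else nrow(x$missing_cells),
      "imputed cells\n")
  invisible(x)
}

#' Marginal posterior probabilities of inclusion
#'
#' The MPPI of a candidate edge (covariate `j`, response `k`) is the mean
#' of its binary inclusion indicator over the stored draws: the
#' model-averaged evidence for that association. Forced covariates are
#' reported with MPPI 1 and flagged.
#'
#' @param chain a `blsem_chain`.
#' @return a data frame of class `blsem_mppi` with columns `response`,
#'   `candidate`, `mppi`, `forced` and `beta_mean` (model-averaged
#'   posterior-mean coefficient).
#' @export
compute_mppi <- function(chain) {
  stopifnot(inherits(chain, "blsem_chain"))
  if (chain$config$n_draws < 1L) stop("empty chain", call. = FALSE)
  out <- lapply(names(chain$candidates), function(k) {
    e <- chain$candidates[[k]]
    if (!length(e$candidates)) return(NULL)
    data.frame(
      response = k, candidate = e$candidates,
      mppi = colMeans(chain$gamma[[k]]),
      forced = e$forced,
      beta_mean = colMeans(chain$beta[[k]]),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("blsem_mppi", "data.frame")
  out
}
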