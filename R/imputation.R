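#' Redraw missing endogenous cells from their Gaussian full conditional
#'
#' Each missing endogenous cell is redrawn from the exact conjugate normal
#' full conditional combining (a) the posterior predictive distribution of
#' its own regression and (b) the likelihood contributions of every
#' downstream regression in which the variable currently appears with a
#' non-zero (included) coefficient. With `predictive_only = TRUE` at
#' initialisation, only (a) is used, i.e. the literal posterior-predictive
#' reading. Variables are processed in chronological block order; observed
#' cells are never modified.
#'
#' @param state a `blsem_state`.
#' @return the updated state.
#' @export
update_missing_endogenous <- function(state) {
  stopifnot(inherits(state, "blsem_state"))
  cols <- state$bs$columns
  rnames <- names(state$ce)
  for (k in seq_along(state$ce)) {
    cn <- rnames[k]
    rows <- state$missing[[cn]]
    if (!length(rows)) next
    j <- state$respidx[k]
    idx <- state$candidx[[k]]
    mu_own <- if (length(idx))
      drop(state$X[rows, idx, drop = FALSE] %*% state$beta[[k]]) +
        state$alpha[k]
    else rep(state$alpha[k], length(rows))
    prec <- rep(1 / state$sigma2[k], length(rows))
    num <- mu_own / state$sigma2[k]
    if (!state$predictive_only) {
      for (m in seq_along(state$ce)) {
        pos <- match(cn, state$ce[[m]]$candidates)
        if (is.na(pos)) next
        b <- state$beta[[m]][pos]
        if (b == 0) next
        midx <- state$candidx[[m]]
        pred_full <- drop(state$X[rows, midx, drop = FALSE] %*%
                            state$beta[[m]]) + state$alpha[m]
        pred_excl <- pred_full - b * state$X[rows, j]
        resid <- state$X[rows, state$respidx[m]] - pred_excl
        prec <- prec + b * b / state$sigma2[m]
        num <- num + b * resid / state$sigma2[m]
      }
    }
    v <- 1 / prec
    if (any(!is.finite(v)))
      stop("non-finite conditional variance while imputing `", cn, "`",
           call. = FALSE)
    state$X[rows, j] <- rnorm(length(rows), num * v, sqrt(v))
  }
  state
}

# Truncated-normal draw via inverse CDF, sign enforced for numerical
# stability at extreme means.
.rtruncnorm_sign <- function(mean, sd, positive) {
  p0 <- pnorm(0, mean, sd)
  u <- ifelse(positive, runif(length(mean), p0, 1), runif(length(mean), 0, p0))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  z <- qnorm(u, mean, sd)
  ifelse(positive, pmax(z, 0), pmin(z, -1e-12))
}

#' Update the latent normal/probit model over exogenous columns
#'
#' One Gibbs sweep of the joint imputation model for exogenous covariates:
#' (1) latent normals behind observed binary cells are redrawn from
#' truncated-normal full conditionals consistent with the observed
#' category (threshold 0); (2) latents of missing cells are redrawn from
#' untruncated conditionals given the other columns; (3) the latent mean
#' and covariance are refreshed from their conjugate
#' normal-inverse-Wishart full conditionals; (4) missing binary cells are
#' set by thresholding their latents and missing continuous exogenous
#' cells to their latent draws. Observed cells are never modified.
#'
#' @param state a `blsem_state`.
#' @return the updated state.
#' @export
update_missing_exogenous <- function(state) {
  stopifnot(inherits(state, "blsem_state"))
  exo <- state$exo
  if (is.null(exo)) return(state)
  pe <- length(exo$idx)
  n <- state$n
  Z <- exo$Z
  mu <- exo$mu

  Omega <- tryCatch(solve(exo$Sigma), error = function(e) {
    solve(exo$Sigma + diag(1e-8, pe))
  })
  Zc <- sweep(Z, 2, mu)
  M <- Zc %*% Omega

  for (jj in seq_len(pe)) {
    j <- exo$idx[jj]
    mrows <- state$missing[[colnames(state$X)[j]]]
    needs_all <- exo$isbin[jj]
    if (!needs_all && !length(mrows)) next
    cm <- mu[jj] - (M[, jj] - Zc[, jj] * Omega[jj, jj]) / Omega[jj, jj]
    cs <- sqrt(1 / Omega[jj, jj])
    znew <- Z[, jj]
    if (needs_all) {
      obs <- setdiff(seq_len(n), mrows)
      if (length(obs)) {
        pos <- state$X[obs, j] >= 0.5
        znew[obs] <- .rtruncnorm_sign(cm[obs], cs, pos)
      }
      if (length(mrows)) znew[mrows] <- rnorm(length(mrows), cm[mrows], cs)
    } else {
      znew[mrows] <- rnorm(length(mrows), cm[mrows], cs)
    }
    delta <- znew - Z[, jj]
    upd <- which(delta != 0)
    if (length(upd)) {
      Z[upd, jj] <- znew[upd]
      Zc[upd, jj] <- znew[upd] - mu[jj]
      M[upd, ] <- M[upd, , drop = FALSE] + outer(delta[upd], Omega[jj, ])
    }
  }

  # conjugate normal-inverse-Wishart refresh of (mu, Sigma)
  zbar <- colMeans(Z)
  Sc <- crossprod(sweep(Z, 2, zbar))
  kn <- exo$k0 + n
  mn <- (exo$k0 * exo$m0 + n * zbar) / kn
  nun <- exo$nu0 + n
  Sn <- exo$S0 + Sc + (exo$k0 * n / kn) * tcrossprod(zbar - exo$m0)
  Sigma <- NULL
  for (jit in c(0, 1e-8, 1e-6)) {
    Sni <- tryCatch(solve(Sn + diag(jit * (1 + max(diag(Sn))), pe)),
                    error = function(e) NULL)
    if (is.null(Sni)) next
    W <- rWishart(1, nun, Sni)[, , 1]
    Sigma <- tryCatch(solve(W), error = function(e) NULL)
    if (!is.null(Sigma)) break
  }
  if (is.null(Sigma))
    stop("latent covariance update failed: scatter matrix not invertible ",
         "after jitter", call. = FALSE)
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(mn + t(chol(Sigma)) %*% rnorm(pe) / sqrt(kn))

  # write imputed exogenous cells back to the model matrix
  for (jj in seq_len(pe)) {
    j <- exo$idx[jj]
    mrows <- state$missing[[colnames(state$X)[j]]]
    if (!length(mrows)) next
    state$X[mrows, j] <- if (exo$isbin[jj])
      as.numeric(Z[mrows, jj] >= 0) else Z[mrows, jj]
  }

  state$exo$Z <- Z
  state$exo$mu <- mu
  state$exo$Sigma <- Sigma
  state
}

#' Current completed data table
#'
#' Returns the model table on the original scale with observed cells
#' verbatim and missing cells filled with the current imputation draws of
#' a sampler state, or with the stored draws of a fitted chain.
#'
#' @param x a `blsem_state` or `blsem_chain`.
#' @param draw for a chain, the index of the stored draw to use.
#' @return a data frame of model columns on the original scale.
#' @export
completed_table <- function(x, draw = NULL) {
  if (inherits(x, "blsem_state")) {
    std <- as.data.frame(x$X)
    return(destandardize_table(std, x$scale))
  }
  stopifnot(inherits(x, "blsem_chain"))
  out <- x$observed
  if (is.null(x$imputed)) return(out)
  if (is.null(draw)) stop("`draw` required for a fitted chain", call. = FALSE)
  stopifnot(draw >= 1, draw <= nrow(x$imputed))
  sc <- x$scale
  for (i in seq_len(nrow(x$missing_cells))) {
    cn <- x$missing_cells$column[i]
    row <- x$missing_cells$row[i]
    v <- x$imputed[draw, i]
    si <- match(cn, sc$column)
    if (sc$scaled[si]) v <- v * sc$scale[si] + sc$center[si]
    out[row, cn] <- v
  }
  out
}

#' Per-cell imputation diagnostics
#'
#' @param chain a `blsem_chain`.
#' @return data frame with one row per imputed cell: `column`, `row`,
#'   posterior mean and SD of the imputed value (original scale), and the
#'   variable's overall missing fraction.
#' @export
imputation_diagnostics <- function(chain) {
  stopifnot(inherits(chain, "blsem_chain"))
  if (is.null(chain$imputed))
    return(data.frame(column = character(), row = integer(),
                      post_mean = numeric(), post_sd = numeric(),
                      missing_frac = numeric()))
  sc <- chain$scale
  mc <- chain$missing_cells
  mfrac <- vapply(mc$column, function(cn)
    mean(is.na(chain$observed[[cn]])), 1)
  pm <- colMeans(chain$imputed)
  ps <- apply(chain$imputed, 2, sd)
  si <- match(mc$column, sc$column)
  scale <- ifelse(sc$scaled[si], sc$scale[si], 1)
  center <- ifelse(sc$scaled[si], sc$center[si], 0)
  data.frame(column = mc$column, row = mc$row,
             post_mean = pm * scale + center, post_sd = ps * scale,
             missing_frac = unname(mfrac), stringsAsFactors = FALSE)
}
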