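#' Specify a synthetic life-course cohort generator
#'
#' Defines the ground truth of a simulated cohort: the block structure,
#' the true sparse forward-only coefficient matrix over the candidate
#' edge set, residual SDs, the latent exogenous model (correlated unit
#' normals; binary and categorical variables arise by thresholding), and
#' an optional missingness mechanism. Exogenous sources each own one
#' latent dimension; categorical variables are cut at quantile cutpoints
#' matching the declared level probabilities.
#'
#' @param bs a `blsem_blocks` object.
#' @param edges data frame with columns `from`, `to`, `beta`: the true
#'   structural coefficients over *model columns*; must be a subset of
#'   the candidate edge set.
#' @param exo_cor correlation matrix over exogenous source variables
#'   (declared order); default identity.
#' @param exo_mean named numeric, means of continuous exogenous sources
#'   (default 0).
#' @param prevalence named list: for binary sources, the success
#'   probability (default 0.5); for categorical sources, the vector of
#'   level probabilities (default uniform).
#' @param resid_sd named numeric of true residual SDs per endogenous
#'   column; by default chosen so each endogenous variable has total
#'   variance 1 where the systematic variance allows (residual variance
#'   floor 0.2).
#' @param missingness `NULL`, or a list with `type` (`"mcar"` or
#'   `"mar"`), `targets` (named rates per variable), and for MAR a fully
#'   observed binary `driver` and `logodds` (difference in log-odds of
#'   missingness between driver levels).
#' @param n default number of subjects.
#' @return an object of class `blsem_genspec` with an attached `truth`
#'   record (analytic means, covariance, SDs, per-response R-squared and
#'   standardised coefficients).
#' @export
generator_spec <- function(bs, edges, exo_cor = NULL, exo_mean = NULL,
                           prevalence = NULL, resid_sd = NULL,
                           missingness = NULL, n = 1000) {
  stopifnot(inherits(bs, "blsem_blocks"))
  cols <- bs$columns
  ce <- candidate_edges(bs)
  allowed <- unlist(lapply(ce, function(e)
    paste(e$candidates, e$response, sep = "\r")))
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "beta") %in% names(edges)))
  bad <- !paste(edges$from, edges$to, sep = "\r") %in% allowed
  if (any(bad))
    stop("true edge(s) outside the candidate edge set: ",
         paste(paste(edges$from[bad], edges$to[bad], sep = "->"),
               collapse = ", "), call. = FALSE)

  exo_src <- unique(cols$source[cols$role != "endogenous"])
  ns <- length(exo_src)
  if (is.null(exo_cor)) exo_cor <- diag(ns)
  stopifnot(nrow(exo_cor) == ns, ncol(exo_cor) == ns)
  ev <- eigen(exo_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("`exo_cor` is not positive definite", call. = FALSE)
  dimnames(exo_cor) <- list(exo_src, exo_src)

  mean_src <- setNames(rep(0, ns), exo_src)
  if (!is.null(exo_mean)) mean_src[names(exo_mean)] <- exo_mean

  # latent interval (a, b] for every binary/indicator model column
  intervals <- list()
  for (src in exo_src) {
    v <- bs$variables[[src]]
    if (v$type == "binary") {
      p <- prevalence[[src]] %||% 0.5
      stopifnot(p > 0, p < 1)
      intervals[[src]] <- c(qnorm(1 - p), Inf)
    } else if (v$type == "categorical") {
      L <- length(v$levels)
      pr <- prevalence[[src]] %||% rep(1 / L, L)
      stopifnot(length(pr) == L, all(pr > 0), abs(sum(pr) - 1) < 1e-8)
      cuts <- c(-Inf, qnorm(cumsum(pr))[-L], Inf)
      for (l in seq_len(L))
        intervals[[paste0(src, ".", v$levels[l])]] <- cuts[c(l, l + 1L)]
    }
  }

  if (!is.null(missingness)) {
    stopifnot(missingness$type %in% c("mcar", "mar"))
    stopifnot(!is.null(missingness$targets),
              all(unlist(missingness$targets) >= 0),
              all(unlist(missingness$targets) < 1))
    if (missingness$type == "mar") {
      if (is.null(missingness$driver) || is.null(missingness$logodds))
        stop("MAR missingness needs `driver` and `logodds`", call. = FALSE)
      if (missingness$driver %in% names(missingness$targets))
        stop("the MAR driver cannot itself be masked", call. = FALSE)
    }
  }

  spec <- structure(list(
    bs = bs, edges = edges, exo_src = exo_src, exo_cor = exo_cor,
    exo_mean = mean_src, intervals = intervals, resid_sd = resid_sd,
    missingness = missingness, n = as.integer(n)), class = "blsem_genspec")
  spec$truth <- .truth_moments(spec)
  spec$resid_sd <- spec$truth$resid_sd
  spec
}

# Cov(1{a < z <= b}, x) for (z, x) standard bivariate normal with
# correlation rho: rho * (phi(a) - phi(b)).
.phi_diff <- function(iv) dnorm(iv[1]) - dnorm(iv[2])

# P(a1 < z1 <= b1, a2 < z2 <= b2) under correlation rho, by univariate
# quadrature over z1.
.rect_prob <- function(iv1, iv2, rho) {
  p1 <- pnorm(iv1[2]) - pnorm(iv1[1])
  p2 <- pnorm(iv2[2]) - pnorm(iv2[1])
  if (abs(rho) < 1e-12) return(p1 * p2)
  s <- sqrt(1 - rho^2)
  f <- function(z) dnorm(z) *
    (pnorm((iv2[2] - rho * z) / s) - pnorm((iv2[1] - rho * z) / s))
  integrate(f, iv1[1], iv1[2], rel.tol = 1e-10)$value
}

# Analytic first and second moments of every model column, the implied
# residual SDs (unit-total-variance target, variance floor 0.2), true
# R-squared per response and standardised coefficients.
.truth_moments <- function(spec) {
  bs <- spec$bs
  cols <- bs$columns
  p <- nrow(cols)
  cn <- cols$column
  Sigma <- matrix(0, p, p, dimnames = list(cn, cn))
  mu <- setNames(numeric(p), cn)

  exo_i <- which(cols$role != "endogenous")
  # exogenous block of the covariance
  for (ii in exo_i) {
    si <- cols$source[ii]
    iv_i <- spec$intervals[[cn[ii]]]
    for (jj in exo_i) {
      if (jj > ii) next
      sj <- cols$source[jj]
      rho <- spec$exo_cor[si, sj]
      iv_j <- spec$intervals[[cn[jj]]]
      v <- if (is.null(iv_i) && is.null(iv_j)) {
        if (ii == jj) 1 else rho
      } else if (is.null(iv_i)) {
        rho * .phi_diff(iv_j)
      } else if (is.null(iv_j)) {
        rho * .phi_diff(iv_i)
      } else if (ii == jj) {
        pi_ <- pnorm(iv_i[2]) - pnorm(iv_i[1])
        pi_ * (1 - pi_)
      } else if (si == sj) {
        # disjoint intervals of the same latent
        pi_ <- pnorm(iv_i[2]) - pnorm(iv_i[1])
        pj_ <- pnorm(iv_j[2]) - pnorm(iv_j[1])
        -pi_ * pj_
      } else {
        pi_ <- pnorm(iv_i[2]) - pnorm(iv_i[1])
        pj_ <- pnorm(iv_j[2]) - pnorm(iv_j[1])
        .rect_prob(iv_i, iv_j, rho) - pi_ * pj_
      }
      Sigma[ii, jj] <- Sigma[jj, ii] <- v
    }
    mu[ii] <- if (is.null(iv_i)) spec$exo_mean[si]
    else pnorm(iv_i[2]) - pnorm(iv_i[1])
  }

  # endogenous columns in block/declaration order
  resid_sd <- spec$resid_sd
  fixed_sd <- !is.null(resid_sd)
  if (!fixed_sd) resid_sd <- c()
  r2 <- c()
  endo_i <- which(cols$role == "endogenous")
  for (ii in endo_i) {
    k <- cn[ii]
    ek <- spec$edges[spec$edges$to == k, , drop = FALSE]
    b <- setNames(ek$beta, ek$from)
    if (length(b)) {
      ji <- match(names(b), cn)
      vsys <- drop(t(b) %*% Sigma[ji, ji, drop = FALSE] %*% b)
      cov_prior <- drop(Sigma[, ji, drop = FALSE] %*% b)
    } else {
      vsys <- 0
      cov_prior <- numeric(p)
    }
    s2 <- if (fixed_sd) resid_sd[[k]]^2 else max(1 - vsys, 0.2)
    if (!fixed_sd) resid_sd[k] <- sqrt(s2)
    Sigma[, ii] <- Sigma[ii, ] <- cov_prior
    Sigma[ii, ii] <- vsys + s2
    mu[ii] <- if (length(b)) sum(b * mu[match(names(b), cn)]) else 0
    r2[k] <- vsys / (vsys + s2)
  }

  sd_all <- sqrt(diag(Sigma))
  # standardised coefficients: continuous predictors per SD, binary per
  # 0-to-1 change, response always per SD
  std_edges <- spec$edges
  if (nrow(std_edges)) {
    sfrom <- ifelse(cols$type[match(std_edges$from, cn)] == "continuous",
                    sd_all[std_edges$from], 1)
    std_edges$beta_std <- std_edges$beta * sfrom / sd_all[std_edges$to]
  } else std_edges$beta_std <- numeric(0)

  list(mean = mu, Sigma = Sigma, sd = sd_all,
       type = setNames(cols$type, cn),
       resid_sd = unlist(resid_sd)[cn[endo_i]],
       r2 = r2, edges = spec$edges, std_edges = std_edges)
}

#' Simulate a complete synthetic cohort
#'
#' Draws the exogenous latents from their joint normal, thresholds them
#' into binary/categorical observations, then generates the endogenous
#' variables block by block as linear combinations of earlier variables
#' plus Gaussian noise. The returned truth record carries the analytic
#' covariance, per-response R-squared, and true standardised
#' coefficients, from which direct/indirect/total effects for any pair
#' follow by path products (see [true_effects()]).
#'
#' @param spec a `blsem_genspec`.
#' @param n number of subjects (default `spec$n`).
#' @param seed integer RNG seed.
#' @return list with `data` (data frame over the declared variables,
#'   categorical columns as level strings) and `truth`.
#' @export
simulate_cohort <- function(spec, n = spec$n, seed = NULL) {
  stopifnot(inherits(spec, "blsem_genspec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  bs <- spec$bs
  cols <- bs$columns
  cn <- cols$column

  ns <- length(spec$exo_src)
  L <- matrix(rnorm(n * ns), n, ns) %*% chol(spec$exo_cor)
  colnames(L) <- spec$exo_src

  X <- matrix(NA_real_, n, nrow(cols), dimnames = list(NULL, cn))
  for (i in which(cols$role != "endogenous")) {
    src <- cols$source[i]
    iv <- spec$intervals[[cn[i]]]
    X[, i] <- if (is.null(iv)) L[, src] + spec$exo_mean[src]
    else as.numeric(L[, src] > iv[1] & L[, src] <= iv[2])
  }
  for (i in which(cols$role == "endogenous")) {
    k <- cn[i]
    ek <- spec$edges[spec$edges$to == k, , drop = FALSE]
    lin <- if (nrow(ek))
      drop(X[, ek$from, drop = FALSE] %*% ek$beta) else rep(0, n)
    X[, i] <- lin + rnorm(n, 0, spec$truth$resid_sd[[k]])
  }

  # fold indicator columns back into declared categorical variables
  out <- list()
  for (nm in names(bs$variables)) {
    v <- bs$variables[[nm]]
    if (v$type == "categorical") {
      lev <- rep(v$levels[1L], n)
      for (l in v$levels[-1L]) {
        ind <- X[, paste0(nm, ".", l)]
        lev[ind == 1] <- l
      }
      out[[nm]] <- lev
    } else {
      out[[nm]] <- X[, nm]
    }
  }
  list(data = as.data.frame(out, optional = TRUE), truth = spec$truth)
}

#' Mask cells of a complete table under the declared mechanism
#'
#' MCAR masks each target cell independently at its rate. MAR masks a
#' target cell with probability logistic in a fully observed binary
#' driver: `logit P(missing) = qlogis(rate) - logodds/2 + logodds * driver`,
#' so the two driver levels differ by `logodds` on the log-odds scale
#' while the marginal rate stays close to `rate` for a balanced driver.
#'
#' @param table complete data frame from [simulate_cohort()].
#' @param spec a `blsem_genspec` whose `missingness` element is non-NULL,
#'   or the missingness list itself.
#' @param seed optional RNG seed.
#' @return list with `table` (masked copy) and `mask` (logical data
#'   frame, `TRUE` = masked).
#' @export
apply_missingness <- function(table, spec, seed = NULL) {
  ms <- if (inherits(spec, "blsem_genspec")) spec$missingness else spec
  if (!is.null(seed)) set.seed(as.integer(seed))
  mask <- as.data.frame(lapply(table, function(x) rep(FALSE, nrow(table))))
  if (is.null(ms)) return(list(table = table, mask = mask))
  stopifnot(ms$type %in% c("mcar", "mar"))
  n <- nrow(table)
  for (nm in names(ms$targets)) {
    rate <- ms$targets[[nm]]
    if (rate <= 0) next
    if (!nm %in% names(table))
      stop("missingness target `", nm, "` not in table", call. = FALSE)
    pr <- if (ms$type == "mcar") rep(rate, n) else {
      drv <- table[[ms$driver]]
      if (anyNA(drv))
        stop("MAR driver `", ms$driver, "` has missing values",
             call. = FALSE)
      plogis(qlogis(rate) - ms$logodds / 2 + ms$logodds * drv)
    }
    m <- runif(n) < pr
    mask[[nm]] <- m
    table[[nm]][m] <- NA
  }
  list(table = table, mask = mask)
}

#' Analytic direct, indirect and total effects from a truth record
#'
#' Path-product effects over the true edge set: the direct effect is the
#' true coefficient of the exposure in the outcome's equation (0 if
#' absent), each indirect path effect the product of true coefficients
#' along a directed path, the total their sum. With
#' `standardized = TRUE`, effects are in SD units of the outcome (per SD
#' of a continuous exposure, per 0-to-1 change of a binary exposure),
#' using the analytic SDs.
#'
#' @param truth truth record from [simulate_cohort()] / `blsem_genspec`.
#' @param exposure,outcome model column names.
#' @param standardized report on the standardised scale (default) or the
#'   generator scale.
#' @return list with `direct`, `indirect`, `total`, `n_paths`, `paths`.
#' @export
true_effects <- function(truth, exposure, outcome, standardized = TRUE) {
  edges <- truth$edges
  nodes <- unique(c(edges$from, edges$to, exposure, outcome))
  dag <- structure(list(
    nodes = nodes,
    edges = data.frame(from = edges$from, to = edges$to, mppi = 1,
                       beta_mean = edges$beta, stringsAsFactors = FALSE),
    tau = 0.5, run_seed = NULL), class = "blsem_dag")
  paths <- enumerate_paths(dag, exposure, outcome)
  bmap <- setNames(edges$beta, paste(edges$from, edges$to, sep = "\r"))
  prod_path <- function(p) {
    prod(bmap[paste(p[-length(p)], p[-1L], sep = "\r")])
  }
  direct <- unname(bmap[paste(exposure, outcome, sep = "\r")])
  if (is.na(direct)) direct <- 0
  ind <- vapply(paths[vapply(paths, length, 1L) > 2L], prod_path, 1)
  indirect <- sum(ind)
  if (standardized) {
    # binary exposures are reported per 0-to-1 change, continuous per SD
    s_exp <- if (truth$type[[exposure]] == "continuous")
      truth$sd[[exposure]] else 1
    f <- s_exp / truth$sd[[outcome]]
    direct <- direct * f
    indirect <- indirect * f
  }
  list(direct = direct, indirect = indirect, total = direct + indirect,
       n_paths = length(paths), paths = paths)
}
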