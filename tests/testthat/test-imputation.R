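test_that("with no missing cells the imputation steps leave data untouched", {
  spec <- nfbc_like_spec(n = 120, missingness = FALSE)
  sim <- simulate_cohort(spec, seed = 21)
  set.seed(2)
  st <- sem_init(sim$data, spec$bs)
  st2 <- update_missing_endogenous(st)
  expect_identical(st2$X, st$X)
  st3 <- update_missing_exogenous(st2)
  expect_identical(st3$X, st$X)   # only mu/Sigma/latents refresh
  expect_false(identical(st3$exo$Sigma, st$exo$Sigma))
})

test_that("observed cells are never modified by the sampler", {
  spec <- nfbc_like_spec(n = 200)
  sim <- simulate_cohort(spec, seed = 31)
  masked <- apply_missingness(sim$data, spec, seed = 32)
  fit <- run_chain(masked$table, spec$bs, iterations = 60, burn_in = 20,
                   thin = 1, seed = 33)
  mobs <- expand_categoricals(spec$bs, masked$table)
  for (d in c(1L, fit$config$n_draws)) {
    comp <- completed_table(fit, draw = d)
    obs <- !is.na(mobs)
    expect_equal(as.matrix(comp)[obs], as.matrix(mobs)[obs],
                 tolerance = 1e-9)
    expect_false(anyNA(comp))
  }
})

test_that("without downstream terms the endogenous draw is the predictive", {
  # single endogenous response: the full conditional must reduce to
  # N(x'beta, sigma2); cross-check against direct predictive sampling
  bs <- two_block_bs()
  set.seed(3)
  tab <- data.frame(x = rnorm(50), y = rnorm(50))
  tab$y[1:10] <- NA
  set.seed(4); st <- sem_init(tab, bs)
  st$beta$y <- 0.7; st$gamma$y <- 1L
  st$alpha["y"] <- 0.2; st$sigma2["y"] <- 0.5
  set.seed(99); st1 <- update_missing_endogenous(st)
  set.seed(99)
  mu <- 0.2 + 0.7 * st$X[1:10, "x"]
  direct <- rnorm(10, mu, sqrt(0.5))
  expect_equal(unname(st1$X[1:10, "y"]), direct, tolerance = 1e-12)
  # and the predictive-only flag gives the same law here
  st$predictive_only <- TRUE
  set.seed(99); st2 <- update_missing_endogenous(st)
  expect_identical(st2$X[1:10, "y"], st1$X[1:10, "y"])
})

test_that("latents behind observed binary cells respect the threshold", {
  spec <- nfbc_like_spec(n = 150)
  sim <- simulate_cohort(spec, seed = 41)
  masked <- apply_missingness(sim$data, spec, seed = 42)$table
  set.seed(5)
  st <- sem_init(masked, spec$bs)
  for (i in 1:5) st <- gibbs_step(st)
  cols <- spec$bs$columns
  for (jj in which(st$exo$isbin)) {
    j <- st$exo$idx[jj]
    cn <- colnames(st$X)[j]
    obs <- setdiff(seq_len(st$n), st$missing[[cn]])
    z <- st$exo$Z[obs, jj]
    x <- st$X[obs, j]
    expect_true(all(z[x == 1] >= 0))
    expect_true(all(z[x == 0] < 0))
  }
})

test_that("a strongly correlated partner pins the imputed value", {
  bs <- block_structure(
    list(list(name = "b1", endogenous = character(),
              exogenous = c("x1", "x2")),
         list(name = "b2", endogenous = "y", exogenous = character())),
    list(x1 = list(type = "continuous"), x2 = list(type = "continuous"),
         y = list(type = "continuous")))
  set.seed(8)
  n <- 300
  x <- rnorm(n)
  tab <- data.frame(x1 = x, x2 = x + rnorm(n, 0, 0.02), y = rnorm(n))
  partner <- tab$x1[5]
  tab$x2[5] <- NA
  fit <- run_chain(tab, bs, iterations = 300, burn_in = 100, thin = 1,
                   seed = 9)
  diag <- imputation_diagnostics(fit)
  row <- diag[diag$column == "x2" & diag$row == 5, ]
  expect_lt(abs(row$post_mean - partner), 0.25)
  expect_lt(row$post_sd, 0.25)
})

test_that("averaging completed tables matches the posterior-mean imputation", {
  bs <- two_block_bs()
  set.seed(10)
  tab <- data.frame(x = rnorm(5), y = rnorm(5))
  tab$x[2] <- NA; tab$y[4] <- NA
  fit <- run_chain(tab, bs, iterations = 200, burn_in = 50, thin = 1,
                   seed = 11)
  diag <- imputation_diagnostics(fit)
  avg <- Reduce(`+`, lapply(seq_len(fit$config$n_draws), function(d)
    as.matrix(completed_table(fit, d)))) / fit$config$n_draws
  for (i in seq_len(nrow(diag)))
    expect_equal(unname(avg[diag$row[i], diag$column[i]]),
                 diag$post_mean[i], tolerance = 1e-8)
})

test_that("rows missing a no-impute variable are dropped at load", {
  bs <- block_structure(
    list(list(name = "b1", endogenous = character(), exogenous = "x"),
         list(name = "b2", endogenous = "y", exogenous = character())),
    list(x = list(type = "continuous", no_impute = TRUE),
         y = list(type = "continuous")))
  set.seed(12)
  tab <- data.frame(x = rnorm(30), y = rnorm(30))
  tab$x[c(3, 7)] <- NA
  expect_message(st <- sem_init(tab, bs), "dropped 2")
  expect_identical(st$n, 28L)
})
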