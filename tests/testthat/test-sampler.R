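test_that("with selection disabled the posterior mean tracks least squares", {
  # y = x exactly after standardisation; vague slab -> OLS slope 1
  bs <- two_block_bs()
  tab <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3))
  fit <- run_chain(tab, bs, iterations = 3000, burn_in = 500, thin = 1,
                   seed = 4, select = FALSE,
                   priors = list(tau2 = 1e6))
  draws <- fit$beta$y[, "x"]
  mcse <- sd(draws) / sqrt(max(blsem:::.ess(draws), 1))
  expect_lt(abs(mean(draws) - 1), 3 * mcse + 1e-3)
  expect_true(all(fit$gamma$y == 1L))
})

test_that("a null candidate keeps MPPI below 0.5 on average", {
  bs <- two_block_bs()
  mp <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    tab <- data.frame(x = rnorm(500), y = rnorm(500))
    fit <- run_chain(tab, bs, iterations = 300, burn_in = 100, thin = 1,
                     seed = s)
    compute_mppi(fit)$mppi[1]
  }, 1)
  expect_lt(mean(mp), 0.5)
})

test_that("a perfect predictor is always included", {
  bs <- two_block_bs()
  x <- rnorm(100)
  fit <- run_chain(data.frame(x = x, y = x), bs, iterations = 300,
                   burn_in = 100, thin = 1, seed = 9)
  expect_true(all(fit$gamma$y[, "x"] == 1L))
})

test_that("stored draw count follows the iteration arithmetic", {
  bs <- two_block_bs()
  set.seed(1)
  tab <- data.frame(x = rnorm(40), y = rnorm(40))
  fit <- run_chain(tab, bs, iterations = 1200, burn_in = 200, thin = 2,
                   seed = 2)
  expect_identical(fit$config$n_draws, 500)
  expect_identical(nrow(fit$beta$y), 500L)
  expect_error(run_chain(tab, bs, iterations = 100, burn_in = 100,
                         thin = 1, seed = 1), "exceed")
  expect_error(run_chain(tab, bs, iterations = 100, burn_in = 10,
                         thin = 1), "seed")
})

test_that("the same seed reproduces the chain bit for bit", {
  spec <- nfbc_like_spec(n = 150)
  sim <- simulate_cohort(spec, seed = 3)
  masked <- apply_missingness(sim$data, spec, seed = 4)$table
  f1 <- run_chain(masked, spec$bs, iterations = 80, burn_in = 30,
                  thin = 1, seed = 77)
  f2 <- run_chain(masked, spec$bs, iterations = 80, burn_in = 30,
                  thin = 1, seed = 77)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$imputed, f2$imputed)
})

test_that("gibbs_step is a deterministic function of state and RNG", {
  spec <- nfbc_like_spec(n = 100)
  sim <- simulate_cohort(spec, seed = 6)
  set.seed(1); st <- sem_init(sim$data, spec$bs)
  set.seed(42); s1 <- gibbs_step(st)
  set.seed(42); s2 <- gibbs_step(st)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$X, s2$X)
})

test_that("every stored draw satisfies the parameter invariants", {
  out <- small_preset_fit()
  fit <- out$fit
  for (k in names(fit$candidates)) {
    expect_true(all(fit$beta[[k]][fit$gamma[[k]] == 0L] == 0))
    fmask <- fit$candidates[[k]]$forced
    if (any(fmask))
      expect_true(all(fit$gamma[[k]][, fmask] == 1L))
  }
  expect_true(all(fit$sigma2 > 0))
  expect_true(all(fit$pi > 0 & fit$pi < 1))
})

test_that("MPPI equals an independent recount of the stored indicators", {
  out <- small_preset_fit()
  fit <- out$fit
  m <- compute_mppi(fit)
  for (i in sample.int(nrow(m), 10)) {
    g <- fit$gamma[[m$response[i]]][, m$candidate[i]]
    expect_equal(m$mppi[i], sum(g == 1L) / length(g))
  }
  expect_true(all(m$mppi >= 0 & m$mppi <= 1))
  expect_true(all(m$mppi[m$forced] == 1))
})

test_that("candidate ordering does not change the inference", {
  # same generative data, exogenous variables declared in reverse order
  mkbs <- function(rev) {
    exo <- c("x1", "x2", "x3")
    if (rev) exo <- rev(exo)
    block_structure(
      list(list(name = "b1", endogenous = character(), exogenous = exo),
           list(name = "b2", endogenous = "y", exogenous = character())),
      list(x1 = list(type = "continuous"), x2 = list(type = "continuous"),
           x3 = list(type = "continuous"), y = list(type = "continuous")))
  }
  set.seed(12)
  n <- 400
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tab$y <- 0.5 * tab$x1 + rnorm(n)
  f1 <- run_chain(tab, mkbs(FALSE), iterations = 400, burn_in = 150,
                  thin = 1, seed = 5)
  f2 <- run_chain(tab, mkbs(TRUE), iterations = 400, burn_in = 150,
                  thin = 1, seed = 6)
  m1 <- compute_mppi(f1); m2 <- compute_mppi(f2)
  key <- function(m) setNames(m$mppi, m$candidate)
  k1 <- key(m1); k2 <- key(m2)[names(key(m1))]
  expect_true(all(abs(k1 - k2) < 0.15))
  b1 <- mean(f1$beta$y[, "x1"]); b2 <- mean(f2$beta$y[, "x1"])
  expect_lt(abs(b1 - b2), 0.1)
})
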