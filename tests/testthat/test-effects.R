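test_that("thresholding keeps exactly the qualifying edges", {
  mp <- data.frame(response = c("y", "y"), candidate = c("a", "b"),
                   mppi = c(0.9, 0.4), forced = c(FALSE, FALSE),
                   beta_mean = c(0.5, 0.1), stringsAsFactors = FALSE)
  dag <- threshold_dag(mp, tau = 0.5)
  expect_identical(dag$edges$from, "a")
  expect_identical(dag$edges$to, "y")
  expect_error(threshold_dag(mp, tau = 0), "probability")
  expect_error(threshold_dag(mp, tau = 1.2), "probability")
})

test_that("raising the threshold never adds edges", {
  out <- small_preset_fit()
  mp <- compute_mppi(out$fit)
  prev <- NULL
  for (tau in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    dag <- threshold_dag(mp, tau = tau)
    keys <- paste(dag$edges$from, dag$edges$to)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  # tau = 1 keeps only edges present in every draw
  dag1 <- threshold_dag(mp, tau = 1)
  for (i in seq_len(nrow(dag1$edges))) {
    g <- out$fit$gamma[[dag1$edges$to[i]]][, dag1$edges$from[i]]
    expect_true(all(g == 1L))
  }
})

test_that("path enumeration is exhaustive, ordered and edge-sensitive", {
  dag <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                       mppi = 1, beta_mean = 0.1,
                       stringsAsFactors = FALSE),
    tau = 0.5, run_seed = NULL), class = "blsem_dag")
  paths <- enumerate_paths(dag, "a", "c")
  expect_length(paths, 2L)
  expect_identical(paths[[1]], c("a", "b", "c"))  # lexicographic order
  expect_identical(paths[[2]], c("a", "c"))
  expect_error(enumerate_paths(dag, "a", "z"), "unknown node")
  expect_error(enumerate_paths(dag, "a", "a"), "differ")

  # removing the outcome's only incoming edges leaves no paths
  dag$edges <- dag$edges[dag$edges$to != "c", , drop = FALSE]
  expect_length(enumerate_paths(dag, "a", "c"), 0L)
})

test_that("path counts match the adjacency-power oracle on layered DAGs", {
  dag <- structure(list(
    nodes = c("s", "a1", "a2", "b1", "b2", "t"),
    edges = expand.grid(from = c("s"), to = c("a1", "a2"),
                        stringsAsFactors = FALSE),
    tau = 0.5, run_seed = NULL), class = "blsem_dag")
  e <- rbind(
    expand.grid(from = "s", to = c("a1", "a2"), stringsAsFactors = FALSE),
    expand.grid(from = c("a1", "a2"), to = c("b1", "b2"),
                stringsAsFactors = FALSE),
    expand.grid(from = c("b1", "b2"), to = "t", stringsAsFactors = FALSE))
  e$mppi <- 1; e$beta_mean <- 0.1
  dag$edges <- e
  expect_identical(length(enumerate_paths(dag, "s", "t")),
                   as.integer(matrix_power_path_count(dag, "s", "t")))
})

test_that("constant-draw chains obey the product and sum rules", {
  ch <- const_chain(data.frame(from = c("x", "m"), to = c("m", "y"),
                               beta = c(0.5, 0.4)))
  dag <- threshold_dag(compute_mppi(ch), tau = 0.5)
  eff <- effect_decomposition(ch, dag, "x", "y")
  expect_equal(unname(eff$direct["mean"]), 0)
  expect_equal(unname(eff$indirect["mean"]), 0.2)
  expect_equal(unname(eff$total["mean"]), 0.2)
  expect_identical(eff$n_paths, 1L)
})

test_that("per-draw additivity holds to machine precision on a fit", {
  out <- small_preset_fit()
  fit <- out$fit
  dag <- threshold_dag(fit, tau = 0.5)
  pairs <- list(c("matBMI", "bmi46"), c("matSmoke", "bmi46"),
                c("bw", "bmi31"), c("bmiAP", "bmi14"))
  for (pr in pairs) {
    eff <- effect_decomposition(fit, dag, pr[1], pr[2])
    # independent recomputation of the total from raw draws
    paths <- enumerate_paths(dag, pr[1], pr[2])
    nd <- fit$config$n_draws
    direct <- tryCatch({
      e <- fit$candidates[[pr[2]]]
      fit$beta[[pr[2]]][, match(pr[1], e$candidates)]
    }, error = function(e) rep(0, nd))
    if (anyNA(direct)) direct <- rep(0, nd)
    tot <- direct
    for (p in paths) {
      if (length(p) == 2L) next
      prod <- rep(1, nd)
      for (i in seq_len(length(p) - 1L))
        prod <- prod * fit$beta[[p[i + 1L]]][, p[i]]
      tot <- tot + prod
    }
    expect_equal(eff$draws$total, tot, tolerance = 1e-14)
    expect_equal(eff$draws$total, eff$draws$direct + eff$draws$indirect,
                 tolerance = 1e-14)
  }
})

test_that("destandardisation applies the SD-ratio conversions", {
  ch <- const_chain(data.frame(from = "x", to = "y", beta = 0.5))
  dag <- threshold_dag(compute_mppi(ch), tau = 0.5)
  eff <- effect_decomposition(ch, dag, "x", "y")
  sc <- data.frame(column = c("x", "y"), center = c(0, 0),
                   scale = c(4, 2), scaled = c(TRUE, TRUE),
                   stringsAsFactors = FALSE)
  class(sc) <- c("blsem_scale", "data.frame")
  d <- destandardize(eff, sc)
  expect_equal(unname(d$original_scale$per_unit$total["mean"]), 0.25)
  expect_equal(unname(d$original_scale$per_sd$total["mean"]), 1.0)
  # identity scales change nothing
  sc$scale <- c(1, 1)
  d2 <- destandardize(eff, sc)
  expect_equal(d2$original_scale$per_unit$total, eff$total)
  sc2 <- sc[1, , drop = FALSE]
  expect_error(destandardize(eff, sc2), "no scale")
})

test_that("subgraphs carry exactly the pathway union", {
  out <- small_preset_fit()
  dag <- threshold_dag(out$fit, tau = 0.5)
  sg <- subgraph(dag, "matBMI", "bmi46")
  expect_identical(length(enumerate_paths(sg, "matBMI", "bmi46")),
                   length(enumerate_paths(dag, "matBMI", "bmi46")))
  # every subgraph edge lies on some path
  paths <- enumerate_paths(dag, "matBMI", "bmi46")
  onpath <- unique(unlist(lapply(paths, function(p)
    paste(p[-length(p)], p[-1]))))
  expect_setequal(paste(sg$edges$from, sg$edges$to), onpath)
  # a pair with no connecting path yields an empty subgraph
  sg0 <- subgraph(dag, "matAge", "bw")
  if (!length(enumerate_paths(dag, "matAge", "bw")))
    expect_identical(nrow(sg0$edges), 0L)
})

test_that("DAG exports are readable and carry edge attributes", {
  out <- small_preset_fit()
  dag <- threshold_dag(out$fit, tau = 0.5)
  fg <- tempfile(fileext = ".graphml")
  export_dag(dag, fg, "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_identical(as.integer(igraph::ecount(g)),
                   as.integer(nrow(dag$edges)))
  expect_true("mppi" %in% igraph::edge_attr_names(g))
  fd <- tempfile(fileext = ".dot")
  export_dag(dag, fd, "dot")
  txt <- readLines(fd)
  expect_identical(sum(grepl("->", txt, fixed = TRUE)),
                   as.integer(nrow(dag$edges)))
  unlink(c(fg, fd))
})
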