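test_that("a minimal two-block config yields the single forward edge", {
  bs <- two_block_bs()
  ce <- candidate_edges(bs)
  expect_length(ce, 1L)
  expect_identical(ce$y$candidates, "x")
  expect_false(any(ce$y$forced))
})

test_that("YAML and JSON configs round-trip to an identical structure", {
  bs <- nfbc_like_blocks()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_block_config(bs, f)
    bs2 <- load_block_config(f)
    expect_identical(bs2$blocks, bs$blocks)
    expect_identical(bs2$variables, bs$variables)
    expect_identical(bs2$columns, bs$columns)
    unlink(f)
  }
})

test_that("the shipped example config parses", {
  f <- system.file("extdata", "example_blocks.yaml", package = "blsem")
  bs <- load_block_config(f)
  expect_identical(bs$Q, 3L)
  expect_true(bs$variables$sex$role == "forced")
  ce <- candidate_edges(bs)
  expect_identical(ce$bmi46$candidates,
                   c("sex", "bw", "matBMI", "matSmoke", "bmiAR", "sep46"))
})

test_that("config validation rejects forbidden structures", {
  blocks <- list(list(name = "b1", endogenous = "y", exogenous = "x"))
  expect_error(
    block_structure(blocks, list(y = list(type = "binary"),
                                 x = list(type = "continuous"))),
    "continuous outcomes")
  expect_error(
    block_structure(
      list(list(name = "b1", endogenous = character(), exogenous = "x"),
           list(name = "b2", endogenous = "x", exogenous = character())),
      list(x = list(type = "continuous"))),
    "duplicate")
  expect_error(
    block_structure(
      list(list(name = "b1", endogenous = character(), exogenous = "x"),
           list(name = "b2", endogenous = "y", exogenous = "s")),
      list(x = list(type = "continuous"), y = list(type = "continuous"),
           s = list(type = "binary", forced = TRUE))),
    "first block")
  f <- tempfile(fileext = ".yaml")
  writeLines("blocks:\n  - name: b1\n    endogenous: [y]", f)
  expect_error(load_block_config(f), "variables")
  unlink(f)
})

test_that("candidate edge counts match brute-force enumeration", {
  bs <- nfbc_like_blocks()
  ce <- candidate_edges(bs)
  cols <- bs$columns
  expect_length(ce, sum(cols$role == "endogenous"))
  for (e in ce) {
    q <- e$block
    # oracle: direct enumeration of the allowed covariate set
    expected <- cols$column[cols$forced |
                              (cols$block < q & !cols$forced) |
                              (cols$block == q & cols$role == "exogenous")]
    expect_setequal(e$candidates, expected)
    expect_false(e$response %in% e$candidates)
  }
  # the final-block response sees every earlier variable as a candidate
  final <- ce$bmi46
  earlier <- cols$column[cols$block < 6 | cols$forced |
                           (cols$block == 6 & cols$role == "exogenous")]
  expect_setequal(final$candidates, earlier)
})

test_that("candidate edges are deterministic and the graph acyclic", {
  bs <- nfbc_like_blocks()
  expect_identical(candidate_edges(bs), candidate_edges(bs))
  edges <- do.call(rbind, lapply(candidate_edges(bs), function(e)
    data.frame(from = e$candidates, to = e$response)))
  g <- igraph::graph_from_data_frame(edges)
  expect_true(igraph::is_dag(g))
})

test_that("data validation reports missingness and type violations", {
  bs <- two_block_bs()
  tab <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 0, -1, 3))
  rep0 <- validate_data(bs, tab)
  expect_true(rep0$ok)
  expect_identical(nrow(rep0$issues), 0L)

  tab$x[1:2] <- NA  # not a round fraction of 5? use 30% on 10 rows below
  tab10 <- data.frame(x = c(rnorm(7), NA, NA, NA), y = rnorm(10))
  rep1 <- validate_data(bs, tab10)
  expect_equal(unname(rep1$missing_frac["x"]), 0.30)

  bsb <- block_structure(
    list(list(name = "b1", endogenous = character(), exogenous = "b"),
         list(name = "b2", endogenous = "y", exogenous = character())),
    list(b = list(type = "binary"), y = list(type = "continuous")))
  bad <- data.frame(b = c(0, 1, 2), y = rnorm(3))
  repb <- validate_data(bsb, bad)
  expect_false(repb$ok)
  expect_true(any(repb$issues$issue == "type_violation" &
                    repb$issues$variable == "b"))

  expect_error(validate_data(bs, data.frame(x = 1:3)), "lacks")
  chr <- data.frame(x = c("1", "oops", "3"), y = rnorm(3),
                    stringsAsFactors = FALSE)
  expect_error(validate_data(bs, chr), "row 2")
  expect_error(validate_data(bs, data.frame(x = c(NA, NA, NA),
                                            y = rnorm(3))),
               "wholly missing")
})

test_that("categorical expansion produces reference-coded indicators", {
  bs <- nfbc_like_blocks()
  sim <- simulate_cohort(nfbc_like_spec(n = 50, missingness = FALSE),
                         seed = 5)
  m <- expand_categoricals(bs, sim$data)
  expect_identical(names(m), bs$columns$column)
  expect_true(all(c("town.town", "town.village") %in% names(m)))
  expect_false("town" %in% names(m))
  # reference level city = both indicators zero
  city <- sim$data$town == "city"
  expect_true(all(m$town.town[city] == 0 & m$town.village[city] == 0))
  expect_true(all(m$town.town + m$town.village <= 1))
})
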