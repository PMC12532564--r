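# Shared fixtures: tiny block structures, a hand-built chain with constant
# draws for effect-algebra tests, and a memoised small preset fit reused
# across test files.

two_block_bs <- function() {
  block_structure(
    blocks = list(
      list(name = "b1", endogenous = character(), exogenous = "x"),
      list(name = "b2", endogenous = "y", exogenous = character())),
    variables = list(x = list(type = "continuous"),
                     y = list(type = "continuous")))
}

# x (exogenous) -> m -> y with a direct x -> y edge; unit-variance design
mediation_spec <- function(b_xm = 0.4, b_my = 0.5, b_xy = 0.3, n = 300) {
  bs <- block_structure(
    blocks = list(
      list(name = "b1", endogenous = character(), exogenous = "x"),
      list(name = "b2", endogenous = "m", exogenous = character()),
      list(name = "b3", endogenous = "y", exogenous = character())),
    variables = list(x = list(type = "continuous"),
                     m = list(type = "continuous"),
                     y = list(type = "continuous")))
  generator_spec(bs, data.frame(
    from = c("x", "m", "x"), to = c("m", "y", "y"),
    beta = c(b_xm, b_my, b_xy), stringsAsFactors = FALSE), n = n)
}

# Minimal blsem_chain whose coefficient draws are constant, for exact
# effect-algebra checks. `edges` is a data.frame(from, to, beta); every
# (from, to) pair becomes a candidate with gamma == 1 in all draws.
const_chain <- function(edges, n_draws = 10) {
  responses <- unique(edges$to)
  # responses may depend on other responses; put sources first
  nodes <- unique(c(edges$from, edges$to))
  candidates <- list()
  beta <- list(); gamma <- list()
  for (k in responses) {
    ek <- edges[edges$to == k, , drop = FALSE]
    candidates[[k]] <- list(response = k, block = NA_integer_,
                            candidates = ek$from,
                            forced = rep(FALSE, nrow(ek)))
    beta[[k]] <- matrix(rep(ek$beta, each = n_draws), n_draws,
                        nrow(ek), dimnames = list(NULL, ek$from))
    gamma[[k]] <- matrix(1L, n_draws, nrow(ek),
                         dimnames = list(NULL, ek$from))
  }
  class(candidates) <- "blsem_candidates"
  K <- length(responses)
  m <- matrix(0, n_draws, K, dimnames = list(NULL, responses))
  structure(list(
    bs = NULL, scale = NULL, candidates = candidates,
    beta = beta, gamma = gamma, alpha = m, sigma2 = m + 1, pi = m + 0.5,
    r2 = m, imputed = NULL, missing_cells = NULL, observed = NULL,
    n = 0L, n_dropped = 0L, ridge_count = 0L,
    config = list(iterations = n_draws, burn_in = 0L, thin = 1L,
                  seed = 0L, n_draws = n_draws)
  ), class = "blsem_chain")
}

# one small fitted preset chain (no missingness) shared across tests
.fit_cache <- new.env(parent = emptyenv())

small_preset_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    spec <- nfbc_like_spec(n = 500, missingness = FALSE)
    sim <- simulate_cohort(spec, seed = 101)
    .fit_cache$spec <- spec
    .fit_cache$sim <- sim
    .fit_cache$fit <- run_chain(sim$data, spec$bs, iterations = 400,
                                burn_in = 150, thin = 1, seed = 11)
  }
  list(spec = .fit_cache$spec, sim = .fit_cache$sim, fit = .fit_cache$fit)
}

# adjacency-matrix-power path-count oracle for DAGs
matrix_power_path_count <- function(dag, from, to) {
  nodes <- dag$nodes
  p <- length(nodes)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(dag$edges))
    A[cbind(match(dag$edges$from, nodes), match(dag$edges$to, nodes))] <- 1
  fi <- match(from, nodes); ti <- match(to, nodes)
  total <- 0
  P <- diag(p)
  for (l in seq_len(p)) {
    P <- P %*% A
    total <- total + P[fi, ti]
  }
  total
}

# random layered DAG (<= max_nodes nodes) as a blsem_dag
random_layered_dag <- function(max_nodes = 12) {
  n_layers <- sample(2:4, 1)
  sizes <- pmax(1, sample(1:3, n_layers, replace = TRUE))
  while (sum(sizes) > max_nodes) sizes[which.max(sizes)] <-
      sizes[which.max(sizes)] - 1L
  nodes <- character(); layer <- integer()
  for (l in seq_len(n_layers)) {
    nodes <- c(nodes, paste0("n", l, "_", seq_len(sizes[l])))
    layer <- c(layer, rep(l, sizes[l]))
  }
  from <- character(); to <- character()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (layer[j] > layer[i] && runif(1) < 0.6) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
    }
  }
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from, to = to,
                       mppi = rep(1, length(from)),
                       beta_mean = rep(0.1, length(from)),
                       stringsAsFactors = FALSE),
    tau = 0.5, run_seed = NULL), class = "blsem_dag")
}
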