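# Independent oracles used to check the package's algorithms.  These are
# deliberately naive (path enumeration, dynamic programming over phases)
# and share no code with the implementation under test.

# Posterior marginals by brute-force enumeration of all S^m hidden paths.
# E: m x S emission matrix; trans: list (length m-1) of S x S transition
# matrices; init: length-S initial distribution.
fb_bruteforce <- function(E, trans, init) {
  m <- nrow(E)
  S <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  w <- init[paths[, 1]] * E[1, ][paths[, 1]]
  if (m > 1) {
    for (t in 2:m) {
      w <- w * trans[[t - 1]][cbind(paths[, t - 1], paths[, t])] *
        E[t, ][paths[, t]]
    }
  }
  post <- matrix(0, m, S)
  for (t in seq_len(m))
    post[t, ] <- vapply(seq_len(S), function(s) sum(w[paths[, t] == s]), 0)
  post / sum(w)
}

# Minimum number of switches consistent with a sequence of unordered
# founder-pair calls, by dynamic programming over ordered phase
# assignments (cost between ordered pairs = number of haplotypes that
# change label).
min_switches_dp <- function(pairs) {
  # pairs: list of c(j, k) unordered calls, NA entries already removed
  if (length(pairs) < 2) return(0L)
  ordered <- function(p) if (p[1] == p[2]) list(p) else list(p, rev(p))
  prev <- ordered(pairs[[1]])
  cost <- rep(0L, length(prev))
  for (i in 2:length(pairs)) {
    cur <- ordered(pairs[[i]])
    newcost <- vapply(cur, function(o) {
      min(vapply(seq_along(prev), function(pi)
        cost[pi] + sum(o != prev[[pi]]), integer(1)))
    }, integer(1))
    prev <- cur
    cost <- newcost
  }
  min(cost)
}

# quick random genotype matrix (markers x samples) with dimnames
rand_geno <- function(n_mark, n_samp, miss = 0, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_mark * n_samp, replace = TRUE), n_mark, n_samp,
              dimnames = list(sprintf("m%03d", seq_len(n_mark)),
                              sprintf("s%02d", seq_len(n_samp))))
  if (miss > 0) g[matrix(runif(length(g)) < miss, n_mark)] <- NA_integer_
  g
}

# full-size default dataset and pipeline, built once and shared across
# test files (the heavyweight fixture behind the round-trip checks)
.fixture_cache <- new.env()
default_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_dataset(sim_config(seed = seed))
  .fixture_cache[[key]]
}
default_pipeline <- function(seed = 1) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_pipeline(default_sim(seed)$data,
                                          run_impact = TRUE)
  .fixture_cache[[key]]
}

# small simulated dataset shared across diagnostic tests
small_sim <- function(seed = 11, ...) {
  make_dataset(sim_config(n_chr = 3, markers_per_chr = 120,
                          groups = data.frame(generation = 8, n = 12),
                          bad_samples = list(), n_bad_markers = 0,
                          n_duplicate_pairs = 0, n_xo = 0,
                          n_sex_mislabel = 0, seed = seed, ...))
}
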