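# Diplotype HMM: transitions, emissions, forward-backward exactness,
# collapse to SNP genotypes, calls, and error LOD scores.

params8 <- hmm_params(n_gen_eff = do_gen_eff(8))

test_that("transition matrices are stochastic with the uniform stationary law", {
  for (d in c(0, 0.01, 0.5, 1, 5, 20)) {
    Tm <- transition_matrix(d, params8)
    expect_equal(rowSums(Tm), rep(1, 36), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(Tm >= 0))
    # stationary distribution: 1/64 per ordered pair
    pi0 <- dip_stationary()
    expect_equal(as.numeric(pi0 %*% Tm), pi0, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # zero distance (after the r floor) is essentially the identity
  expect_lt(max(abs(transition_matrix(0, params8) - diag(36))), 1e-5)
  # longer intervals mix more: diagonal decreases with d
  dg <- vapply(c(0.1, 1, 5, 20, 80), function(d)
    min(diag(transition_matrix(d, params8))), 0)
  expect_true(all(diff(dg) < 0))
})

test_that("transition matrix equals the two-haplotype kernel product", {
  # independent construction: 64x64 ordered-pair kronecker product,
  # collapsed onto unordered states
  d <- 2.5
  ng <- 9
  r <- cf_forward(d)
  p_sw <- 1 - exp(-(8 / 7) * ng * (100 * r) / 100)
  P1 <- matrix(p_sw / 8, 8, 8); diag(P1) <- 1 - p_sw + p_sw / 8
  P64 <- kronecker(P1, P1)  # ordered pairs (a,b), index (a-1)*8+b
  st <- dip_states()
  T36 <- matrix(0, 36, 36)
  for (s in 1:36) {
    from <- (st$hap1[s] - 1) * 8 + st$hap2[s]
    for (t in 1:36) {
      to1 <- (st$hap1[t] - 1) * 8 + st$hap2[t]
      to2 <- (st$hap2[t] - 1) * 8 + st$hap1[t]
      T36[s, t] <- P64[from, to1] + if (to1 != to2) P64[from, to2] else 0
    }
  }
  expect_equal(unname(transition_matrix(d, hmm_params(n_gen_eff = ng))), T36,
               tolerance = 1e-12)
})

test_that("emissions implement the symmetric error model", {
  fc <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)  # founders B,D,F,H carry allele B
  e <- emission_probs(NA, fc)
  expect_equal(e, rep(1, 36))
  st <- dip_states()
  e_ab <- emission_probs(1L, fc, epsilon = 0.002)
  ab_states <- (fc[st$hap1] + fc[st$hap2]) == 1L
  expect_equal(unique(e_ab[ab_states]), 0.998)
  expect_equal(unique(e_ab[!ab_states]), 0.001)
  # a missing founder call makes its states uninformative
  fc2 <- fc; fc2[3] <- NA
  e2 <- emission_probs(0L, fc2)
  involves3 <- st$hap1 == 3 | st$hap2 == 3
  expect_equal(e2[involves3], rep(1, sum(involves3)))
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(42)
  for (m in 2:4) {
    pos <- cumsum(c(0, runif(m - 1, 0.5, 4)))
    fnd <- matrix(sample(0:1, m * 8, replace = TRUE), m, 8,
                  dimnames = list(sprintf("m%d", 1:m), LETTERS[1:8]))
    obs <- sample(c(0:2, NA), m, replace = TRUE)
    E <- do.call(rbind, lapply(seq_len(m), function(i)
      emission_probs(obs[i], fnd[i, ], 0.002)))
    trans <- lapply(diff(pos), transition_matrix, params = params8)
    init <- dip_stationary()
    map <- data.frame(marker = rownames(fnd), chr = "1", pos = pos)
    geno <- matrix(obs, m, 1, dimnames = list(rownames(fnd), "s1"))
    covar <- data.frame(id = "s1", sex = "F", generation = 8)
    data <- do_data(geno, fnd, map, covar)
    pr <- calc_diplotype_probs(data, params8, markers = rownames(fnd))
    expected <- fb_bruteforce(E, trans, init)
    expect_equal(unname(pr[["1"]][, , 1]), expected, tolerance = 1e-10)
  }
})

test_that("an uninformative chromosome returns the stationary distribution", {
  fnd <- matrix(rep(c(0L, 1L), each = 4 * 3), 3, 8,
                dimnames = list(c("m1", "m2", "m3"), LETTERS[1:8]))
  map <- data.frame(marker = rownames(fnd), chr = "1", pos = c(0, 1, 2))
  geno <- matrix(NA_integer_, 3, 1, dimnames = list(rownames(fnd), "s1"))
  data <- do_data(geno, fnd, map,
                  data.frame(id = "s1", sex = "F", generation = 8))
  pr <- calc_diplotype_probs(data, params8)
  for (i in 1:3)
    expect_equal(unname(pr[["1"]][i, , 1]), dip_stationary(), tolerance = 1e-12)
})

test_that("collapse to SNP probabilities conserves and distributes mass", {
  fc <- c(rep(0L, 4), rep(1L, 4))
  # uniform over ordered pairs: expect (0.25, 0.5, 0.25) at a 4/4 split
  expect_equal(collapse_to_snp_probs(dip_stationary(), fc),
               c(AA = 0.25, AB = 0.5, BB = 0.25))
  # concentrated posterior maps through the homozygote
  p <- rep(0, 36); p[dip_state_index(2, 2)] <- 1
  expect_equal(collapse_to_snp_probs(p, fc), c(AA = 1, AB = 0, BB = 0))
  # random posteriors: mass conserved
  set.seed(1)
  for (i in 1:20) {
    p <- runif(36); p <- p / sum(p)
    expect_equal(sum(collapse_to_snp_probs(p, fc)), 1, tolerance = 1e-9)
  }
  # incomplete founders: flagged as NA
  expect_true(all(is.na(collapse_to_snp_probs(dip_stationary(),
                                              c(fc[-8], NA)))))
})

test_that("max-marginal calls require a strict majority", {
  arr <- array(0, c(3, 36, 1), dimnames = list(paste0("m", 1:3), NULL, "s1"))
  arr[1, , 1] <- c(0.9, 0.1, rep(0, 34))
  arr[2, , 1] <- c(0.4, 0.35, 0.25, rep(0, 33))
  arr[3, , 1] <- c(0.5, 0.5, rep(0, 34))   # exactly 0.5 is not enough
  calls <- call_max_marginal(structure(list(`1` = arr),
                                       class = "diplotype_probs"))
  expect_equal(unname(calls[["1"]][, 1]), c(1L, NA, NA))
})

test_that("predicted genotypes follow calls through the founder alleles", {
  fnd <- rbind(m1 = c(0L, 1L, rep(0L, 6)),
               m2 = c(1L, 1L, rep(0L, 6)),
               m3 = c(0L, NA, rep(0L, 6)))
  cm <- matrix(c(dip_state_index(1, 2), NA, dip_state_index(1, 2)), 3, 1,
               dimnames = list(rownames(fnd), "s1"))
  pred <- predicted_snp_genotypes(list(`1` = cm), fnd)
  # AB call; missing call -> NA; founder gap -> NA
  expect_equal(unname(pred[, 1]), c(1L, NA, NA))
  cm2 <- matrix(dip_state_index(1, 2), 1, 1, dimnames = list("m2", "s1"))
  expect_equal(unname(predicted_snp_genotypes(list(`1` = cm2), fnd)[, 1]), 2L)
})

test_that("error LOD matches direct arithmetic and flags at the usual cut", {
  # q = 0.5 at epsilon 0.002: log10(499) = 2.698
  expect_equal(genotyping_error_lod(c(AA = 0.5, AB = 0.25, BB = 0.25), "AA"),
               2.69810054562339, tolerance = 1e-10)
  expect_equal(genotyping_error_lod(c(AA = 0.999, AB = 5e-4, BB = 5e-4), "AA"),
               -0.301464942602592, tolerance = 1e-10)
  # monotone decreasing in q
  q <- seq(0.05, 0.95, by = 0.05)
  lods <- vapply(q, function(qi)
    genotyping_error_lod(c(AA = qi, AB = (1 - qi) / 2, BB = (1 - qi) / 2), 0L), 0)
  expect_true(all(diff(lods) < 0))
  # q = 0 capped at the ceiling; missing observation unscored
  expect_equal(genotyping_error_lod(c(AA = 0, AB = 1, BB = 0), "AA"), 12)
  expect_true(is.na(genotyping_error_lod(c(AA = 1, AB = 0, BB = 0), NA)))
  # the LOD > 2 rule corresponds to q below ~0.833
  expect_gt(genotyping_error_lod(c(AA = 0.8, AB = 0.1, BB = 0.1), "AA"), 2)
  expect_lt(genotyping_error_lod(c(AA = 0.9, AB = 0.05, BB = 0.05), "AA"), 2)
})

test_that("posterior change metric is the L1 distance on [0, 2]", {
  p <- rep(0, 36); p[1] <- 1
  expect_equal(posterior_abs_diff(p, p), 0)
  q <- rep(0, 36); q[2] <- 1
  expect_equal(posterior_abs_diff(p, q), 2)  # disjoint support
  h <- rep(0, 36); h[1] <- 0.5; h[2] <- 0.5
  expect_equal(posterior_abs_diff(p, h), 1)  # half the mass moved
  # array form sums over the state dimension
  a1 <- array(rep(p, 2), c(1, 36, 2))
  a2 <- array(rep(q, 2), c(1, 36, 2))
  expect_equal(unname(posterior_abs_diff(a1, a2)), matrix(2, 1, 2))
})

test_that("per-sample densities separate outbreeding generations", {
  # the default dataset mixes generation-8 and generation-11 groups with
  # their calibrated switch densities; recovered genome-wide crossover
  # counts must separate in the simulated direction over the 60 samples
  sim <- default_sim()
  bundle <- default_pipeline()
  xo <- bundle$sample_report$n_crossovers
  gen <- bundle$sample_report$generation
  keep <- bundle$sample_report$retained
  xo8 <- xo[keep & gen == 8]
  xo11 <- xo[keep & gen == 11]
  expect_gt(mean(xo11), mean(xo8))
  expect_lt(stats::t.test(xo11, xo8, alternative = "greater")$p.value, 0.01)
})
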