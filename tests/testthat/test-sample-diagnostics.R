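# Sample-level diagnostics: missingness, sex checks, duplicates,
# intensity profiles, genotype frequencies, crossover counting, and
# error rates.

test_that("percent missing by sample follows the omission thresholds", {
  g <- rand_geno(100, 3)
  g[1:20, 2] <- NA    # exactly 20% -> omit at the default cutoff
  g[, 3] <- NA
  pm <- percent_missing_by_sample(g)
  expect_equal(unname(pm), c(0, 20, 100))
  th <- qc_thresholds()
  expect_equal(pm >= 100 * th$sample_missing_omit,
               c(s01 = FALSE, s02 = TRUE, s03 = TRUE))
  # restricting to an informative subset changes the denominator
  pm2 <- percent_missing_by_sample(g, markers = rownames(g)[1:20])
  expect_equal(unname(pm2), c(0, 100, 100))
})

test_that("sex classes are inferred from X/Y intensity quadrants", {
  mk <- c(paste0("x", 1:5), paste0("y", 1:3))
  samples <- c("f1", "m1", "xo1", "xxy1", "mis1")
  base <- rbind(matrix(c(0.52, 0.24, 0.22, 0.50, 0.54), 5, 5, byrow = TRUE),
                matrix(c(0.08, 0.55, 0.08, 0.52, 0.07), 3, 5, byrow = TRUE))
  dimnames(base) <- list(mk, samples)
  sx <- sex_check(base, base, x_markers = paste0("x", 1:5),
                  y_markers = paste0("y", 1:3),
                  nominal_sex = c("F", "M", "F", "M", "M"),
                  thresholds = c(0.35, 0.30))
  expect_equal(sx$inferred_sex, c("XX", "XY", "XO", "XXY", "XX"))
  # the nominal male inside the female cluster is the mismatch
  expect_equal(sx$sample[sx$sex_mismatch], "mis1")
})

test_that("sex thresholds default to nominal-group median midpoints", {
  sim <- small_sim(seed = 31, n_x_markers = 60, n_y_markers = 20)
  d <- sim$data
  xm <- d$map$marker[d$map$chr == "X"]
  ym <- d$map$marker[d$map$chr == "Y"]
  sx <- sex_check(d$int_x, d$int_y, xm, ym, d$covar$sex)
  truth <- sim$truth$true_sex[sx$sample]
  expect_equal(sx$inferred_sex, unname(truth))
  expect_false(any(sx$sex_mismatch))
})

test_that("engineered sex anomalies are recovered with zero misclassification", {
  sim <- make_dataset(sim_config(
    n_chr = 2, markers_per_chr = 60,
    groups = data.frame(generation = 8, n = 16),
    bad_samples = list(), n_bad_markers = 0, n_duplicate_pairs = 0,
    n_xo = 2, n_sex_mislabel = 1, n_xxy = 2, seed = 77))
  d <- sim$data
  sx <- sex_check(d$int_x, d$int_y,
                  d$map$marker[d$map$chr == "X"],
                  d$map$marker[d$map$chr == "Y"], d$covar$sex)
  expect_equal(sx$inferred_sex, unname(sim$truth$true_sex[sx$sample]))
  expect_equal(sort(sx$sample[sx$sex_mismatch]),
               sort(sim$truth$special$sex_mislabel))
  # X heterozygosity separates XX from hemizygous classes (a rare
  # genotyping error can put a stray het call in a hemizygous sample)
  hx <- x_heterozygosity(d$geno, d$map$marker[d$map$chr == "X"])
  expect_true(all(hx[sim$truth$true_sex %in% c("XY", "XO")] < 0.05))
  expect_true(all(hx[sim$truth$true_sex %in% c("XX", "XXY")] > 0.1))
})

test_that("pairwise matching counts shared non-missing calls", {
  g <- rbind(m1 = c(0L, 0L), m2 = c(1L, 2L), m3 = c(2L, 2L),
             m4 = c(NA, 0L))
  colnames(g) <- c("a", "b")
  mt <- pairwise_match(g, min_shared = 2)
  expect_equal(nrow(mt), 1)   # self-pairs excluded
  expect_equal(mt$n_shared, 3L)
  expect_equal(mt$prop_match, 2 / 3)
  expect_true(mt$scored)
  # under-shared pairs are reported but unscored
  mt2 <- pairwise_match(g, min_shared = 10)
  expect_false(mt2$scored)
  expect_error(pairwise_match(g[, 1, drop = FALSE]), "two samples")
})

test_that("duplicates are flagged above the sharing threshold, siblings are not", {
  mt <- data.frame(sample1 = c("a", "a", "b"), sample2 = c("b", "c", "c"),
                   n_shared = 5000L, prop_match = c(0.999, 0.671, 0.46),
                   scored = TRUE, stringsAsFactors = FALSE)
  fl <- flag_duplicates(mt)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$recommend_omit, "b")
  # empty input stays empty
  expect_equal(nrow(flag_duplicates(mt[0, ])), 0)
  # high-missing samples are excluded before flagging
  fl2 <- flag_duplicates(mt, pct_missing = c(a = 1, b = 25, c = 1))
  expect_equal(nrow(fl2), 0)
})

test_that("simulated duplicate pairs match almost perfectly, others do not", {
  sim <- make_dataset(sim_config(
    n_chr = 3, markers_per_chr = 150,
    groups = data.frame(generation = 8, n = 14),
    bad_samples = list(), n_bad_markers = 0, n_duplicate_pairs = 1,
    n_xo = 0, n_sex_mislabel = 0, n_x_markers = 0, n_y_markers = 0,
    seed = 13))
  info <- filter_informative(sim$data$founders)
  mt <- pairwise_match(sim$data$geno[info, ], min_shared = 100)
  dup <- mt$sample1 == "S001" & mt$sample2 == "S002"
  expect_gt(mt$prop_match[dup], 0.99)   # two independent 0.2% error passes
  expect_lt(max(mt$prop_match[!dup]), 0.9)
  fl <- flag_duplicates(mt)
  expect_equal(fl$sample2, "S002")
})

test_that("intensity profiles use log10(x+1) with interpolated percentiles", {
  ix <- matrix(c(rep(0, 10), rep(9, 10)), 10, 2,
               dimnames = list(paste0("m", 1:10), c("a", "b")))
  pr_a <- intensity_profile(ix, ix, "a")
  expect_equal(c(pr_a$p1, pr_a$p99), c(0, 0))
  pr_b <- intensity_profile(ix, ix, "b")
  expect_equal(c(pr_b$p1, pr_b$p99), c(1, 1))  # log10(10)
  # percentiles agree with a direct sort-and-interpolate oracle
  set.seed(3)
  v <- rexp(501, 2)
  im <- matrix(v[1:500], 250, 2, dimnames = list(NULL, c("a", "b")))
  rownames(im) <- paste0("m", 1:250)
  pr <- intensity_profile(im, im, "a")
  pooled <- unname(sort(log10(c(im[, "a"], im[, "a"]) + 1)))
  n <- length(pooled)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    pooled[lo] + (h - lo) * (pooled[min(lo + 1, n)] - pooled[lo])
  }
  expect_equal(pr$p1, interp(0.01), tolerance = 1e-12)
  expect_equal(pr$p99, interp(0.99), tolerance = 1e-12)
})

test_that("genotype frequencies sit near the MAF-class expectations", {
  g10 <- rand_geno(10, 2)
  exp_tab <- genotype_freq_by_maf(
    g10, simulate_founders(10, marker_ids = rownames(g10), seed = 1))$expected
  expect_equal(unname(exp_tab["4/8", ]), c(0.25, 0.5, 0.25))
  expect_equal(exp_tab[["1/8", "AB"]], 2 * (1 / 8) * (7 / 8))
  expect_equal(exp_tab[["3/8", "AB"]], 0.46875)
  # clean simulation: observed per-class frequencies track the expectation
  sim <- small_sim(seed = 41, epsilon = 0, missing_rate = 0,
                   founder_missing_rate = 0)
  auto <- sim$data$map$marker[!(sim$data$map$chr %in% c("X", "Y"))]
  gf <- genotype_freq_by_maf(sim$data$geno, sim$data$founders,
                             intersect(filter_informative(sim$data$founders),
                                       auto))
  pooled <- apply(gf$freq, c(2, 3), mean, na.rm = TRUE)
  expect_lt(max(abs(pooled - gf$expected)), 0.05)
  # mixing two samples' alleles (contamination) inflates heterozygosity
  g <- sim$data$geno
  contam <- ifelse(g[, 1] == g[, 2], g[, 1], 1L)
  g2 <- cbind(g, contam = contam)
  gf2 <- genotype_freq_by_maf(g2, sim$data$founders)
  expect_true(all(gf2$freq["contam", , "AB"] > gf$expected[, "AB"]))
})

test_that("ternary coordinates place the vertices and the centroid", {
  expect_equal(unname(ternary_coords(c(1, 0, 0))), cbind(0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(ternary_coords(c(0, 1, 0))), cbind(0.5, sqrt(3) / 2),
               ignore_attr = TRUE)
  expect_equal(unname(ternary_coords(c(0, 0, 1))), cbind(1, 0),
               ignore_attr = TRUE)
  xy <- ternary_coords(c(1, 1, 1) / 3)
  expect_equal(unname(xy[1, ]), c(0.5, sqrt(3) / 6), ignore_attr = TRUE)
})

test_that("crossover counts equal the exhaustive minimal-switch oracle", {
  st <- dip_states()
  # fixed contracts
  mk3 <- function(lbls) matrix(match(lbls, st$label), ncol = 1,
                               dimnames = list(NULL, "s"))
  expect_equal(unname(count_crossovers(mk3(c("AA", "AA", "AA")))), 0L)
  expect_equal(unname(count_crossovers(mk3(c("AA", "AB", "BB")))), 2L)
  expect_equal(unname(count_crossovers(mk3(c("AB", "CD")))), 2L)
  # missing calls are skipped (flanking distance)
  expect_equal(unname(count_crossovers(mk3(c("AA", NA, "AB")))), 1L)
  # random sequences over <= 4 founders vs the phase DP
  set.seed(7)
  for (rep in 1:300) {
    len <- sample(2:12, 1)
    hp <- matrix(sample(1:4, 2 * len, replace = TRUE), len, 2)
    states <- dip_state_index(hp[, 1], hp[, 2])
    drop <- runif(len) < 0.2
    states[drop] <- NA
    cm <- matrix(states, ncol = 1, dimnames = list(NULL, "s"))
    kept <- states[!is.na(states)]
    pairs <- lapply(kept, function(s) c(st$hap1[s], st$hap2[s]))
    expect_equal(unname(count_crossovers(cm)), min_switches_dp(pairs))
  }
})

test_that("sample error rates summarize the LOD table", {
  lt <- data.frame(sample = rep(c("a", "b"), each = 4),
                   marker = paste0("m", 1:8),
                   lod = c(3, -1, 5, 0, -2, -2, -2, -2))
  er <- sample_error_rate(lt)
  expect_equal(er$pct_errors, c(50, 0))
  er2 <- sample_error_rate(lt, samples = c("a", "b", "c"))
  expect_true(is.na(er2$pct_errors[3]))
  # near-clean simulation: median error rate is tiny
  sim <- small_sim(seed = 51, epsilon = 0, founder_missing_rate = 0,
                   n_gen_eff = 7.64)
  pr <- calc_diplotype_probs(sim$data, hmm_params(n_gen_eff = 7.64))
  sp <- snp_genotype_probs(pr, sim$data$founders)
  lod <- error_lod_table(sp, sim$data$geno)
  er3 <- sample_error_rate(lod)
  expect_lt(stats::median(er3$pct_errors), 0.1)  # < 10^-3 as a fraction
})
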