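# Simulation of DO-like genotype datasets with known truth.
#
# Each sample carries two founder-label mosaics per autosome, generated by
# the same exchangeable exponential-mosaic kernel the HMM assumes: over an
# interval of d cM the founder is redrawn uniformly from the 8 founders
# (self allowed) with probability 1 - exp(-a d/100), a = (8/7) n_gen_eff.
# Redraw-to-self keeps simulator and HMM on one shared kernel; visible
# switch expectations therefore carry a 7/8 factor.  Crossover
# interference is not simulated (the kernel is Markov); the
# Carter-Falconer map function enters only through the HMM's
# distance-to-recombination conversion at inference time.
#
# The generator can inject the anomalies the diagnostics are built to
# catch: high-missingness/high-error samples, duplicated samples,
# sex-mislabeled samples, XO and XXY samples, and clustered two-channel
# intensities with sex-chromosome dosage effects.

#' Simulation configuration
#'
#' Defaults emulate a modest DO study arm: 60 mice from outbreeding
#' generations 8 (20 mice) and 11 (40 mice), genotyped on 10 autosomes
#' with 200 markers at 1 cM spacing plus X/Y markers with two-channel
#' intensities, a 0.2% genotyping error rate, 1% missing data, founder MAF
#' classes drawn as binomial(8, 1/2) conditioned on polymorphism, and one
#' of each engineered anomaly (duplicate pair, XO female, sex mislabel,
#' plus three elevated-missingness samples, two of them above the 20%
#' omission threshold).
#'
#' @param n_chr Number of autosomes.
#' @param markers_per_chr Markers per autosome.
#' @param spacing_cM Inter-marker spacing (cM).
#' @param groups Data frame `generation`, `n` of sample group sizes.
#' @param n_gen_eff Optional switch densities per group (default
#'   [do_gen_eff()] of the generation).
#' @param maf_weights Probabilities of founder MAF classes 1/8..4/8.
#' @param founder_missing_rate Per-call missing rate in the founder
#'   genotypes (creates "incomplete" markers).
#' @param epsilon Genotyping error rate applied to sample calls.
#' @param missing_rate Per-call missing rate for ordinary samples.
#' @param bad_samples List of `list(missing, error)` specs for
#'   low-quality samples.
#' @param n_bad_markers Number of autosomal markers given a systematic
#'   cluster-swap miscall: a fraction `bad_marker_frac` of true
#'   heterozygotes is reported as the major homozygote (the
#'   variable-intensity / wrongly-assigned-cluster pattern of misbehaving
#'   array probes).
#' @param bad_marker_frac Fraction of the swapped cluster that is miscalled.
#' @param n_duplicate_pairs Number of duplicated-sample pairs.
#' @param n_xo Number of XO females (nominal F).
#' @param n_sex_mislabel Number of XX samples labeled male.
#' @param n_xxy Number of XXY males.
#' @param n_x_markers,x_length_cM,n_y_markers Sex-chromosome marker counts
#'   and X map length.
#' @param intensity Cluster parameters: `means` (3 x 2 matrix of x/y
#'   channel means for AA/AB/BB), `sd` (common channel noise), `y_mean`
#'   (Y-marker signal), `background` (absent-chromosome signal).
#' @param seed Mandatory integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_chr = 10, markers_per_chr = 200, spacing_cM = 1,
                       groups = data.frame(generation = c(8, 11), n = c(20, 40)),
                       n_gen_eff = NULL,
                       maf_weights = c(16, 56, 112, 70) / 254,
                       founder_missing_rate = 0.01,
                       epsilon = 0.002, missing_rate = 0.01,
                       bad_samples = list(list(missing = 0.55, error = 0.02),
                                          list(missing = 0.30, error = 0.02),
                                          list(missing = 0.09, error = 0.005)),
                       n_bad_markers = 10, bad_marker_frac = 0.85,
                       n_duplicate_pairs = 1, n_xo = 1, n_sex_mislabel = 1,
                       n_xxy = 0,
                       n_x_markers = 100, x_length_cM = 70, n_y_markers = 30,
                       intensity = list(
                         means = rbind(AA = c(1.0, 0.1), AB = c(0.55, 0.55),
                                       BB = c(0.1, 1.0)),
                         sd = 0.06, y_mean = 0.6, background = 0.08),
                       seed) {
  if (missing(seed)) stop("a seed is required for dataset generation")
  stopifnot(abs(sum(maf_weights) - 1) < 1e-8,
            epsilon >= 0, epsilon <= 1, missing_rate >= 0, missing_rate <= 1)
  # mosaic density calibrated to the simulated genome so genome-wide
  # crossover counts land on the observed DO scale (304 / 357 per mouse)
  map_length_M <- n_chr * (markers_per_chr - 1) * spacing_cM / 100
  if (is.null(n_gen_eff))
    n_gen_eff <- do_gen_eff(groups$generation, map_length_M)
  structure(list(n_chr = n_chr, markers_per_chr = markers_per_chr,
                 spacing_cM = spacing_cM, groups = groups,
                 n_gen_eff = n_gen_eff, maf_weights = maf_weights,
                 founder_missing_rate = founder_missing_rate,
                 epsilon = epsilon, missing_rate = missing_rate,
                 bad_samples = bad_samples,
                 n_bad_markers = n_bad_markers, bad_marker_frac = bad_marker_frac,
                 n_duplicate_pairs = n_duplicate_pairs, n_xo = n_xo,
                 n_sex_mislabel = n_sex_mislabel, n_xxy = n_xxy,
                 n_x_markers = n_x_markers, x_length_cM = x_length_cM,
                 n_y_markers = n_y_markers, intensity = intensity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate founder strain genotypes
#'
#' Each marker is assigned a MAF class by the weights and the minor allele
#' (B) is given to a uniformly chosen founder subset of that size, so
#' every marker is polymorphic before missingness is applied.
#'
#' @param n_markers Number of markers.
#' @param maf_weights Probabilities of classes 1/8..4/8.
#' @param missing_rate Per-call missing rate.
#' @param marker_ids Optional marker names.
#' @param seed Optional seed (set it when calling stand-alone).
#' @return Integer founder matrix (markers x 8, 0 = A, 1 = B).
#' @export
simulate_founders <- function(n_markers, maf_weights = c(16, 56, 112, 70) / 254,
                              missing_rate = 0, marker_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(4, n_markers, replace = TRUE, prob = maf_weights)
  f <- matrix(0L, n_markers, 8,
              dimnames = list(marker_ids %||% sprintf("M%05d", seq_len(n_markers)),
                              LETTERS[1:8]))
  for (i in seq_len(n_markers))
    f[i, sample.int(8, cls[i])] <- 1L
  if (missing_rate > 0)
    f[matrix(stats::runif(length(f)) < missing_rate, nrow(f))] <- NA_integer_
  f
}

#' Simulate one haplotype mosaic along a chromosome
#'
#' Founder labels at the marker positions: uniform start, then over each
#' interval of d cM a redraw event with probability `1 - exp(-a d/100)`
#' (`a = (8/7) n_gen_eff`), new founder uniform over 8 with self allowed.
#'
#' @param pos Sorted marker positions (cM).
#' @param n_gen_eff Switch density.
#' @param seed Optional seed.
#' @return Integer vector of founder labels (1..8) per marker.
#' @export
simulate_mosaic <- function(pos, n_gen_eff, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pos)
  h <- integer(n)
  h[1] <- sample.int(8, 1)
  if (n > 1) {
    p_sw <- hap_switch_prob(diff(pos), n_gen_eff)
    ev <- stats::runif(n - 1) < p_sw
    draws <- sample.int(8, n - 1, replace = TRUE)
    for (i in seq_len(n - 1))
      h[i + 1] <- if (ev[i]) draws[i] else h[i]
  }
  h
}

#' Genotypes implied by a mosaic pair
#'
#' @param h1,h2 Founder-label vectors for the two haplotypes.
#' @param founders Integer founder matrix rows for the same markers.
#' @return Integer genotype vector (0/1/2, NA where a founder call is
#'   missing).
#' @export
genotypes_from_mosaic <- function(h1, h2, founders) {
  idx <- seq_along(h1)
  founders[cbind(idx, h1)] + founders[cbind(idx, h2)]
}

#' Corrupt clean genotypes with errors and missingness
#'
#' Each call is set missing with its sample's missing rate; surviving
#' calls are flipped to one of the two other genotypes (uniformly) with
#' the sample's error rate.  Both masks are returned.
#'
#' @param clean Integer genotype matrix.
#' @param missing_rate,error_rate Scalars or per-sample vectors.
#' @param seed Optional seed.
#' @return List `geno`, `missing_mask`, `error_mask` (masks are logical
#'   matrices; disjoint by construction).
#' @export
corrupt_genotypes <- function(clean, missing_rate = 0.01, error_rate = 0.002,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(clean); p <- ncol(clean)
  missing_rate <- rep(missing_rate, length.out = p)
  error_rate <- rep(error_rate, length.out = p)
  mr <- matrix(missing_rate, n, p, byrow = TRUE)
  er <- matrix(error_rate, n, p, byrow = TRUE)
  obs <- clean
  miss <- matrix(stats::runif(n * p) < mr, n, p) & !is.na(clean)
  err <- matrix(stats::runif(n * p) < er, n, p) & !is.na(clean) & !miss
  obs[miss] <- NA_integer_
  if (any(err)) {
    cur <- clean[err]
    shift <- sample.int(2, sum(err), replace = TRUE)  # 1 or 2 steps mod 3
    obs[err] <- (cur + shift) %% 3L
  }
  dimnames(obs) <- dimnames(clean)
  list(geno = obs, missing_mask = miss, error_mask = err)
}

#' Simulate two-channel probe intensities
#'
#' Autosomal and X markers draw their channel pair from the genotype's
#' cluster mean plus independent Gaussian noise; X-marker means are scaled
#' by X dosage (XX/XXY = 1, XY/XO = 0.5) and Y markers carry signal only
#' in samples with a Y chromosome (XY/XXY), otherwise background.
#' Intensities are truncated at zero.
#'
#' @param clean_geno Integer genotype matrix (autosomes + X).
#' @param sex_class `"XX"/"XY"/"XO"/"XXY"` per sample.
#' @param map Genetic map (to locate X markers).
#' @param y_markers Y marker ids (intensity-only).
#' @param intensity Cluster parameter list (see [sim_config()]).
#' @param seed Optional seed.
#' @return List of `int_x`, `int_y` matrices covering genotyped markers
#'   plus Y markers.
#' @export
simulate_intensities <- function(clean_geno, sex_class, map, y_markers,
                                 intensity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  markers <- c(rownames(clean_geno), y_markers)
  samples <- colnames(clean_geno)
  nm <- length(markers); np <- length(samples)
  x_dose <- c(XX = 1, XY = 0.5, XO = 0.5, XXY = 1)[sex_class]
  y_dose <- c(XX = 0, XY = 1, XO = 0, XXY = 1)[sex_class]
  mx <- matrix(NA_real_, nm, np, dimnames = list(markers, samples))
  my <- mx
  is_x <- markers %in% map$marker[map$chr == "X"]
  is_y <- markers %in% y_markers
  g <- clean_geno[markers[!is_y], , drop = FALSE]
  gi <- g + 1L
  mean_x <- matrix(intensity$means[, 1][gi], nrow(g))
  mean_y <- matrix(intensity$means[, 2][gi], nrow(g))
  # uncalled genotypes (missing founder calls) sit between the clusters
  mean_x[is.na(mean_x)] <- mean(intensity$means[, 1])
  mean_y[is.na(mean_y)] <- mean(intensity$means[, 2])
  dose <- matrix(1, nrow(g), np)
  if (any(is_x))
    dose[is_x[!is_y], ] <- matrix(x_dose, sum(is_x), np, byrow = TRUE)
  mx[!is_y, ] <- mean_x * dose
  my[!is_y, ] <- mean_y * dose
  if (any(is_y)) {
    ym <- matrix(intensity$y_mean * y_dose + intensity$background * (1 - y_dose),
                 sum(is_y), np, byrow = TRUE)
    mx[is_y, ] <- ym
    my[is_y, ] <- ym
  }
  noise <- function(m) pmax(m + stats::rnorm(length(m), sd = intensity$sd), 0)
  list(int_x = noise(mx), int_y = noise(my))
}

#' Generate a complete synthetic DO dataset with truth
#'
#' Builds the genetic map, founder genotypes, per-sample mosaics, clean and
#' corrupted genotype matrices, two-channel intensities, and metadata, and
#' records the full hidden truth.  Engineered anomalies are placed on
#' deterministic sample indices: the duplicate pairs first, then the
#' low-quality samples, then the XO, sex-mislabel, and XXY samples.
#' Identical seeds give bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return List of class `"do_sim"` with elements `data` (a [do_data()]
#'   bundle), `truth` (mosaics, true genotypes, masks, true sex, duplicate
#'   links, true switch counts), and `config`.
#' @export
make_dataset <- function(config) {
  set.seed(config$seed)
  n_samples <- sum(config$groups$n)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  generation <- rep(config$groups$generation, config$groups$n)
  gen_eff <- rep(config$n_gen_eff, config$groups$n)

  # --- map ---------------------------------------------------------------
  auto_map <- do.call(rbind, lapply(seq_len(config$n_chr), function(ch) {
    data.frame(marker = sprintf("c%02d_m%04d", ch, seq_len(config$markers_per_chr)),
               chr = as.character(ch),
               pos = (seq_len(config$markers_per_chr) - 1) * config$spacing_cM)
  }))
  x_map <- if (config$n_x_markers > 0)
    data.frame(marker = sprintf("cX_m%04d", seq_len(config$n_x_markers)),
               chr = "X",
               pos = seq(0, config$x_length_cM, length.out = config$n_x_markers))
  y_map <- if (config$n_y_markers > 0)
    data.frame(marker = sprintf("cY_m%04d", seq_len(config$n_y_markers)),
               chr = "Y", pos = seq_len(config$n_y_markers) - 1)
  map <- rbind(auto_map, x_map, y_map)

  # true founder genotypes are complete; missingness is applied only to the
  # *reported* founder matrix (samples are assayed regardless of how complete
  # the founder genotype file is)
  geno_markers <- c(auto_map$marker, if (!is.null(x_map)) x_map$marker)
  founders_true <- simulate_founders(length(geno_markers), config$maf_weights,
                                     missing_rate = 0,
                                     marker_ids = geno_markers)
  founders <- founders_true
  if (config$founder_missing_rate > 0)
    founders[matrix(stats::runif(length(founders)) < config$founder_missing_rate,
                    nrow(founders))] <- NA_integer_

  # --- special sample roles ----------------------------------------------
  idx <- 1L
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- seq.int(idx, length.out = n)
    idx <<- idx + n
    if (max(out) > n_samples) stop("too few samples for the requested anomalies")
    out
  }
  dup_idx <- take(2L * config$n_duplicate_pairs)
  dup_pairs <- if (config$n_duplicate_pairs > 0)
    matrix(dup_idx, ncol = 2, byrow = TRUE) else matrix(integer(0), 0, 2)
  bad_idx <- take(length(config$bad_samples))
  xo_idx <- take(config$n_xo)
  mis_idx <- take(config$n_sex_mislabel)
  xxy_idx <- take(config$n_xxy)

  # nominal sexes alternate; anomalies override below
  nominal_sex <- rep(c("F", "M"), length.out = n_samples)
  true_sex <- ifelse(nominal_sex == "F", "XX", "XY")
  true_sex[xo_idx] <- "XO";  nominal_sex[xo_idx] <- "F"
  true_sex[mis_idx] <- "XX"; nominal_sex[mis_idx] <- "M"
  true_sex[xxy_idx] <- "XXY"; nominal_sex[xxy_idx] <- "M"
  if (nrow(dup_pairs) > 0) {
    nominal_sex[dup_pairs[, 2]] <- nominal_sex[dup_pairs[, 1]]
    true_sex[dup_pairs[, 2]] <- true_sex[dup_pairs[, 1]]
  }

  # --- mosaics and clean genotypes ---------------------------------------
  clean <- matrix(NA_integer_, length(geno_markers), n_samples,
                  dimnames = list(geno_markers, sample_ids))
  mosaics <- vector("list", n_samples)
  switch_counts <- integer(n_samples)
  for (si in seq_len(n_samples)) {
    mosaics[[si]] <- list()
    for (ch in unique(auto_map$chr)) {
      pos <- auto_map$pos[auto_map$chr == ch]
      mk <- auto_map$marker[auto_map$chr == ch]
      h1 <- simulate_mosaic(pos, gen_eff[si])
      h2 <- simulate_mosaic(pos, gen_eff[si])
      mosaics[[si]][[ch]] <- cbind(h1 = h1, h2 = h2)
      clean[mk, si] <- genotypes_from_mosaic(h1, h2, founders_true[mk, , drop = FALSE])
      switch_counts[si] <- switch_counts[si] + sum(diff(h1) != 0) + sum(diff(h2) != 0)
    }
    if (!is.null(x_map)) {
      n_x_hap <- c(XX = 2, XY = 1, XO = 1, XXY = 2)[true_sex[si]]
      mk <- x_map$marker
      hx <- replicate(n_x_hap, simulate_mosaic(x_map$pos, gen_eff[si]))
      if (n_x_hap == 1) {
        clean[mk, si] <- 2L * founders_true[cbind(match(mk, rownames(founders_true)), hx[, 1])]
      } else {
        clean[mk, si] <- genotypes_from_mosaic(hx[, 1], hx[, 2],
                                               founders_true[mk, , drop = FALSE])
      }
      mosaics[[si]][["X"]] <- hx
    }
  }
  # duplicates share the partner's genome (independent corruption below)
  for (pr in seq_len(nrow(dup_pairs))) {
    i <- dup_pairs[pr, 1]; j <- dup_pairs[pr, 2]
    mosaics[[j]] <- mosaics[[i]]
    clean[, j] <- clean[, i]
    switch_counts[j] <- switch_counts[i]
  }

  # --- systematic bad markers (cluster-swap miscalls) --------------------
  # applied before random corruption: a fraction of true heterozygotes at
  # the affected markers is reported as the major homozygote (AA)
  pre_obs <- clean
  bad_markers <- character(0)
  bad_marker_mask <- matrix(FALSE, nrow(clean), ncol(clean),
                            dimnames = dimnames(clean))
  if (config$n_bad_markers > 0) {
    bad_markers <- sample(auto_map$marker, config$n_bad_markers)
    for (bm in bad_markers) {
      hit <- which(clean[bm, ] == 1L &
                   stats::runif(n_samples) < config$bad_marker_frac)
      pre_obs[bm, hit] <- 0L
      bad_marker_mask[bm, hit] <- TRUE
    }
  }

  # --- corruption ---------------------------------------------------------
  miss_rate <- rep(config$missing_rate, n_samples)
  err_rate <- rep(config$epsilon, n_samples)
  for (bi in seq_along(config$bad_samples)) {
    miss_rate[bad_idx[bi]] <- config$bad_samples[[bi]]$missing
    err_rate[bad_idx[bi]] <- config$bad_samples[[bi]]$error
  }
  cor <- corrupt_genotypes(pre_obs, miss_rate, err_rate)

  # --- intensities --------------------------------------------------------
  ints <- simulate_intensities(clean, true_sex, map,
                               y_markers = if (!is.null(y_map)) y_map$marker else character(0),
                               intensity = config$intensity)

  covar <- data.frame(id = sample_ids, sex = nominal_sex,
                      generation = generation, stringsAsFactors = FALSE)
  data <- do_data(cor$geno, founders, map, covar, ints$int_x, ints$int_y)
  truth <- list(mosaics = stats::setNames(mosaics, sample_ids),
                true_geno = clean,
                missing_mask = cor$missing_mask,
                error_mask = cor$error_mask,
                true_sex = stats::setNames(true_sex, sample_ids),
                bad_markers = bad_markers,
                bad_marker_mask = bad_marker_mask,
                switch_counts = stats::setNames(switch_counts, sample_ids),
                duplicate_pairs = dup_pairs,
                special = list(duplicates = sample_ids[dup_idx],
                               bad = sample_ids[bad_idx],
                               xo = sample_ids[xo_idx],
                               sex_mislabel = sample_ids[mis_idx],
                               xxy = sample_ids[xxy_idx]))
  structure(list(data = data, truth = truth, config = config),
            class = "do_sim")
}

#' True diplotype state indices from the simulated mosaics
#'
#' @param sim A `"do_sim"` object.
#' @param chr Autosome id.
#' @return Integer `markers x samples` matrix of true state indices.
#' @export
true_diplotype_states <- function(sim, chr) {
  samples <- names(sim$truth$mosaics)
  out <- vapply(samples, function(s) {
    h <- sim$truth$mosaics[[s]][[chr]]
    dip_state_index(h[, 1], h[, 2])
  }, integer(nrow(sim$truth$mosaics[[1]][[chr]])))
  rownames(out) <- sim$data$map$marker[sim$data$map$chr == chr]
  out
}
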