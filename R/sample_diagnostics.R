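# Per-sample quality-control statistics: missing data, sex verification
# from X/Y probe intensities, duplicate detection, array intensity
# profiles, genotype frequencies by founder minor allele frequency,
# crossover counts, and genotyping-error rates.

#' QC decision thresholds
#'
#' All cutoffs used by the pipeline, with the defaults used for DO array
#' data: samples with >= 20% missing genotypes are omitted and samples with
#' > 2% are annotated; error LOD > 2 defines a presumed genotyping error;
#' pairs sharing > 90% of genotypes are duplicates (observed duplicates
#' share > 99.9% while all other pairs stay below ~76%, so 0.90 sits in the
#' gap with margin); markers with > 5% presumed errors are omitted.
#'
#' @param sample_missing_omit Fraction of missing genotypes at or above
#'   which a sample is omitted (default 0.20).
#' @param sample_missing_note Fraction above which a sample is annotated
#'   but retained (default 0.02).
#' @param errorlod_cut Error-LOD threshold defining a presumed error
#'   (default 2).
#' @param duplicate_share Proportion of matching genotypes above which a
#'   pair is flagged as duplicates (default 0.90).
#' @param min_shared_markers Pairs sharing fewer non-missing markers are
#'   reported but not scored (default 1000).
#' @param call_threshold Minimum posterior for a diplotype call (0.5).
#' @param marker_error_omit Marker error-rate fraction above which a marker
#'   is listed for omission (default 0.05).
#' @param maf_outlier_freq Advisory bound: sample minor allele frequency
#'   above which a founder-MAF-1/8 marker is flagged (default 0.40).
#' @param het_outlier_freq Advisory bound: heterozygosity below which a
#'   founder-MAF-4/8 marker is flagged (default 0.25).
#' @return List of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(sample_missing_omit = 0.20,
                          sample_missing_note = 0.02,
                          errorlod_cut = 2,
                          duplicate_share = 0.90,
                          min_shared_markers = 1000,
                          call_threshold = 0.5,
                          marker_error_omit = 0.05,
                          maf_outlier_freq = 0.40,
                          het_outlier_freq = 0.25) {
  th <- list(sample_missing_omit = sample_missing_omit,
             sample_missing_note = sample_missing_note,
             errorlod_cut = errorlod_cut,
             duplicate_share = duplicate_share,
             min_shared_markers = min_shared_markers,
             call_threshold = call_threshold,
             marker_error_omit = marker_error_omit,
             maf_outlier_freq = maf_outlier_freq,
             het_outlier_freq = het_outlier_freq)
  fr <- c("sample_missing_omit", "sample_missing_note", "duplicate_share",
          "call_threshold", "marker_error_omit")
  stopifnot(all(unlist(th[fr]) > 0), all(unlist(th[fr]) < 1))
  structure(th, class = "qc_thresholds")
}

#' Percent missing genotypes by sample
#'
#' @param geno Integer genotype matrix (markers x samples).
#' @param markers Marker subset (default: all rows); typically the
#'   founder-informative markers.
#' @return Named numeric vector of percentages (0-100) per sample.
#' @export
percent_missing_by_sample <- function(geno, markers = NULL) {
  if (!is.null(markers)) geno <- geno[intersect(markers, rownames(geno)), , drop = FALSE]
  if (nrow(geno) == 0) stop("no markers to assess")
  100 * colMeans(is.na(geno))
}

#' Sex-informative X markers
#'
#' Drops X-chromosome markers whose mean intensity does not separate the
#' nominal sexes (absolute Welch z-score below `z_min`); such probes only
#' blur the X-intensity average used for sex verification.
#'
#' @param int_x,int_y Intensity channel matrices.
#' @param x_markers X-chromosome marker ids.
#' @param nominal_sex `"M"`/`"F"` per sample (matrix column order).
#' @param z_min Minimum |z| to retain a marker (default 2).
#' @return Character vector of retained marker ids.
#' @export
sex_informative_x_markers <- function(int_x, int_y, x_markers, nominal_sex,
                                      z_min = 2) {
  x_markers <- intersect(x_markers, rownames(int_x))
  avg <- (int_x[x_markers, , drop = FALSE] + int_y[x_markers, , drop = FALSE]) / 2
  m <- nominal_sex == "M" & !is.na(nominal_sex)
  f <- nominal_sex == "F" & !is.na(nominal_sex)
  if (sum(m) < 2 || sum(f) < 2) return(x_markers)
  mu_m <- rowMeans(avg[, m, drop = FALSE], na.rm = TRUE)
  mu_f <- rowMeans(avg[, f, drop = FALSE], na.rm = TRUE)
  v_m <- apply(avg[, m, drop = FALSE], 1, stats::var, na.rm = TRUE)
  v_f <- apply(avg[, f, drop = FALSE], 1, stats::var, na.rm = TRUE)
  z <- (mu_f - mu_m) / sqrt(v_m / sum(m) + v_f / sum(f))
  x_markers[!is.na(z) & abs(z) >= z_min]
}

#' Verify sample sex from X/Y probe intensities
#'
#' Computes the average probe intensity (mean of the two channels) over X-
#' and over Y-chromosome markers for each sample and classifies: high X /
#' low Y is XX, low X / high Y is XY, low on both is XO, high on both is
#' XXY.  Default thresholds are the midpoints between the nominal-sex group
#' medians; with a single-sex cohort thresholds must be supplied, otherwise
#' every sample is `"ambiguous"`.
#'
#' @param int_x,int_y Intensity channel matrices (markers x samples).
#' @param x_markers,y_markers Marker ids on the X and Y chromosome.
#' @param nominal_sex `"M"`/`"F"`/NA per sample, in matrix column order.
#' @param thresholds Optional `c(tx, ty)` intensity cutoffs.
#' @return Data frame per sample: `sample`, `mean_x`, `mean_y`,
#'   `nominal_sex`, `inferred_sex` (`XX`, `XY`, `XO`, `XXY`, `ambiguous`),
#'   and `sex_mismatch` (nominal male classified XX or nominal female
#'   classified XY).
#' @export
sex_check <- function(int_x, int_y, x_markers, y_markers,
                      nominal_sex = NULL, thresholds = NULL) {
  stopifnot(length(x_markers) > 0, length(y_markers) > 0)
  samples <- colnames(int_x)
  avg <- (int_x + int_y) / 2
  mean_x <- colMeans(avg[intersect(x_markers, rownames(avg)), , drop = FALSE],
                     na.rm = TRUE)
  mean_y <- colMeans(avg[intersect(y_markers, rownames(avg)), , drop = FALSE],
                     na.rm = TRUE)
  if (is.null(nominal_sex)) nominal_sex <- rep(NA_character_, length(samples))
  if (is.null(thresholds)) {
    m <- nominal_sex == "M" & !is.na(nominal_sex)
    f <- nominal_sex == "F" & !is.na(nominal_sex)
    if (sum(m) >= 2 && sum(f) >= 2) {
      tx <- (stats::median(mean_x[m]) + stats::median(mean_x[f])) / 2
      ty <- (stats::median(mean_y[m]) + stats::median(mean_y[f])) / 2
      thresholds <- c(tx, ty)
    }
  }
  if (is.null(thresholds)) {
    inferred <- rep("ambiguous", length(samples))
    warning("single-sex or unlabeled cohort: supply intensity thresholds")
  } else {
    hx <- mean_x >= thresholds[1]
    hy <- mean_y >= thresholds[2]
    inferred <- ifelse(hx & !hy, "XX",
                ifelse(!hx & hy, "XY",
                ifelse(!hx & !hy, "XO", "XXY")))
  }
  mismatch <- (nominal_sex == "M" & inferred == "XX") |
              (nominal_sex == "F" & inferred == "XY")
  mismatch[is.na(nominal_sex)] <- FALSE
  data.frame(sample = samples, mean_x = mean_x, mean_y = mean_y,
             nominal_sex = nominal_sex, inferred_sex = inferred,
             sex_mismatch = mismatch, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Proportion of heterozygous calls on the X chromosome
#'
#' Males (and XO females) are hemizygous on X, so heterozygous X calls in a
#' nominal male point at a sex problem.  Returns `NA` for samples with no
#' non-missing X genotype.
#'
#' @param geno Integer genotype matrix.
#' @param x_markers X-chromosome marker ids.
#' @return Named numeric vector of fractions per sample.
#' @export
x_heterozygosity <- function(geno, x_markers) {
  g <- geno[intersect(x_markers, rownames(geno)), , drop = FALSE]
  nhet <- colSums(g == 1L, na.rm = TRUE)
  ntot <- colSums(!is.na(g))
  ifelse(ntot > 0, nhet / ntot, NA_real_)
}

#' Proportion of matching genotypes for all sample pairs
#'
#' For each pair, the proportion of identical calls among markers
#' non-missing in both samples.  Pairs sharing fewer than `min_shared`
#' markers are reported but marked unscored.
#'
#' @param geno Integer genotype matrix.
#' @param min_shared Minimum number of shared non-missing markers for a
#'   pair to be scored.
#' @return Data frame (upper triangle): `sample1`, `sample2`, `n_shared`,
#'   `prop_match`, `scored`.
#' @export
pairwise_match <- function(geno, min_shared = 1000) {
  n <- ncol(geno)
  if (n < 2) stop("need at least two samples")
  ids <- colnames(geno)
  # one-hot trick: matches and shared counts via crossprod
  ok <- !is.na(geno)
  shared <- crossprod(ok)
  match_ct <- matrix(0, n, n)
  for (g in 0:2) {
    ind <- ok & geno == g
    ind[is.na(ind)] <- FALSE
    match_ct <- match_ct + crossprod(ind)
  }
  ut <- which(upper.tri(shared), arr.ind = TRUE)
  ns <- shared[ut]
  out <- data.frame(sample1 = ids[ut[, 1]], sample2 = ids[ut[, 2]],
                    n_shared = as.integer(ns),
                    prop_match = ifelse(ns > 0, match_ct[ut] / ns, NA_real_),
                    scored = ns >= min_shared, stringsAsFactors = FALSE)
  out[order(out$sample1, out$sample2), , drop = FALSE]
}

#' Flag duplicate sample pairs
#'
#' Samples already slated for omission (missingness at or above the omit
#' threshold) are excluded first; among scored pairs of the remainder,
#' those with `prop_match > duplicate_share` are flagged.  The second
#' sample of each pair (by input order) is the recommended omission;
#' resolving sex-inconsistent pairs is left to the caller.
#'
#' @param match_table Output of [pairwise_match()].
#' @param thresholds [qc_thresholds()].
#' @param pct_missing Optional named percent-missing vector used to apply
#'   the omission rule before flagging.
#' @return Data frame of flagged pairs with a `recommend_omit` column.
#' @export
flag_duplicates <- function(match_table, thresholds = qc_thresholds(),
                            pct_missing = NULL) {
  if (!is.null(pct_missing)) {
    bad <- names(pct_missing)[pct_missing >= 100 * thresholds$sample_missing_omit]
    match_table <- match_table[!(match_table$sample1 %in% bad) &
                               !(match_table$sample2 %in% bad), , drop = FALSE]
  }
  hit <- match_table$scored & !is.na(match_table$prop_match) &
    match_table$prop_match > thresholds$duplicate_share
  out <- match_table[hit, , drop = FALSE]
  out$recommend_omit <- out$sample2
  rownames(out) <- NULL
  out
}

#' Array intensity profile for one sample
#'
#' Pools both probe channels across markers, applies the `log10(x + 1)`
#' transformation, and returns the 1st and 99th percentiles (linear
#' interpolation between order statistics, quantile type 7) plus a binned
#' density table.
#'
#' @param int_x,int_y Intensity channel matrices.
#' @param sample Sample id.
#' @param n_bins Number of histogram bins for the density table.
#' @return List with `p1`, `p99`, and `density` (data frame `mid`, `count`).
#' @export
intensity_profile <- function(int_x, int_y, sample, n_bins = 50) {
  v <- c(int_x[, sample], int_y[, sample])
  v <- log10(v[!is.na(v)] + 1)
  q <- stats::quantile(v, c(0.01, 0.99), type = 7, names = FALSE)
  h <- graphics::hist(v, breaks = n_bins, plot = FALSE)
  list(p1 = q[1], p99 = q[2],
       density = data.frame(mid = h$mids, count = h$counts))
}

#' Intensity percentiles for all samples
#'
#' @inheritParams intensity_profile
#' @return Data frame `sample`, `p1`, `p99` of the log10(x+1) intensities.
#' @export
intensity_percentiles <- function(int_x, int_y) {
  samples <- colnames(int_x)
  q <- vapply(samples, function(s) {
    v <- c(int_x[, s], int_y[, s])
    v <- log10(v[!is.na(v)] + 1)
    stats::quantile(v, c(0.01, 0.99), type = 7, names = FALSE)
  }, numeric(2))
  data.frame(sample = samples, p1 = q[1, ], p99 = q[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

# expected genotype frequencies (minor hom, het, major hom) for a founder
# MAF class under equal founder dosage
maf_class_expectation <- function(classes = c("1/8", "2/8", "3/8", "4/8")) {
  m <- vapply(strsplit(classes, "/"), function(x) as.numeric(x[1]) / as.numeric(x[2]), 0)
  out <- cbind(BB = m^2, AB = 2 * m * (1 - m), AA = (1 - m)^2)
  rownames(out) <- classes
  out[, c("AA", "AB", "BB"), drop = FALSE]
}

#' SNP genotype frequencies by founder MAF class
#'
#' For each sample and each founder minor-allele-frequency class (markers
#' with complete founder genotypes only), the observed frequencies of the
#' major homozygote, heterozygote, and minor homozygote among non-missing
#' calls, together with the expectation under equal founder dosage:
#' minor hom `m^2`, het `2m(1-m)`, major hom `(1-m)^2` with `m` the class
#' MAF.  Contaminated samples show excess heterozygosity in every class.
#'
#' @param geno Integer genotype matrix.
#' @param founders Integer founder matrix.
#' @param markers Marker subset (default: informative markers).
#' @return List with `freq` (`samples x class x genotype` array), `n`
#'   (calls per sample and class), and `expected` (`class x genotype`).
#' @export
genotype_freq_by_maf <- function(geno, founders, markers = NULL) {
  if (is.null(markers)) markers <- filter_informative(founders)
  cls <- founder_maf_class(founders, markers)
  classes <- c("1/8", "2/8", "3/8", "4/8")
  samples <- colnames(geno)
  freq <- array(NA_real_, c(length(samples), length(classes), 3),
                dimnames = list(samples, classes, c("AA", "AB", "BB")))
  n <- matrix(0L, length(samples), length(classes),
              dimnames = list(samples, classes))
  for (ci in seq_along(classes)) {
    mk <- names(cls)[!is.na(cls) & cls == classes[ci]]
    if (length(mk) == 0) next
    g <- geno[mk, , drop = FALSE]
    ntot <- colSums(!is.na(g))
    n[, ci] <- ntot
    for (gv in 0:2)
      freq[, ci, gv + 1] <- ifelse(ntot > 0, colSums(g == gv, na.rm = TRUE) / ntot, NA)
  }
  list(freq = freq, n = n, expected = maf_class_expectation(classes))
}

#' Ternary plot coordinates for trinomial genotype frequencies
#'
#' Maps `(f_hom_minor, f_het, f_hom_major)` (summing to 1) to a point in a
#' unit-side equilateral triangle: `x = f_hom_major + f_het/2`,
#' `y = f_het * sqrt(3)/2`; the distances to the three sides recover the
#' three frequencies.
#'
#' @param f Numeric vector of length 3, or an `n x 3` matrix of rows
#'   `(minor hom, het, major hom)`.
#' @return `(x, y)` vector or `n x 2` matrix.
#' @export
ternary_coords <- function(f) {
  if (is.null(dim(f))) f <- matrix(f, 1)
  stopifnot(ncol(f) == 3, all(abs(rowSums(f) - 1) < 1e-6))
  cbind(x = f[, 3] + f[, 2] / 2, y = f[, 2] * sqrt(3) / 2)
}

#' Minimum crossover counts from called diplotypes
#'
#' Within each chromosome, consecutive non-missing diplotype calls
#' contribute the switch distance between the two unordered founder pairs
#' (0 if equal, 1 if they share one founder, 2 if disjoint); missing calls
#' are skipped, so the distance is taken between flanking calls.  This is
#' the minimum number of crossovers consistent with the calls (it
#' undercounts double recombinants hidden in gaps).  The genome total sums
#' over chromosomes.
#'
#' @param calls Output of [call_max_marginal()] (list per chromosome of
#'   state-index matrices), or a single such matrix.
#' @return Named integer vector of genome-wide counts per sample.
#' @export
count_crossovers <- function(calls) {
  if (is.matrix(calls)) calls <- list(calls)
  D <- dip_distance_matrix()
  per_chr <- lapply(calls, function(cm) {
    vapply(seq_len(ncol(cm)), function(si) {
      s <- cm[, si]
      s <- s[!is.na(s)]
      if (length(s) < 2) return(0L)
      sum(D[cbind(s[-length(s)], s[-1])])
    }, integer(1))
  })
  total <- Reduce(`+`, per_chr)
  stats::setNames(as.integer(total), colnames(calls[[1]]))
}

#' Estimated genotyping error rate by sample
#'
#' Fraction of scored sites (non-missing observed genotypes at markers
#' with complete founder genotypes) whose error LOD exceeds the cut.
#'
#' @param lod_table Output of [error_lod_table()].
#' @param errorlod_cut LOD threshold (default 2).
#' @param samples Optional sample ids to include (zero-count rows are
#'   returned for samples without scored sites).
#' @return Data frame `sample`, `n_scored`, `n_errors`, `pct_errors`.
#' @export
sample_error_rate <- function(lod_table, errorlod_cut = 2, samples = NULL) {
  if (is.null(samples)) samples <- unique(lod_table$sample)
  ns <- table(factor(lod_table$sample, levels = samples))
  ne <- table(factor(lod_table$sample[lod_table$lod > errorlod_cut],
                     levels = samples))
  data.frame(sample = samples, n_scored = as.integer(ns),
             n_errors = as.integer(ne),
             pct_errors = ifelse(ns > 0, 100 * as.integer(ne) / as.integer(ns), NA),
             row.names = NULL, stringsAsFactors = FALSE)
}
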