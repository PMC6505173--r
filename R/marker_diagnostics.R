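# Per-marker quality control: missingness, estimated error rates, genotype
# frequencies by founder MAF class, omission flags, and the
# cleaning-impact rerun.  Marker QC is computed on the samples surviving
# sample-level omission (samples first, then markers).

#' Percent missing genotypes by marker
#'
#' @param geno Integer genotype matrix.
#' @param samples Sample subset to assess (default: all); pass the retained
#'   samples so that low-quality samples do not inflate marker missingness.
#' @return Named numeric vector of percentages (0-100) per marker.
#' @export
percent_missing_by_marker <- function(geno, samples = NULL) {
  if (!is.null(samples)) geno <- geno[, samples, drop = FALSE]
  100 * rowMeans(is.na(geno))
}

#' Estimated genotyping error rate by marker
#'
#' Fraction of scored sites at each marker whose error LOD exceeds the cut;
#' markers with no scored site get `NA`.
#'
#' @param lod_table Output of [error_lod_table()].
#' @param errorlod_cut LOD threshold (default 2).
#' @param markers Optional marker ids to include.
#' @return Data frame `marker`, `n_scored`, `n_errors`, `pct_errors`.
#' @export
marker_error_rate <- function(lod_table, errorlod_cut = 2, markers = NULL) {
  if (is.null(markers)) markers <- unique(lod_table$marker)
  ns <- table(factor(lod_table$marker, levels = markers))
  ne <- table(factor(lod_table$marker[lod_table$lod > errorlod_cut],
                     levels = markers))
  data.frame(marker = markers, n_scored = as.integer(ns),
             n_errors = as.integer(ne),
             pct_errors = ifelse(ns > 0, 100 * as.integer(ne) / as.integer(ns),
                                 NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype frequencies and frequency flags by marker
#'
#' Observed AA/AB/BB frequencies among non-missing calls of the retained
#' samples, for markers with complete founder genotypes, plus the founder
#' MAF class, its expected frequencies, and two advisory outlier flags
#' drawn from anomalies seen in real DO data: `maf_flag` (class 1/8 but
#' sample minor allele frequency above `maf_outlier_freq`, the pattern
#' produced by meiotic drive) and `het_flag` (class 4/8 but heterozygosity
#' below `het_outlier_freq`).
#'
#' @param geno Integer genotype matrix.
#' @param founders Integer founder matrix.
#' @param samples Retained sample ids (default: all).
#' @param markers Marker subset (default: informative markers with complete
#'   founder genotypes).
#' @param thresholds [qc_thresholds()] (for the advisory bounds).
#' @return Data frame per marker: `marker`, `maf_class`, `n_called`,
#'   `f_AA`, `f_AB`, `f_BB`, `sample_maf`, `expected_het`, `maf_flag`,
#'   `het_flag`.
#' @export
marker_genotype_freqs <- function(geno, founders, samples = NULL,
                                  markers = NULL,
                                  thresholds = qc_thresholds()) {
  if (is.null(markers)) {
    cls_all <- founder_maf_class(founders, filter_informative(founders))
    markers <- names(cls_all)[!is.na(cls_all) & cls_all != "incomplete"]
  }
  cls <- founder_maf_class(founders, markers)
  g <- geno[markers, , drop = FALSE]
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  n <- rowSums(!is.na(g))
  fAA <- rowSums(g == 0L, na.rm = TRUE) / n
  fAB <- rowSums(g == 1L, na.rm = TRUE) / n
  fBB <- rowSums(g == 2L, na.rm = TRUE) / n
  maf <- (2 * rowSums(g == 2L, na.rm = TRUE) + rowSums(g == 1L, na.rm = TRUE)) /
    (2 * n)
  m <- as.numeric(substr(cls, 1, 1)) / 8
  expected_het <- 2 * m * (1 - m)
  data.frame(marker = markers, maf_class = unname(cls), n_called = n,
             f_AA = fAA, f_AB = fAB, f_BB = fBB, sample_maf = maf,
             expected_het = expected_het,
             maf_flag = !is.na(maf) & cls == "1/8" &
               maf > thresholds$maf_outlier_freq,
             het_flag = !is.na(fAB) & cls == "4/8" &
               fAB < thresholds$het_outlier_freq,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the per-marker QC report
#'
#' @param geno Integer genotype matrix.
#' @param founders Integer founder matrix.
#' @param map Genetic map.
#' @param lod_table Output of [error_lod_table()] on the retained samples.
#' @param samples Retained sample ids.
#' @param markers Marker subset (default: informative markers).
#' @param thresholds [qc_thresholds()].
#' @return Data frame per marker with chromosome, position, missingness,
#'   error rate, genotype frequencies, and flags (`omit_error`,
#'   `high_missing`, `freq_outlier`).
#' @export
marker_report <- function(geno, founders, map, lod_table, samples = NULL,
                          markers = NULL, thresholds = qc_thresholds()) {
  if (is.null(markers)) markers <- intersect(filter_informative(founders),
                                             rownames(geno))
  pm <- percent_missing_by_marker(geno[markers, , drop = FALSE], samples)
  er <- marker_error_rate(lod_table, thresholds$errorlod_cut, markers)
  fr <- marker_genotype_freqs(geno, founders, samples,
                              markers = intersect(
                                markers,
                                names(which(founder_maf_class(founders, markers) != "incomplete"))),
                              thresholds = thresholds)
  out <- data.frame(marker = markers,
                    chr = map$chr[match(markers, map$marker)],
                    pos = map$pos[match(markers, map$marker)],
                    pct_missing = unname(pm),
                    stringsAsFactors = FALSE)
  out <- merge(out, er, by = "marker", all.x = TRUE, sort = FALSE)
  out <- merge(out, fr, by = "marker", all.x = TRUE, sort = FALSE)
  out$omit_error <- !is.na(out$pct_errors) &
    out$pct_errors > 100 * thresholds$marker_error_omit
  out$high_missing <- out$pct_missing > 100 * thresholds$sample_missing_omit
  out$freq_outlier <- (!is.na(out$maf_flag) & out$maf_flag) |
    (!is.na(out$het_flag) & out$het_flag)
  out[match(markers, out$marker), , drop = FALSE]
}

#' Markers flagged for omission
#'
#' Markers whose estimated error rate exceeds the omission threshold;
#' high-missingness and frequency-outlier flags remain advisory.
#'
#' @param report Output of [marker_report()] (or any data frame with
#'   `marker` and `pct_errors`).
#' @param thresholds [qc_thresholds()].
#' @return Character vector of marker ids to omit.
#' @export
flag_markers <- function(report, thresholds = qc_thresholds()) {
  report$marker[!is.na(report$pct_errors) &
                report$pct_errors > 100 * thresholds$marker_error_omit]
}

#' Impact of omitting markers on the diplotype probabilities
#'
#' Recomputes the diplotype posteriors with the observations at the omitted
#' markers masked (the marker grid is unchanged, so probabilities remain
#' comparable site by site) and summarizes the per-site sum of absolute
#' probability differences, which ranges from 0 to 2.
#'
#' @param data A [do_data()] bundle.
#' @param omit_markers Markers whose genotypes are masked in the rerun.
#' @param params [hmm_params()].
#' @param samples Retained sample ids.
#' @param probs_before Optional precomputed posteriors (saves the first
#'   HMM pass).
#' @return List with `diff` (list per chromosome of `markers x samples`
#'   matrices), `n_sites`, `n_gt_1`, `n_gt_1.5`, and `max_diff`.
#' @export
cleaning_impact <- function(data, omit_markers, params = hmm_params(),
                            samples = NULL, probs_before = NULL) {
  if (is.null(probs_before))
    probs_before <- calc_diplotype_probs(data, params, samples = samples)
  probs_after <- calc_diplotype_probs(
    data, params, markers = unlist(lapply(probs_before, function(a) dimnames(a)[[1]])),
    samples = samples, mask_markers = omit_markers)
  diffs <- lapply(names(probs_before), function(chr)
    posterior_abs_diff(probs_before[[chr]], probs_after[[chr]]))
  names(diffs) <- names(probs_before)
  all_d <- unlist(diffs)
  list(diff = diffs, n_sites = length(all_d),
       n_gt_1 = sum(all_d > 1), n_gt_1.5 = sum(all_d > 1.5),
       max_diff = if (length(all_d)) max(all_d) else 0)
}

#' Allele intensity table for one marker
#'
#' Export-ready table for an allele-intensity scatterplot colored by
#' observed and by predicted genotype (the most informative view of a
#' misbehaving SNP).  No clustering or re-calling is performed.
#'
#' @param int_x,int_y Intensity channel matrices.
#' @param geno Observed integer genotype matrix.
#' @param predicted Predicted genotype matrix from
#'   [predicted_snp_genotypes()] (optional).
#' @param marker Marker id.
#' @return Data frame per sample: `sample`, `x`, `y`, `observed`,
#'   `predicted` (calls as strings, NA when missing); intensity rows are
#'   retained with NA coordinates when the marker lacks intensities.
#' @export
allele_intensity_table <- function(int_x, int_y, geno, predicted = NULL,
                                   marker) {
  samples <- colnames(geno)
  x <- if (marker %in% rownames(int_x)) int_x[marker, samples]
       else rep(NA_real_, length(samples))
  y <- if (marker %in% rownames(int_y)) int_y[marker, samples]
       else rep(NA_real_, length(samples))
  obs <- if (marker %in% rownames(geno)) geno_to_calls(geno[marker, samples])
         else rep(NA_character_, length(samples))
  pred <- if (!is.null(predicted) && marker %in% rownames(predicted))
    geno_to_calls(predicted[marker, samples]) else rep(NA_character_, length(samples))
  data.frame(sample = samples, x = unname(x), y = unname(y),
             observed = unname(obs), predicted = unname(pred),
             row.names = NULL, stringsAsFactors = FALSE)
}
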