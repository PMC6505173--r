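# Pipeline orchestration: sample QC -> omission -> HMM -> error LOD ->
# marker QC -> optional cleaning-impact rerun, with machine- and
# human-readable outputs.  The pipeline is a pure function of (data,
# thresholds, parameters): repeated runs are identical.

#' Run the full genotype QC pipeline
#'
#' Fixed stage order: sample missingness, sex verification, X
#' heterozygosity, pairwise matching and duplicate flags, intensity
#' percentiles, per-sample genotype frequencies by MAF class, diplotype
#' HMM, crossover counts, error LOD scores, per-sample error rates, marker
#' QC and flags, and (optionally) the cleaning-impact rerun.  Sample
#' omission (missingness at or above the omit threshold, plus the second
#' member of each duplicate pair) is applied between sample QC and marker
#' QC; samples in the 2-20% missingness band are annotated but retained.
#' Stages needing intensities are skipped with a warning when intensities
#' are absent.
#'
#' @param data A [do_data()] bundle.
#' @param thresholds [qc_thresholds()].
#' @param params [hmm_params()].
#' @param run_impact Also rerun the HMM without the flagged markers and
#'   summarize the change in diplotype probabilities (doubles the HMM
#'   work; default `FALSE`).
#' @param out_dir Optional directory: report tables are written as CSV and
#'   the summary as JSON.
#' @return List of class `"do_qc_report"`: `sample_report`, `match_table`,
#'   `duplicates`, `marker_report`, `omit_markers`, `lod_table`, `probs`,
#'   `calls`, `impact` (when run), `retained_samples`, `summary` (named
#'   list of counts), `thresholds`, `params`.
#' @export
run_pipeline <- function(data, thresholds = qc_thresholds(),
                         params = hmm_params(), run_impact = FALSE,
                         out_dir = NULL) {
  info <- filter_informative(data$founders)
  samples <- colnames(data$geno)
  covar <- data$covar
  has_int <- !is.null(data$int_x)
  x_markers <- data$map$marker[data$map$chr == "X"]
  y_markers <- data$map$marker[data$map$chr == "Y"]

  # --- sample-level diagnostics ------------------------------------------
  pct_missing <- percent_missing_by_sample(data$geno, info)
  sexes <- NULL
  pctiles <- NULL
  if (has_int && length(x_markers) > 0 && length(y_markers) > 0) {
    keep_x <- sex_informative_x_markers(data$int_x, data$int_y, x_markers,
                                        covar$sex)
    sexes <- sex_check(data$int_x, data$int_y, keep_x, y_markers, covar$sex)
    pctiles <- intensity_percentiles(data$int_x, data$int_y)
  } else {
    warning("no intensities (or no X/Y markers): sex check and intensity ",
            "profiles skipped")
  }
  het_x <- if (length(x_markers) > 0) x_heterozygosity(data$geno, x_markers)
           else stats::setNames(rep(NA_real_, length(samples)), samples)
  match_table <- pairwise_match(data$geno[intersect(info, rownames(data$geno)), ,
                                          drop = FALSE],
                                thresholds$min_shared_markers)
  dups <- flag_duplicates(match_table, thresholds, pct_missing)
  # genotype-frequency diagnostics on autosomes only (X frequencies are
  # sex-dependent through hemizygosity)
  auto <- data$map$marker[!(data$map$chr %in% c("X", "Y", "M", "MT"))]
  freq <- genotype_freq_by_maf(data$geno, data$founders,
                               intersect(info, auto))

  # --- omission rules -----------------------------------------------------
  omit_missing <- names(pct_missing)[pct_missing >= 100 * thresholds$sample_missing_omit]
  omit_dup <- unique(dups$recommend_omit)
  retained <- setdiff(samples, c(omit_missing, omit_dup))

  # --- HMM, crossovers, error LOD (retained samples) ----------------------
  probs <- calc_diplotype_probs(data, params, samples = retained)
  calls <- call_max_marginal(probs, thresholds$call_threshold)
  xo <- count_crossovers(calls)
  sp <- snp_genotype_probs(probs, data$founders)
  lod <- error_lod_table(sp, data$geno, params$epsilon, params$error_lod_cap)
  err <- sample_error_rate(lod, thresholds$errorlod_cut, retained)

  # --- sample report ------------------------------------------------------
  sr <- data.frame(sample = samples,
                   pct_missing = unname(pct_missing),
                   nominal_sex = covar$sex,
                   generation = covar$generation,
                   stringsAsFactors = FALSE)
  if (!is.null(sexes))
    sr <- merge(sr, sexes[c("sample", "mean_x", "mean_y", "inferred_sex",
                            "sex_mismatch")], by = "sample", sort = FALSE)
  sr$pct_het_x <- het_x[sr$sample]
  if (!is.null(pctiles))
    sr <- merge(sr, pctiles, by = "sample", sort = FALSE)
  sr$n_crossovers <- unname(xo[sr$sample])
  sr <- merge(sr, err[c("sample", "pct_errors")], by = "sample",
              all.x = TRUE, sort = FALSE)
  sr$flag_omit_missing <- sr$sample %in% omit_missing
  sr$flag_note_missing <- !sr$flag_omit_missing &
    sr$pct_missing > 100 * thresholds$sample_missing_note
  sr$duplicate_of <- NA_character_
  if (nrow(dups) > 0)
    sr$duplicate_of[match(dups$sample2, sr$sample)] <- dups$sample1
  sr$retained <- sr$sample %in% retained
  sr <- sr[match(samples, sr$sample), , drop = FALSE]
  rownames(sr) <- NULL

  # --- marker-level diagnostics ------------------------------------------
  mr <- marker_report(data$geno, data$founders, data$map, lod,
                      samples = retained, thresholds = thresholds)
  omit_markers <- flag_markers(mr, thresholds)

  impact <- NULL
  if (run_impact) {
    impact <- cleaning_impact(data, omit_markers, params,
                              samples = retained, probs_before = probs)
    impact$diff <- NULL  # keep the report light; counts carry the summary
  }

  summary <- list(
    n_samples = length(samples),
    n_markers_informative = length(info),
    n_omitted_missing = length(omit_missing),
    n_duplicate_pairs = nrow(dups),
    n_sex_mismatch = if (!is.null(sexes)) sum(sexes$sex_mismatch) else NA,
    n_aneuploid = if (!is.null(sexes))
      sum(sexes$inferred_sex %in% c("XO", "XXY")) else NA,
    n_retained = length(retained),
    median_prop_match = stats::median(match_table$prop_match[match_table$scored],
                                      na.rm = TRUE),
    median_pct_errors = stats::median(err$pct_errors, na.rm = TRUE),
    crossover_mean_by_generation = vapply(
      split(xo, covar$generation[match(names(xo), covar$id)]),
      mean, 0),
    n_markers_flagged_omit = length(omit_markers),
    n_impact_gt_1 = if (!is.null(impact)) impact$n_gt_1 else NA,
    n_impact_gt_1.5 = if (!is.null(impact)) impact$n_gt_1.5 else NA)

  bundle <- structure(
    list(sample_report = sr, match_table = match_table, duplicates = dups,
         genotype_freq = freq, marker_report = mr,
         omit_markers = omit_markers, lod_table = lod,
         probs = probs, calls = calls, impact = impact,
         retained_samples = retained, summary = summary,
         thresholds = thresholds, params = params),
    class = "do_qc_report")
  if (!is.null(out_dir)) write_qc_report(bundle, out_dir)
  bundle
}

#' Write pipeline outputs to disk
#'
#' CSV tables (`sample_report.csv`, `match_table.csv`, `marker_report.csv`,
#' `error_lod.csv`) plus `summary.json` with the headline counts and every
#' flagged sample/marker with the triggering rule.
#'
#' @param bundle A `"do_qc_report"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_qc_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                         row.names = FALSE)
  wt(bundle$sample_report, "sample_report.csv")
  wt(bundle$match_table, "match_table.csv")
  wt(bundle$marker_report, "marker_report.csv")
  wt(bundle$lod_table, "error_lod.csv")
  flags <- list(
    omit_missing = bundle$sample_report$sample[bundle$sample_report$flag_omit_missing],
    note_missing = bundle$sample_report$sample[bundle$sample_report$flag_note_missing],
    sex_mismatch = if ("sex_mismatch" %in% names(bundle$sample_report))
      bundle$sample_report$sample[isTRUE_vec(bundle$sample_report$sex_mismatch)]
      else character(0),
    duplicate_pairs = bundle$duplicates[c("sample1", "sample2")],
    omit_markers = bundle$omit_markers,
    freq_outlier_markers = bundle$marker_report$marker[
      isTRUE_vec(bundle$marker_report$freq_outlier)])
  jsonlite::write_json(list(summary = bundle$summary, flags = flags),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Render a plain-text pipeline summary
#'
#' @param bundle A `"do_qc_report"`.
#' @return Character vector of markdown lines.
#' @export
render_summary <- function(bundle) {
  s <- bundle$summary
  sr <- bundle$sample_report
  lines <- c(
    "# Genotype QC summary", "",
    sprintf("- samples: %d (%d retained after omission rules)",
            s$n_samples, s$n_retained),
    sprintf("- informative markers: %d", s$n_markers_informative),
    sprintf("- samples omitted for missingness (>= %.0f%%): %d",
            100 * bundle$thresholds$sample_missing_omit, s$n_omitted_missing),
    sprintf("- samples annotated for missingness (> %.0f%%): %d",
            100 * bundle$thresholds$sample_missing_note,
            sum(sr$flag_note_missing)),
    sprintf("- duplicate pairs: %d", s$n_duplicate_pairs),
    if (!is.na(s$n_sex_mismatch))
      sprintf("- sex mismatches: %d; sex-chromosome aneuploidies: %d",
              s$n_sex_mismatch, s$n_aneuploid),
    sprintf("- median pairwise genotype sharing: %.1f%%",
            100 * s$median_prop_match),
    sprintf("- median per-sample error rate: %.3f%%", s$median_pct_errors),
    paste0("- mean crossovers by generation: ",
           paste(sprintf("gen %s: %.1f",
                         names(s$crossover_mean_by_generation),
                         s$crossover_mean_by_generation), collapse = "; ")),
    sprintf("- markers flagged for omission (error rate > %.0f%%): %d",
            100 * bundle$thresholds$marker_error_omit,
            s$n_markers_flagged_omit))
  if (!is.na(s$n_impact_gt_1))
    lines <- c(lines,
               sprintf("- cleaning impact: %d sites changed > 1, %d > 1.5",
                       s$n_impact_gt_1, s$n_impact_gt_1.5))
  no_issue <- s$n_omitted_missing == 0 && s$n_duplicate_pairs == 0 &&
    (is.na(s$n_sex_mismatch) || s$n_sex_mismatch == 0) &&
    s$n_markers_flagged_omit == 0
  if (no_issue) lines <- c(lines, "", "No issues detected.")
  lines[!is.na(lines)]
}

#' @export
print.do_qc_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
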