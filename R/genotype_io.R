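# Reading, validation, and recoding of genotype, founder, intensity, and
# map files.
#
# Internal coding conventions (used throughout the package):
#   - sample genotypes: integer count of B alleles (0 = AA, 1 = AB, 2 = BB,
#     NA = missing), markers in rows, samples in columns, dimnames set
#   - founder genotypes: integer 0 = A, 1 = B, NA = missing, markers x 8,
#     columns named A..H
#   - A is the allele most frequent among the eight founder strains (see
#     recode_to_founder_major)
#   - genetic map: data frame (marker, chr, pos) with pos in cM, sorted by
#     position within chromosome (ties broken by marker id)

.missing_tokens <- c("NA", "N", "-", "--", "")

#' Convert genotype call strings to internal integer codes
#'
#' `"AA"/"AB"/"BB"` become 0/1/2 (the count of B alleles); the missing
#' tokens `"NA"`, `"N"`, `"-"`, `"--"` and the empty string become `NA`.
#' Any other token is set to `NA` with a warning giving the count, recorded
#' in the `"n_unparseable"` attribute.
#'
#' @param calls Character matrix or vector of genotype calls.
#' @return Integer object of the same shape (dimnames preserved).
#' @export
calls_to_geno <- function(calls) {
  x <- toupper(trimws(as.character(calls)))
  out <- rep(NA_integer_, length(x))
  out[x == "AA"] <- 0L
  out[x == "AB" | x == "BA"] <- 1L
  out[x == "BB"] <- 2L
  bad <- is.na(out) & !(x %in% .missing_tokens) & !is.na(calls)
  n_bad <- sum(bad)
  if (n_bad > 0)
    warning(n_bad, " unparseable genotype call(s) set to missing")
  if (!is.null(dim(calls))) {
    dim(out) <- dim(calls)
    dimnames(out) <- dimnames(calls)
  } else names(out) <- names(calls)
  attr(out, "n_unparseable") <- n_bad
  out
}

#' @rdname calls_to_geno
#' @param geno Integer genotype codes (0/1/2/NA).
#' @export
geno_to_calls <- function(geno) {
  out <- c("AA", "AB", "BB")[unclass(geno) + 1L]
  if (!is.null(dim(geno))) {
    dim(out) <- dim(geno)
    dimnames(out) <- dimnames(geno)
  } else names(out) <- names(geno)
  out
}

# founder call strings ("A"/"B", doubled letters accepted) -> 0/1/NA;
# heterozygous founder calls are treated as missing (founders are inbred)
# and counted in the "n_het_founder" attribute.
founder_calls_to_codes <- function(calls) {
  x <- toupper(trimws(as.character(calls)))
  x[x %in% .missing_tokens] <- NA_character_
  two <- !is.na(x) & nchar(x) == 2L
  het <- two & substr(x, 1, 1) != substr(x, 2, 2)
  x[two] <- substr(x[two], 1, 1)
  x[het] <- NA_character_
  out <- rep(NA_integer_, length(x))
  out[x == "A"] <- 0L
  out[x == "B"] <- 1L
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) warning(sum(bad), " unparseable founder call(s) set to missing")
  if (!is.null(dim(calls))) {
    dim(out) <- dim(calls)
    dimnames(out) <- dimnames(calls)
  }
  attr(out, "n_het_founder") <- sum(het)
  out
}

read_csv_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (anyDuplicated(df[[1]]))
    stop("duplicate row identifiers in ", path, ": ",
         paste(utils::head(unique(df[[1]][duplicated(df[[1]])]), 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m)))
    stop("duplicate column identifiers in ", path)
  m
}

#' Read a genotype call matrix from CSV
#'
#' Expects a rectangular comma-delimited table with a header row; the first
#' column holds row identifiers.  Calls are `AA/AB/BB` plus missing tokens.
#'
#' @param path CSV file path.
#' @param markers_in_rows If `FALSE`, the file has samples in rows and is
#'   transposed after reading.
#' @param map Optional genetic map data frame; if given, every marker must
#'   be present in it (offenders are listed in the error).
#' @return Integer genotype matrix, markers x samples (see
#'   [calls_to_geno()] for the coding).
#' @export
read_genotypes <- function(path, markers_in_rows = TRUE, map = NULL) {
  m <- read_csv_matrix(path)
  if (!markers_in_rows) m <- t(m)
  g <- calls_to_geno(m)
  if (!is.null(map)) {
    absent <- setdiff(rownames(g), map$marker)
    if (length(absent) > 0)
      stop("markers absent from the genetic map: ",
           paste(utils::head(absent, 10), collapse = ", "),
           if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10))
  }
  g
}

#' Read founder strain genotypes from CSV
#'
#' Markers in rows, eight founder columns; calls are single letters `A`/`B`
#' (doubled letters accepted) plus missing tokens.
#'
#' @inheritParams read_genotypes
#' @return Integer founder matrix (0 = A, 1 = B, NA), markers x 8.
#' @export
read_founder_genotypes <- function(path, markers_in_rows = TRUE, map = NULL) {
  m <- read_csv_matrix(path)
  if (!markers_in_rows) m <- t(m)
  f <- founder_calls_to_codes(m)
  if (!is.null(map)) {
    absent <- setdiff(rownames(f), map$marker)
    if (length(absent) > 0)
      stop("markers absent from the genetic map: ",
           paste(utils::head(absent, 10), collapse = ", "))
  }
  f
}

#' Read a genetic map from CSV
#'
#' Columns `marker`, `chr`, `pos` (cM).  Markers are sorted by position
#' within chromosome, ties broken by marker id; chromosomes keep their
#' order of first appearance.
#'
#' @param path CSV file path.
#' @return Data frame with columns `marker`, `chr`, `pos`.
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chr", "pos")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  validate_map(df[need])
}

validate_map <- function(map) {
  map$chr <- as.character(map$chr)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$marker))
    stop("duplicate marker ids in map")
  if (any(is.na(map$pos)) || any(map$pos < 0))
    stop("map positions must be non-negative numbers")
  chr_order <- unique(map$chr)
  map <- map[order(match(map$chr, chr_order), map$pos, map$marker), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Read a two-channel intensity matrix from CSV
#'
#' @inheritParams read_genotypes
#' @return Numeric matrix, markers x samples.
#' @export
read_intensities <- function(path, markers_in_rows = TRUE) {
  m <- read_csv_matrix(path)
  if (!markers_in_rows) m <- t(m)
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities in ", path)
  m
}

#' Bundle genotype data components
#'
#' Validates cross-component consistency and returns a `"do_data"` list as
#' produced by [read_control_file()] and [make_dataset()].
#'
#' @param geno Integer genotype matrix (markers x samples).
#' @param founders Integer founder matrix (markers x 8).
#' @param map Genetic map data frame (`marker`, `chr`, `pos`).
#' @param covar Sample metadata data frame with columns `id`, `sex`
#'   (`"M"`/`"F"`/NA), `generation`.
#' @param int_x,int_y Optional intensity matrices (markers x samples) for
#'   the allele-A (x) and allele-B (y) probe channels.
#' @return List of class `"do_data"`.
#' @export
do_data <- function(geno, founders, map, covar = NULL,
                    int_x = NULL, int_y = NULL) {
  map <- validate_map(map)
  if (!all(rownames(geno) %in% map$marker))
    stop("genotype markers missing from map")
  if (!all(rownames(founders) %in% map$marker))
    stop("founder markers missing from map")
  if (ncol(founders) != 8L) stop("founder matrix must have 8 columns")
  if (anyDuplicated(colnames(geno))) stop("duplicate sample ids")
  if (is.null(covar)) {
    covar <- data.frame(id = colnames(geno), sex = NA_character_,
                        generation = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!all(colnames(geno) %in% covar$id))
    stop("samples missing from covariate table")
  covar <- covar[match(colnames(geno), covar$id), , drop = FALSE]
  rownames(covar) <- NULL
  if (!is.null(int_x) != !is.null(int_y))
    stop("provide both intensity channels or neither")
  if (!is.null(int_x)) {
    if (!identical(dim(int_x), dim(int_y)))
      stop("intensity channel matrices must have the same shape")
    if (!all(rownames(int_x) %in% map$marker))
      stop("intensity markers missing from map")
  }
  structure(list(geno = geno, founders = founders, map = map, covar = covar,
                 int_x = int_x, int_y = int_y),
            class = "do_data")
}

#' @export
print.do_data <- function(x, ...) {
  cat("do_data:", nrow(x$geno), "genotyped markers x", ncol(x$geno),
      "samples;", nrow(x$map), "markers in map")
  if (!is.null(x$int_x)) cat(";", nrow(x$int_x), "markers with intensities")
  cat("\n")
  invisible(x)
}

#' Read a dataset described by a YAML/JSON control file
#'
#' The control file names the component CSVs (paths relative to its
#' directory): `geno`, `founder_geno`, `gmap`, and optionally `covar`,
#' `intensity_x`, `intensity_y`.  A logical `geno_transposed` entry marks
#' files with samples in rows.
#'
#' @param path Path to the control file.
#' @return A [do_data()] bundle.
#' @export
read_control_file <- function(path) {
  ctl <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  dir <- dirname(path)
  p <- function(f) file.path(dir, f)
  rows <- !isTRUE(ctl$geno_transposed)
  map <- read_map(p(ctl$gmap))
  geno <- read_genotypes(p(ctl$geno), markers_in_rows = rows, map = map)
  founders <- read_founder_genotypes(p(ctl$founder_geno), map = map)
  covar <- NULL
  if (!is.null(ctl$covar)) {
    covar <- utils::read.csv(p(ctl$covar), stringsAsFactors = FALSE)
    covar$sex <- as.character(covar$sex)
  }
  int_x <- if (!is.null(ctl$intensity_x)) read_intensities(p(ctl$intensity_x))
  int_y <- if (!is.null(ctl$intensity_y)) read_intensities(p(ctl$intensity_y))
  do_data(geno, founders, map, covar, int_x, int_y)
}

#' Recode nucleotide genotypes relative to the founder major allele
#'
#' Raw calls use nucleotide pairs (e.g. `"GT"`); founder calls are single
#' nucleotides (doubled letters accepted).  At each marker the allele
#' observed in more founder strains becomes A, the other B, and sample
#' calls are mapped to AA/AB/BB accordingly.  Equally frequent alleles are
#' tied-broken alphabetically so the recoding is deterministic.
#' Heterozygous founder calls are treated as missing (and counted); markers
#' with more than two alleles, or with no non-missing founder call, are
#' dropped and reported.
#'
#' @param raw Character matrix of sample nucleotide pairs, markers x samples.
#' @param founder_raw Character matrix of founder nucleotide calls,
#'   markers x 8.
#' @return List with `geno` (integer matrix, see [calls_to_geno()]),
#'   `founders` (integer matrix 0/1/NA), `info` (per retained marker:
#'   `marker`, `major`, `minor`, `informative`, `n_het_founder`), and
#'   `dropped` (data frame of dropped markers with a `reason`).
#' @export
recode_to_founder_major <- function(raw, founder_raw) {
  stopifnot(nrow(raw) == nrow(founder_raw))
  markers <- rownames(raw) %||% rownames(founder_raw) %||%
    paste0("M", seq_len(nrow(raw)))
  parse1 <- function(x) {
    x <- toupper(trimws(x))
    x[x %in% .missing_tokens] <- NA_character_
    x
  }
  geno <- matrix(NA_integer_, nrow(raw), ncol(raw),
                 dimnames = list(markers, colnames(raw)))
  fg <- matrix(NA_integer_, nrow(raw), 8L,
               dimnames = list(markers, colnames(founder_raw) %||% LETTERS[1:8]))
  info <- vector("list", nrow(raw))
  dropped <- list()
  for (i in seq_len(nrow(raw))) {
    fcell <- parse1(founder_raw[i, ])
    # founder letters; heterozygous (two distinct letters) -> missing
    f1 <- substr(fcell, 1, 1)
    f2 <- substr(fcell, nchar(fcell), nchar(fcell))
    fhet <- !is.na(fcell) & f1 != f2
    flet <- ifelse(fhet, NA_character_, f1)
    scell <- parse1(raw[i, ])
    s1 <- substr(scell, 1, 1)
    s2 <- substr(scell, nchar(scell), nchar(scell))
    alleles <- sort(unique(stats::na.omit(c(flet, s1, s2))))
    if (length(alleles) > 2) {
      dropped[[length(dropped) + 1]] <- data.frame(
        marker = markers[i], reason = "more_than_two_alleles")
      next
    }
    if (all(is.na(flet))) {
      dropped[[length(dropped) + 1]] <- data.frame(
        marker = markers[i], reason = "no_founder_genotypes")
      next
    }
    counts <- table(factor(flet, levels = alleles))
    major <- names(counts)[counts == max(counts)]
    major <- sort(major)[1]  # alphabetical tie-break
    minor <- setdiff(alleles, major)
    minor <- if (length(minor)) minor else NA_character_
    fg[i, ] <- ifelse(is.na(flet), NA_integer_,
                      ifelse(flet == major, 0L, 1L))
    geno[i, ] <- ifelse(is.na(scell), NA_integer_,
                        (s1 != major) + (s2 != major))
    info[[i]] <- data.frame(
      marker = markers[i], major = major, minor = minor,
      informative = !is.na(minor), n_het_founder = sum(fhet),
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(info, is.null, logical(1))
  info <- do.call(rbind, info[keep])
  rownames(info) <- NULL
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(marker = character(), reason = character())
  n_het <- sum(info$n_het_founder)
  if (n_het > 0)
    warning(n_het, " heterozygous founder call(s) treated as missing")
  list(geno = geno[keep, , drop = FALSE],
       founders = fg[keep, , drop = FALSE],
       info = info, dropped = dropped)
}

#' Markers polymorphic among the founder strains
#'
#' Retains markers where both the A and B allele are observed among the
#' non-missing founder calls; monomorphic (and all-missing) markers carry
#' no information about founder origin and are excluded from diagnostics.
#'
#' @param founders Integer founder matrix (markers x 8).
#' @return Character vector of informative marker ids.
#' @export
filter_informative <- function(founders) {
  hasA <- rowSums(founders == 0L, na.rm = TRUE) > 0
  hasB <- rowSums(founders == 1L, na.rm = TRUE) > 0
  rownames(founders)[hasA & hasB]
}

#' Founder minor allele frequency class
#'
#' The number of founder strains (of 8) carrying the minor allele: classes
#' `1/8` to `4/8`.  Markers with any missing founder call are `"incomplete"`
#' (their class cannot be determined); monomorphic markers get `NA`.
#'
#' @param founders Integer founder matrix (markers x 8).
#' @param markers Optional subset of marker ids.
#' @return Named character vector of classes per marker.
#' @export
founder_maf_class <- function(founders, markers = NULL) {
  if (!is.null(markers)) founders <- founders[markers, , drop = FALSE]
  nmiss <- rowSums(is.na(founders))
  nB <- rowSums(founders == 1L, na.rm = TRUE)
  nA <- rowSums(founders == 0L, na.rm = TRUE)
  m <- pmin(nA, nB)
  cls <- ifelse(nmiss > 0, "incomplete",
                ifelse(m == 0, NA_character_, paste0(m, "/8")))
  stats::setNames(cls, rownames(founders))
}

#' Write a dataset to the standard CSV + control-file layout
#'
#' Emits `geno.csv`, `founder_geno.csv`, `map.csv`, `covar.csv`, intensity
#' CSVs when present, and a YAML control file readable by
#' [read_control_file()].
#'
#' @param data A [do_data()] bundle.
#' @param dir Output directory (created if needed).
#' @param control Control file name.
#' @return The control file path, invisibly.
#' @export
write_dataset <- function(data, dir, control = "control.yaml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, file) {
    df <- data.frame(marker = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE,
                     na = "-")
  }
  wm(geno_to_calls(data$geno), "geno.csv")
  wm(matrix(c("A", "B")[data$founders + 1L], nrow(data$founders),
            dimnames = dimnames(data$founders)), "founder_geno.csv")
  utils::write.csv(data$map, file.path(dir, "map.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data$covar, file.path(dir, "covar.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  ctl <- list(geno = "geno.csv", founder_geno = "founder_geno.csv",
              gmap = "map.csv", covar = "covar.csv", geno_transposed = FALSE)
  if (!is.null(data$int_x)) {
    wm2 <- function(m, file) {
      df <- data.frame(marker = rownames(m), signif(m, 6), check.names = FALSE)
      utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
    }
    wm2(data$int_x, "intensity_x.csv")
    wm2(data$int_y, "intensity_y.csv")
    ctl$intensity_x <- "intensity_x.csv"
    ctl$intensity_y <- "intensity_y.csv"
  }
  path <- file.path(dir, control)
  yaml::write_yaml(ctl, path)
  invisible(path)
}
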