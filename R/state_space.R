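# 36-state diplotype space for an 8-founder population.
#
# A diplotype is an unordered pair of founder haplotypes.  With founders
# labeled A..H there are 36 states: 8 homozygous (AA..HH) and 28
# heterozygous.  States are ordered lower-triangle row-wise:
#   AA, AB, BB, AC, BC, CC, ..., AH, BH, ..., HH
# so state (j,k) with j <= k has index k(k-1)/2 + j.  All serialized output
# uses the two-letter labels, never the indices.

#' Diplotype state space
#'
#' The 36 unordered founder-pair states for an eight-founder population,
#' in the package's fixed lower-triangle row-wise order.
#'
#' @return Data frame with one row per state: `state` (index 1..36),
#'   `hap1`, `hap2` (founder indices, `hap1 <= hap2`), `label` (two founder
#'   letters, e.g. `"AB"`), and `homozygous`.
#' @examples
#' head(dip_states())
#' @export
dip_states <- function() {
  if (is.null(.doqc_cache$states)) {
    k <- rep.int(seq_len(8L), seq_len(8L))
    j <- unlist(lapply(seq_len(8L), seq_len), use.names = FALSE)
    .doqc_cache$states <- data.frame(
      state = seq_along(j), hap1 = j, hap2 = k,
      label = paste0(LETTERS[j], LETTERS[k]),
      homozygous = j == k, stringsAsFactors = FALSE)
  }
  .doqc_cache$states
}

#' State index for a founder pair
#'
#' @param hap1,hap2 Founder indices in 1..8 (order irrelevant); vectorized.
#' @return Integer state index in 1..36.
#' @examples
#' dip_state_index(2, 1)  # "AB"
#' @export
dip_state_index <- function(hap1, hap2) {
  j <- pmin(hap1, hap2)
  k <- pmax(hap1, hap2)
  as.integer(k * (k - 1L) / 2L + j)
}

#' Stationary diplotype distribution
#'
#' Under random mating each ordered founder pair has probability 1/64, so
#' each homozygous state has probability 1/64 and each heterozygous state
#' 2/64.  Used as the initial distribution of the diplotype HMM.
#'
#' @return Numeric vector of length 36, summing to 1.
#' @export
dip_stationary <- function() {
  st <- dip_states()
  ifelse(st$homozygous, 1 / 64, 2 / 64)
}

# Minimal switch distance between two unordered founder pairs:
# 0 if equal as multisets, 1 if they share exactly one founder, 2 if
# disjoint.  Summing this over consecutive called diplotypes gives the
# minimum number of crossovers consistent with the calls.
dip_distance_matrix <- function() {
  if (is.null(.doqc_cache$distmat)) {
    st <- dip_states()
    n <- nrow(st)
    D <- matrix(0L, n, n, dimnames = list(st$label, st$label))
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        a1 <- st$hap1[s]; b1 <- st$hap2[s]
        a2 <- st$hap1[t]; b2 <- st$hap2[t]
        shared <- if (a1 == a2 && b1 == b2) 2L
          else if (a1 == a2 || a1 == b2 || b1 == a2 || b1 == b2) 1L
          else 0L
        D[s, t] <- 2L - shared
      }
    }
    .doqc_cache$distmat <- D
  }
  .doqc_cache$distmat
}

# SNP genotype (0/1/2 = count of B alleles) implied by each diplotype state
# at one marker, given the founder codes (0 = A, 1 = B, NA) at that marker.
# Returns a length-36 integer vector with NA where a contributing founder
# call is missing.
dip_snp_genotype <- function(founder_codes) {
  st <- dip_states()
  founder_codes[st$hap1] + founder_codes[st$hap2]
}
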