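# 36-state diplotype hidden Markov model.
#
# Each DO genome is a mosaic of the eight founder haplotypes.  The hidden
# state at a marker is the unordered founder pair (diplotype); the two
# haplotypes are modeled as independent chains (random mating, autosomes
# only).  Along one haplotype the founder label follows an exchangeable
# exponential-mosaic kernel: over an interval of effective length d cM the
# founder is redrawn uniformly from the 8 founders (self allowed) with
# probability 1 - exp(-a d / 100), where a = (8/7) * n_gen_eff reflects
# the accumulated recombination density of the outbreeding generations.
# Marker distances are converted to recombination fractions with the
# Carter-Falconer map function (interference) before entering the kernel.
# Emissions compare the SNP genotype implied by the diplotype and the
# founder alleles against the observed call, with a symmetric genotyping
# error rate epsilon (default 0.2%).

#' HMM parameters
#'
#' @param epsilon Genotyping error rate assumed by the emission model
#'   (default 0.002, i.e. 0.2%).
#' @param n_gen_eff Effective switch-density parameter of the founder
#'   mosaic (expected crossovers per haplotype per Morgan).  `NULL` (the
#'   default) derives it per sample from the `generation` covariate via
#'   [do_gen_eff()]; a single number applies to all samples.
#' @param map_function `"carter_falconer"` (default) or `"haldane"`,
#'   used to convert marker distances to recombination fractions.
#' @param error_lod_cap Cap on the absolute genotyping-error LOD score
#'   (guards against infinite values when a posterior is exactly 0 or 1).
#' @param call_threshold Minimum marginal probability for a diplotype call.
#' @return List of class `"hmm_params"`.
#' @export
hmm_params <- function(epsilon = 0.002, n_gen_eff = NULL,
                       map_function = c("carter_falconer", "haldane"),
                       error_lod_cap = 12, call_threshold = 0.5) {
  stopifnot(epsilon > 0, epsilon < 0.5,
            is.null(n_gen_eff) || all(n_gen_eff > 0))
  structure(list(epsilon = epsilon, n_gen_eff = n_gen_eff,
                 map_function = match.arg(map_function),
                 error_lod_cap = error_lod_cap,
                 call_threshold = call_threshold),
            class = "hmm_params")
}

#' Effective switch density for a DO generation
#'
#' Calibrates the mosaic density parameter so that the expected genome-wide
#' diploid crossover count, `2 * n_gen_eff * L` over an autosomal map of
#' length `L` Morgans, matches the average counts observed in DO mice:
#' 304 at outbreeding generation 8 and 357 at generation 11, interpolated
#' linearly in generation.  On the ~14 Morgan mouse autosomal map this
#' gives 10.86 (gen 8) and 12.75 (gen 11) crossovers per haplotype per
#' Morgan; for a simulated genome, pass its own map length so simulated
#' counts land on the same scale.
#'
#' @param generation Outbreeding generation number(s).
#' @param map_length_M Autosomal map length in Morgans (default 14, the
#'   mouse autosomes).
#' @return Effective switch density (crossovers per haplotype per Morgan).
#' @examples
#' do_gen_eff(8)   # ~10.86
#' do_gen_eff(11)  # 12.75
#' @export
do_gen_eff <- function(generation, map_length_M = 14) {
  (304 + 53 * (generation - 8) / 3) / (2 * map_length_M)
}

# total autosomal map length (Morgans) of a genetic map data frame
autosomal_map_length <- function(map) {
  auto <- !(map$chr %in% c("X", "Y", "M", "MT"))
  sum(tapply(map$pos[auto], map$chr[auto], function(p) diff(range(p)))) / 100
}

# single-haplotype founder-exchange probability over d cM
hap_switch_prob <- function(d_cM, n_gen_eff) {
  a <- (8 / 7) * n_gen_eff
  1 - exp(-a * d_cM / 100)
}

#' Diplotype transition matrix for one marker interval
#'
#' Built from two independent single-haplotype chains.  Each haplotype
#' stays in its founder with probability `exp(-a d/100) + (1 -
#' exp(-a d/100))/8` and moves to each other founder with probability
#' `(1 - exp(-a d/100))/8`, `a = (8/7) n_gen_eff`.  Ordered-pair products
#' are collapsed onto the 36 unordered states.  When `use_map_function` is
#' `TRUE` the interval length is first converted to a recombination
#' fraction r (floored at 1e-8) and the kernel is evaluated at the
#' effective distance 100*r, so that map-function interference shortens
#' long intervals; the simulator uses the raw distance.
#'
#' @param d_cM Interval length in cM.
#' @param params [hmm_params()]; `n_gen_eff` must be a single number here.
#' @param use_map_function Convert d to r first (default `TRUE`).
#' @return 36 x 36 stochastic matrix (rows sum to 1).
#' @export
transition_matrix <- function(d_cM, params = hmm_params(n_gen_eff = do_gen_eff(8)),
                              use_map_function = TRUE) {
  stopifnot(d_cM >= 0, length(params$n_gen_eff) == 1)
  d_eff <- if (use_map_function) 100 * map_forward(d_cM, params$map_function)
           else d_cM
  p_sw <- hap_switch_prob(d_eff, params$n_gen_eff)
  P1 <- matrix(p_sw / 8, 8, 8)
  diag(P1) <- (1 - p_sw) + p_sw / 8
  st <- dip_states()
  j <- st$hap1; k <- st$hap2
  # T[s,t] = P1[j_s,j_t] P1[k_s,k_t] + [t het] P1[j_s,k_t] P1[k_s,j_t]
  M1 <- P1[j, j] * P1[k, k]
  M2 <- P1[j, k] * P1[k, j]
  het_t <- matrix(!st$homozygous, 36, 36, byrow = TRUE)
  out <- M1 + M2 * het_t
  dimnames(out) <- list(st$label, st$label)
  out
}

# cached transition matrix lookup (keyed by interval, density, map function)
cached_transition <- function(d_cM, n_gen_eff, map_function) {
  key <- sprintf("T|%.10g|%.10g|%s", d_cM, n_gen_eff, map_function)
  if (is.null(.doqc_cache[[key]])) {
    p <- hmm_params(n_gen_eff = n_gen_eff, map_function = map_function)
    .doqc_cache[[key]] <- transition_matrix(d_cM, p)
  }
  .doqc_cache[[key]]
}

#' Emission probabilities for one observed call
#'
#' For state (j,k) the implied SNP genotype is the sum of founder alleles
#' j and k; the emission is `1 - epsilon` if the observation matches it and
#' `epsilon/2` otherwise (symmetric three-state confusion).  A missing
#' observation gives 1 for every state; a missing founder call gives 1 for
#' every state involving that founder (no information).
#'
#' @param obs Observed genotype code (0/1/2/NA).
#' @param founder_codes Length-8 integer vector of founder alleles (0/1/NA)
#'   at the marker.
#' @param epsilon Genotyping error rate.
#' @return Numeric vector of length 36.
#' @export
emission_probs <- function(obs, founder_codes, epsilon = 0.002) {
  g <- dip_snp_genotype(founder_codes)
  if (is.na(obs)) return(rep(1, 36))
  ifelse(is.na(g), 1, ifelse(g == obs, 1 - epsilon, epsilon / 2))
}

# emission matrix for one sample on one chromosome: markers x 36
emission_matrix <- function(obs_vec, founder_sub, epsilon) {
  st <- dip_states()
  G <- founder_sub[, st$hap1, drop = FALSE] + founder_sub[, st$hap2, drop = FALSE]
  E <- matrix(1, nrow(founder_sub), 36)
  ok <- !is.na(obs_vec)
  if (any(ok)) {
    Gk <- G[ok, , drop = FALSE]
    match_ <- Gk == obs_vec[ok]
    Ek <- ifelse(is.na(Gk), 1, ifelse(match_, 1 - epsilon, epsilon / 2))
    E[ok, ] <- Ek
  }
  E
}

# scaled forward-backward for one sample on one chromosome.
# E: markers x 36 emissions; trans: list of length m-1 of 36x36 matrices;
# init: length-36 initial distribution.  Returns list(posterior, loglik).
forward_backward_core <- function(E, trans, init) {
  m <- nrow(E)
  alpha <- matrix(0, m, 36)
  sc <- numeric(m)
  a <- init * E[1, ]
  sc[1] <- sum(a)
  alpha[1, ] <- a / sc[1]
  if (m > 1) {
    for (t in 2:m) {
      a <- (alpha[t - 1, ] %*% trans[[t - 1]])[1, ] * E[t, ]
      sc[t] <- sum(a)
      alpha[t, ] <- a / sc[t]
    }
  }
  beta <- matrix(0, m, 36)
  beta[m, ] <- 1
  if (m > 1) {
    for (t in (m - 1):1) {
      b <- trans[[t]] %*% (E[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b[, 1] / sc[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(sc)))
}

#' Diplotype posterior probabilities along the autosomes
#'
#' Runs the scaled forward-backward algorithm per sample and chromosome,
#' starting from the stationary distribution (1/64 per ordered founder
#' pair).  Restricted to autosomes; the X chromosome enters the package
#' only through the intensity- and heterozygosity-based sex checks.
#'
#' @param data A [do_data()] bundle.
#' @param params [hmm_params()].
#' @param markers Markers to use (default: informative autosomal markers).
#' @param samples Sample ids (default: all).
#' @param mask_markers Markers whose observations are treated as missing
#'   (posteriors are still computed at them); used for cleaning-impact
#'   comparisons.
#' @return Object of class `"diplotype_probs"`: a list with one element per
#'   chromosome, each a `markers x 36 x samples` array, with attributes
#'   `map` (the marker subset used) and `loglik`.
#' @export
calc_diplotype_probs <- function(data, params = hmm_params(),
                                 markers = NULL, samples = NULL,
                                 mask_markers = NULL) {
  map <- data$map
  autosomes <- setdiff(unique(map$chr), c("X", "Y", "M", "MT"))
  if (is.null(markers)) {
    markers <- intersect(filter_informative(data$founders),
                         map$marker[map$chr %in% autosomes])
  }
  map <- map[map$marker %in% markers & map$chr %in% autosomes, , drop = FALSE]
  if (is.null(samples)) samples <- colnames(data$geno)
  ngen <- params$n_gen_eff
  if (is.null(ngen)) {
    gen <- data$covar$generation[match(samples, data$covar$id)]
    if (any(is.na(gen)))
      stop("n_gen_eff not given and generation missing for some samples")
    ngen <- do_gen_eff(gen, autosomal_map_length(data$map))
  } else if (length(ngen) == 1) {
    ngen <- rep(ngen, length(samples))
  }
  init <- dip_stationary()
  st_labels <- dip_states()$label
  out <- list()
  loglik <- matrix(NA_real_, length(unique(map$chr)), length(samples),
                   dimnames = list(unique(map$chr), samples))
  for (chr in unique(map$chr)) {
    mchr <- map[map$chr == chr, , drop = FALSE]
    mk <- mchr$marker
    d <- diff(mchr$pos)
    fsub <- data$founders[mk, , drop = FALSE]
    gsub <- data$geno[mk, samples, drop = FALSE]
    if (!is.null(mask_markers)) gsub[rownames(gsub) %in% mask_markers, ] <- NA
    arr <- array(NA_real_, c(length(mk), 36, length(samples)),
                 dimnames = list(mk, st_labels, samples))
    for (si in seq_along(samples)) {
      trans <- lapply(d, cached_transition, n_gen_eff = ngen[si],
                      map_function = params$map_function)
      E <- emission_matrix(gsub[, si], fsub, params$epsilon)
      fb <- forward_backward_core(E, trans, init)
      arr[, , si] <- fb$posterior
      loglik[chr, si] <- fb$loglik
    }
    out[[chr]] <- arr
  }
  structure(out, map = map, loglik = loglik, epsilon = params$epsilon,
            class = "diplotype_probs")
}

#' Collapse diplotype posteriors to SNP genotype probabilities
#'
#' Each diplotype's posterior mass is added to the SNP genotype it implies
#' given the founder alleles.  Markers with incomplete founder genotypes
#' are left `NA` (the collapse is only partial there).
#'
#' @param probs A `"diplotype_probs"` object.
#' @param founders Integer founder matrix.
#' @return List per chromosome of `markers x 3 x samples` arrays with
#'   genotype dimension `AA`, `AB`, `BB`.
#' @export
snp_genotype_probs <- function(probs, founders) {
  st <- dip_states()
  lapply(unclass(probs), function(arr) {
    mk <- dimnames(arr)[[1]]
    fsub <- founders[mk, , drop = FALSE]
    G <- fsub[, st$hap1, drop = FALSE] + fsub[, st$hap2, drop = FALSE]
    complete <- rowSums(is.na(fsub)) == 0
    out <- array(NA_real_, c(length(mk), 3, dim(arr)[3]),
                 dimnames = list(mk, c("AA", "AB", "BB"), dimnames(arr)[[3]]))
    for (g in 0:2) {
      W <- (G == g) & complete  # markers x 36 indicator
      W[is.na(W)] <- FALSE
      for (si in seq_len(dim(arr)[3])) {
        p <- matrix(arr[, , si], nrow = length(mk))
        out[complete, g + 1, si] <- rowSums(p * W)[complete]
      }
    }
    out
  })
}

#' Single-marker collapse of a 36-state posterior
#'
#' @param posterior Length-36 posterior vector.
#' @param founder_codes Length-8 founder allele vector (0/1/NA) at the
#'   marker.
#' @return Named numeric vector `(AA, AB, BB)`, or all `NA` when the
#'   founder genotypes are incomplete.
#' @export
collapse_to_snp_probs <- function(posterior, founder_codes) {
  if (any(is.na(founder_codes)))
    return(stats::setNames(rep(NA_real_, 3), c("AA", "AB", "BB")))
  g <- dip_snp_genotype(founder_codes)
  stats::setNames(vapply(0:2, function(x) sum(posterior[g == x]), 0),
                  c("AA", "AB", "BB"))
}

#' Max-marginal diplotype calls
#'
#' At each marker the state with the highest marginal posterior is called,
#' provided its probability exceeds the threshold (strictly); otherwise the
#' call is missing.
#'
#' @param probs A `"diplotype_probs"` object.
#' @param threshold Minimum posterior probability (default 0.5).
#' @return List per chromosome of integer `markers x samples` matrices of
#'   state indices (1..36, NA when uncalled).
#' @export
call_max_marginal <- function(probs, threshold = 0.5) {
  lapply(unclass(probs), function(arr) {
    out <- matrix(NA_integer_, dim(arr)[1], dim(arr)[3],
                  dimnames = dimnames(arr)[c(1, 3)])
    for (si in seq_len(dim(arr)[3])) {
      p <- matrix(arr[, , si], nrow = dim(arr)[1])
      mx <- max.col(p, ties.method = "first")
      pm <- p[cbind(seq_len(nrow(p)), mx)]
      out[, si] <- ifelse(pm > threshold, mx, NA_integer_)
    }
    out
  })
}

#' Predicted SNP genotypes from called diplotypes
#'
#' Maps each called diplotype through the founder alleles to an AA/AB/BB
#' genotype; missing calls and incomplete founder genotypes give NA.
#'
#' @param calls Output of [call_max_marginal()].
#' @param founders Integer founder matrix.
#' @return Integer genotype matrix (markers x samples) over the called
#'   markers of all chromosomes.
#' @export
predicted_snp_genotypes <- function(calls, founders) {
  st <- dip_states()
  res <- lapply(calls, function(cm) {
    fsub <- founders[rownames(cm), , drop = FALSE]
    out <- matrix(NA_integer_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
    for (si in seq_len(ncol(cm))) {
      s <- cm[, si]
      ok <- !is.na(s)
      out[ok, si] <- fsub[cbind(which(ok), st$hap1[s[ok]])] +
        fsub[cbind(which(ok), st$hap2[s[ok]])]
    }
    out
  })
  do.call(rbind, res)
}

#' Genotyping-error LOD scores
#'
#' For each non-missing observed genotype at a marker with complete founder
#' genotypes, the score is
#' `log10((1 - q) / q) + log10((1 - epsilon) / epsilon)`,
#' where `q` is the posterior probability of the observed SNP genotype from
#' the collapsed diplotype probabilities (computed from the full data,
#' including the site itself).  Large scores flag observations that the
#' flanking-marker information contradicts; scores above 2 are the usual
#' "potential error" threshold.  Scores are capped at `+/- cap`.
#'
#' @param snp_probs Output of [snp_genotype_probs()].
#' @param geno Observed genotype matrix.
#' @param epsilon Genotyping error rate used in the prior odds term.
#' @param cap Absolute cap on the score (default 12).
#' @return Data frame with columns `sample`, `marker`, `chr`, `obs`
#'   (observed call), `qy` (posterior probability of the observation), and
#'   `lod`.
#' @export
error_lod_table <- function(snp_probs, geno, epsilon = 0.002, cap = 12) {
  prior <- log10((1 - epsilon) / epsilon)
  res <- lapply(names(snp_probs), function(chr) {
    arr <- snp_probs[[chr]]
    mk <- dimnames(arr)[[1]]
    samples <- dimnames(arr)[[3]]
    gsub <- geno[mk, samples, drop = FALSE]
    qAA <- matrix(arr[, 1, ], nrow = length(mk))
    idx <- which(!is.na(gsub) & !is.na(qAA), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    obs <- gsub[idx]
    qy <- arr[cbind(idx[, 1], obs + 1L, idx[, 2])]
    lod <- log10((1 - qy) / qy) + prior
    lod <- pmin(pmax(lod, -cap), cap)
    data.frame(sample = samples[idx[, 2]], marker = mk[idx[, 1]],
               chr = chr, obs = geno_to_calls(obs), qy = qy, lod = lod,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genotyping-error LOD score at a single site
#'
#' @param p Named probability vector `(AA, AB, BB)` for the site.
#' @param obs Observed genotype (`"AA"/"AB"/"BB"` or code 0/1/2).
#' @param epsilon Genotyping error rate.
#' @param cap Absolute cap on the score.
#' @return The LOD score, or `NA` for a missing observation.
#' @examples
#' genotyping_error_lod(c(AA = 0.5, AB = 0.3, BB = 0.2), "AA")  # ~2.698
#' @export
genotyping_error_lod <- function(p, obs, epsilon = 0.002, cap = 12) {
  if (length(obs) != 1 || is.na(obs)) return(NA_real_)
  if (is.character(obs)) obs <- match(obs, c("AA", "AB", "BB")) - 1L
  qy <- p[obs + 1L]
  lod <- log10((1 - qy) / qy) + log10((1 - epsilon) / epsilon)
  unname(pmin(pmax(lod, -cap), cap))
}

#' Sum of absolute differences between two posteriors
#'
#' Measures the change in diplotype probabilities before and after data
#' cleaning; ranges from 0 (identical) to 2 (disjoint supports).
#'
#' @param post_before,post_after Probability vectors (or matrices /
#'   `markers x states x samples` arrays of matching shape, in which case
#'   the sum runs over the state dimension).
#' @return Numeric: scalar for vectors, `markers x samples` matrix for
#'   arrays.
#' @export
posterior_abs_diff <- function(post_before, post_after) {
  stopifnot(identical(dim(post_before), dim(post_after)))
  d <- abs(post_before - post_after)
  if (is.null(dim(d))) return(sum(d))
  if (length(dim(d)) == 2) return(rowSums(d))
  apply(d, c(1, 3), sum)
}
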