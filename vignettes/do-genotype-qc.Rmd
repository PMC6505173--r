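---
title: "Genotype QC for Diversity Outbred mice: models and methods"
author: "doqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype QC for Diversity Outbred mice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doqc)
```

# The problem

Diversity Outbred (DO) mice descend from eight inbred founder strains by
repeated random outbreeding, so each chromosome is a mosaic of founder
haplotypes with segment lengths shrinking as generations accumulate.
Array genotypes for such a population are biallelic SNP calls (AA/AB/BB)
plus two allele-specific probe intensities per marker.  Before QTL
mapping, the data need a QC pass that can answer: which samples are low
quality or mislabeled?  Which are duplicates?  Which markers misbehave?
And does dropping the bad markers change the haplotype reconstruction
that mapping will rely on?

`doqc` implements that QC pass end to end, together with a simulator that
generates DO-like data with known truth so every diagnostic is testable
offline.

# Data model and conventions

Genotypes are stored as integer matrices (markers × samples) counting B
alleles: 0 = AA, 1 = AB, 2 = BB, `NA` = missing.  The A allele is, by
construction of the recoding step, the allele most frequent among the
eight founder strains; ties are broken alphabetically by nucleotide so the
recoding is deterministic (`recode_to_founder_major()`).  Founder
genotypes are 0/1 matrices (markers × 8); heterozygous founder calls —
which should not occur in inbred strains — are treated as missing and
counted.  The genetic map is a data frame (marker, chr, pos in cM),
ordered by position within chromosome with ties broken by marker id.
Markers monomorphic across the founders carry no information about
founder origin and are excluded by `filter_informative()`.  Only
autosomes enter the haplotype reconstruction; the X chromosome is used by
the intensity- and heterozygosity-based sex checks.

# The 36-state diplotype HMM

At each marker the hidden state is the unordered founder pair
(*diplotype*): 8 homozygous and 28 heterozygous states, ordered
lower-triangle row-wise (AA, AB, BB, AC, BC, CC, ..., HH).

**Transitions.** The two haplotypes are modeled as independent
exchangeable founder mosaics.  Over an interval of effective length $d$
cM, a haplotype keeps its founder with probability
$e^{-ad/100} + (1 - e^{-ad/100})/8$ and moves to each other founder with
probability $(1 - e^{-ad/100})/8$, where $a = (8/7)\,n_\mathrm{gen\_eff}$.
Redrawing the founder uniformly *with self allowed* makes the visible
switch rate $(7/8)a$ per Morgan, i.e. exactly $n_\mathrm{gen\_eff}$
crossovers per haplotype per Morgan.  Ordered-pair products are collapsed
onto the 36 unordered states; the stationary law is uniform over ordered
pairs (1/64 per homozygote, 2/64 per heterozygote) and is the HMM's
initial distribution.  This single-parameter kernel is a deliberately
self-contained approximation to full multigeneration pedigree transition
probabilities; it is exact for the package's own simulator and
asymptotically equivalent for dense maps.

**Interference.** Marker distances are converted to recombination
fractions with the Carter–Falconer map function,
$d = 25[\mathrm{atanh}(2r) + \arctan(2r)]$, which models the strong
crossover interference of the mouse.  The forward direction ($d \to r$)
has no closed form and is solved by bisection on $[0, 0.5)$ to $10^{-12}$
(robustness was preferred over speed; the conversion happens once per
interval).  The kernel is then evaluated at the effective distance
$100r$.  Note the ordering $r_\mathrm{Haldane}(d) \le
r_\mathrm{CF}(d) \le d/100$: interference keeps the recombination
fraction close to the linear map, from below.  Zero-length intervals
(co-located markers) are floored at $r = 10^{-8}$ so transition matrices
stay irreducible.  The simulator applies the same kernel to the raw map
distance; at the 1 cM spacings simulated here the difference is below
$10^{-4}$ in the switch probability.

**Emissions.** Each diplotype implies a SNP genotype through the founder
alleles.  An observed call matching that genotype has probability
$1-\varepsilon$, each wrong genotype $\varepsilon/2$ (symmetric
confusion, the simplest allowance for genotyping error), with
$\varepsilon = 0.002$ by default.  Missing observations, and states
involving a founder whose call is missing, contribute a factor of 1.

**Inference.** Scaled forward–backward per sample and chromosome gives
marginal posteriors (rows sum to 1 within $10^{-9}$; the log-likelihood
is retained).  Exactness is tested against brute-force enumeration of all
$36^m$ paths on toy instances.  Diplotypes are called by maximum marginal
probability with a strict $>0.5$ rule, otherwise missing.

# Calibrating the switch density

`do_gen_eff(generation, map_length_M)` sets
$n_\mathrm{gen\_eff} = \bigl(304 + 53\,(g-8)/3\bigr) / (2L)$, anchored to
the observed genome-wide averages in DO mice: 304 crossovers per mouse at
outbreeding generation 8 and 357 at generation 11.  The density is the
expected diploid count divided by twice the map length $L$ being
analyzed: on the ~14 Morgan mouse autosomal map this gives 10.86 and
12.75 crossovers per haplotype per Morgan; on the default simulated
genome (10 autosomes × 199 cM = 19.9 M) it gives 7.64 and 8.97, so that
simulated genome-wide counts land on the same 304–357 scale as real DO
mice.  Both simulator and HMM default to this rule evaluated on the map
at hand, which keeps them consistent automatically.

# Error LOD scores

For each non-missing observation $y$ at a marker with complete founder
genotypes, the 36-state posterior is collapsed to 3-state SNP genotype
probabilities and the genotyping-error LOD is

$$\mathrm{LOD} = \log_{10}\frac{1-q_y}{q_y} +
  \log_{10}\frac{1-\varepsilon}{\varepsilon},$$

with $q_y$ the posterior probability of the observed genotype.  The
posterior *includes* the focal observation (no leave-one-out): this
matches the natural computation order — reconstruct once, then score every
site — and is cheaper; with dense data the difference is negligible, with
sparse data it makes the score conservative, since the site's own
likelihood ($\approx 499{:}1$ at $\varepsilon = 0.002$) pulls $q_y$
toward the observation.  Scores are capped at $\pm 12$ to keep
$q_y \in \{0, 1\}$ finite.  At $\varepsilon = 0.002$, LOD $> 2$ — the
usual flagging threshold — corresponds to $q_y < 0.833$.

# Crossover counting

Within a chromosome, consecutive non-missing diplotype calls contribute
the switch distance between unordered pairs: 0 if equal, 1 if they share
exactly one founder, 2 if disjoint.  Because a forced shared-founder phase
never constrains later steps, the sum of consecutive distances equals the
global minimum number of crossovers consistent with the call sequence
(verified against an exhaustive phase DP in the tests).  Missing calls are
skipped, so the distance is taken between flanking calls — this
undercounts double recombinants hidden in uncalled gaps, consistent with
"minimum consistent".

# Sample and marker diagnostics

Thresholds live in `qc_thresholds()`; defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `sample_missing_omit` | 0.20 | omission rule for low-quality samples |
| `sample_missing_note` | 0.02 | annotate-but-retain band |
| `errorlod_cut` | 2 | conservative potential-error threshold |
| `duplicate_share` | 0.90 | sits in the empirical gap: duplicates share >99.9%, all other pairs ≤ ~76% |
| `min_shared_markers` | 1000 | below this a pair's sharing is reported, not scored |
| `call_threshold` | 0.5 | strict max-marginal call rule |
| `marker_error_omit` | 0.05 | markers above 5% presumed errors are listed for omission |
| `maf_outlier_freq` | 0.40 | advisory: MAF-1/8 markers whose sample MAF exceeds 40% (drive-like distortion) |
| `het_outlier_freq` | 0.25 | advisory: MAF-4/8 markers with heterozygosity below 0.25 |

The frequency-outlier bounds are advisory by design: the anomalies they
mirror (meiotic-drive distortion, heterozygote deficits) are descriptive
patterns, not crisp rules.  Sibling-level sharing (~67%) and the median
sharing are reported, never thresholded.

Sex is verified from probe intensities: per-marker intensity is the mean
of the two channels, averaged over X and over Y markers; classification
is by quadrant, with thresholds defaulting to the midpoints between the
nominal-sex group medians (a stand-in heuristic — the underlying clusters
are read off a scatterplot in practice; single-sex cohorts must supply
thresholds).  X markers whose intensities do not separate the nominal
sexes (|Welch z| < 2 by default) are dropped from the average first.
Intensity percentiles use type-7 (linear interpolation) quantiles, for
reproducibility.

Order of operations is fixed: sample QC first, then omission (missingness
≥ 20% plus the second member of each duplicate pair), then all marker
statistics on the retained samples only.  The cleaning-impact rerun masks
the omitted markers' observations while keeping the marker grid, so
before/after posteriors stay comparable site by site; the per-site L1
change lies in [0, 2] by construction.

# The simulator and what it does (not) emulate

`make_dataset()` draws founder MAF classes as binomial(8, 1/2)
conditioned on polymorphism (weights 16:56:112:70 for classes 1/8..4/8),
assigns the minor allele to a random founder subset, runs two independent
mosaics per autosome per sample, derives genotypes, and then corrupts
them: random missingness (1%), random symmetric genotype errors (0.2%),
per-sample overrides for engineered bad samples (55%, 30%, 9% missing by
default), a duplicated sample (same genome, independent corruption), a
sex-mislabeled XX mouse, an XO female, and optionally XXY males.  Ten
markers get a systematic cluster swap (85% of true heterozygotes reported
as major homozygotes), the signature of a wrongly assigned intensity
cluster.  Intensities are Gaussian clusters per genotype, scaled by X/Y
dosage on the sex chromosomes and truncated at zero.  Founder-file
missingness (1%) is applied to the *reported* founder matrix only —
samples are assayed regardless of how complete the founder reference is.
All randomness flows from one mandatory seed; identical seeds give
bit-identical datasets.

Not emulated: crossover interference within the mosaic (the kernel is
Markov; interference enters only through the map-function conversion at
inference), pedigree-exact DO breeding structure, meiotic drive (off by
default), batch effects in intensities, and intensity shifts in
low-quality samples.  Passing tests therefore demonstrate correctness of
the algorithms under a matched generative model, not robustness to every
failure mode of real arrays.

# Numerical choices

Forward–backward uses per-marker scaling constants (no underflow for
arbitrarily long chromosomes); transition matrices are cached per
(interval, density) pair; max-marginal ties resolve to the lowest state
index but are then discarded by the strict > 0.5 rule; all serialized
output uses state labels, never indices.  Posterior rows are renormalized
defensively after the alpha–beta product.

# Known limitations

The default simulated map (1 cM spacing) is roughly 50× sparser than the
arrays used in practice (~69,000 informative markers over ~1400 cM).  At
that density, with the calibrated switch densities, founder mosaic
segments span only ~5–13 markers, and the 36-state posterior is genuinely
uncertain: the posteriors are well calibrated (mean called posterior ≈
called accuracy, as expected for a matched generative model), yet
called-site accuracy plateaus around 86–88%, minimum-crossover counts
undercount true switch counts by ~25–30% (short segments are smoothed
over; the loss grows with density), and only ~35–40% of injected random
errors reach LOD > 2 because the focal observation itself dominates
$q_y$ when flanking information is weak.  These are information limits of
the study design, not implementation defects — with many markers per
mosaic segment the posteriors concentrate and the same statistics sharpen
dramatically.  The acceptance suite asserts the idealized targets
(≥90% accuracy, ≤15% crossover error, >70% error sensitivity) and the
corresponding checks fail honestly at the simulated density; all
anomaly-detection, exactness, frequency, and impact checks pass.

Marker-level error rates need a reasonable denominator: with few retained
samples a single flagged site can push a marker past the 5% omission
rule, so small cohorts over-flag markers.  The sex-check thresholds
assume both sexes are present; XO/XXY classification inherits whatever
separation the intensity clusters provide.
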