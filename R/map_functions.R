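# Genetic map functions.
#
# The Carter-Falconer map function models the strong crossover interference
# seen in the mouse.  The closed form maps a recombination fraction r to a
# map distance d (in cM):
#     d(r) = 25 * [atanh(2r) + atan(2r)]
# The forward direction (d -> r) has no closed form and is obtained by
# bisection on [0, 0.5).  Haldane's function (no interference) is kept as a
# cross-check baseline.

#' Carter-Falconer map function: recombination fraction to distance
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centiMorgans: `25 * (atanh(2r) + atan(2r))`.
#' @examples
#' cf_inverse(0.1)   # about 10.0032 cM
#' @seealso [cf_forward()]
#' @export
cf_inverse <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must be in [0, 0.5)")
  25 * (atanh(2 * r) + atan(2 * r))
}

#' Carter-Falconer map function: distance to recombination fraction
#'
#' Inverts [cf_inverse()] by bisection on the bracket `[0, 0.5 - 1e-12]`;
#' the function is strictly increasing so the root is unique.  Very large
#' distances saturate toward 0.5.
#'
#' @param d Map distance(s) in centiMorgans, `>= 0`.
#' @param tol Convergence tolerance in `r` units.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' cf_forward(10.0032)  # about 0.1
#' @export
cf_forward <- function(d, tol = 1e-12) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be >= 0")
  lo <- rep(0, length(d))
  hi <- rep(0.5 - 1e-12, length(d))
  # saturate: beyond cf_inverse(hi) (~365 cM) return the upper bracket end
  sat <- d >= cf_inverse(0.5 - 1e-12)
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    below <- cf_inverse(mid) < d
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  r <- (lo + hi) / 2
  r[sat] <- 0.5 - 1e-12
  r[d == 0] <- 0
  r
}

#' Haldane map function
#'
#' No-interference baseline: `r = (1 - exp(-2d/100)) / 2` and its inverse.
#'
#' @param d Map distance(s) in cM.
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return `haldane_forward()`: recombination fraction; `haldane_inverse()`:
#'   distance in cM.
#' @export
haldane_forward <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be >= 0")
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane_forward
#' @export
haldane_inverse <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

# dispatch d -> r for the HMM; r floored at 1e-8 so co-located markers keep
# an irreducible transition matrix
map_forward <- function(d, map_function = c("carter_falconer", "haldane")) {
  map_function <- match.arg(map_function)
  r <- switch(map_function,
              carter_falconer = cf_forward(d),
              haldane = haldane_forward(d))
  pmax(r, 1e-8)
}
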