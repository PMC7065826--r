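#' Kosambi map function
#'
#' Convert a recombination fraction to a Kosambi map distance in
#' centimorgans, or back.  The Kosambi function,
#' \eqn{d = \frac{1}{4}\log\frac{1+2r}{1-2r}} (Morgans), allows moderate
#' crossover interference and is the standard map function for cereal
#' linkage maps.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return `kosambi_cM`: map distance(s) in cM.
#' @examples
#' kosambi_cM(0.25)          # 25 * log(3) ~ 27.465
#' inverse_kosambi(10)       # 0.5 * tanh(0.2) ~ 0.09867
#' @export
kosambi_cM <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fractions must lie in [0, 0.5)")
  }
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @param d Map distance(s) in cM, `>= 0`.
#' @return `inverse_kosambi`: recombination fraction(s) in `[0, 0.5)`.
#' @export
inverse_kosambi <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("map distances must be finite and >= 0")
  }
  0.5 * tanh(2 * d / 100)
}

# Compose two recombination fractions across adjacent segments assuming no
# interference: r = r1 + r2 - 2*r1*r2 (an odd number of crossovers in
# exactly one of the two segments).
rf_compose <- function(r1, r2) {
  r1 + r2 - 2 * r1 * r2
}

# Probability that the alleles at the two ends of a chain of segments with
# per-segment recombination fractions `rs` are in the parental phase.
# Equals (1 + prod(1 - 2 rs)) / 2.
rf_chain_same <- function(rs) {
  (1 + prod(1 - 2 * rs)) / 2
}
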