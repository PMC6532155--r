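#' Weir-Cockerham Fst for two populations from allele counts
#'
#' Moment estimator of the fixation index between two populations observed
#' as allele counts (suited to pooled sequencing, where genotypes are
#' unavailable). With allele sample sizes \eqn{n_1, n_2} and alternate
#' counts \eqn{x_1, x_2}, the among-population and within-population mean
#' squares are
#' \deqn{MSP = \sum_i n_i (p_i - \bar p)^2, \quad
#'       MSG = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1),}
#' and \eqn{\hat F_{ST} = (MSP - MSG) / (MSP + (n_c - 1) MSG)} with
#' \eqn{n_c = n_1 + n_2 - (n_1^2 + n_2^2)/(n_1 + n_2)}.
#'
#' The raw estimate can be negative (no differentiation) and is returned
#' as-is unless `clamp = TRUE`, which truncates to \[0, 1\] for reporting.
#'
#' @param alt_a,n_a Alternate-allele count and total allele count in
#'   population 1 (vectors allowed, one entry per locus).
#' @param alt_b,n_b Same for population 2.
#' @param clamp Truncate estimates to \[0, 1\]?
#' @return Numeric vector of Fst estimates (`NaN` when the locus is
#'   monomorphic in the pooled sample).
#' @examples
#' wc_fst(32, 32, 0, 32)           # fixed difference -> 1
#' wc_fst(round(0.8 * 32), 32, round(0.2 * 32), 32)
#' @export
wc_fst <- function(alt_a, n_a, alt_b, n_b, clamp = FALSE) {
  check_that(all(n_a >= 1) && all(n_b >= 1),
             "each population needs at least one sampled allele")
  check_that(all(alt_a >= 0 & alt_a <= n_a) && all(alt_b >= 0 & alt_b <= n_b),
             "allele counts must satisfy 0 <= alt <= n")
  p1 <- alt_a / n_a
  p2 <- alt_b / n_b
  comp <- wc_components(p1, n_a, p2, n_b)
  est <- comp$msp_adj / comp$denom
  if (clamp) est <- pmin(pmax(est, 0), 1)
  est
}

# shared variance components; also used by the multi-locus aggregator
wc_components <- function(p1, n1, p2, n2) {
  ntot <- n1 + n2
  nc <- ntot - (n1^2 + n2^2) / ntot  # r - 1 = 1 populations divisor
  pbar <- (n1 * p1 + n2 * p2) / ntot
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2  # / (r - 1) = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  list(msp_adj = msp - msg, denom = msp + (nc - 1) * msg)
}

#' Multi-locus Weir-Cockerham Fst (ratio of sums)
#'
#' Aggregates per-locus variance components as a ratio of sums, the
#' standard genome-wide summary.
#'
#' @inheritParams wc_fst
#' @return A single Fst estimate.
#' @export
wc_fst_global <- function(alt_a, n_a, alt_b, n_b) {
  comp <- wc_components(alt_a / n_a, n_a, alt_b / n_b, n_b)
  keep <- is.finite(comp$msp_adj) & is.finite(comp$denom)
  sum(comp$msp_adj[keep]) / sum(comp$denom[keep])
}
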