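#' Probability of miscalling a heterozygote at a given read depth
#'
#' With `d` reads drawn independently from the two chromosomes of a diploid
#' heterozygote (and no sequencing error), the call is wrong exactly when
#' every read samples the same chromosome: `2 * (1/2)^d = (1/2)^(d-1)`.
#' One read can never reveal a heterozygote (probability 1), two reads give
#' a coin flip (0.5), three reads 1 in 4.
#'
#' @param d integer read depth(s), `>= 1`.
#' @return numeric vector of miscall probabilities.
#' @export
het_miscall_prob <- function(d) {
  d <- as.integer(d)
  if (any(is.na(d)) || any(d < 1L)) stop("read depth must be an integer >= 1")
  0.5^(d - 1)
}

#' Phred genotype quality to error probability, and back
#'
#' GQ is phred-scaled: `GQ = -10 * log10(p)` where `p` is the probability
#' that the genotype call is wrong; so `gq_to_error(20) == 0.01` (a call
#' with GQ 20 is correct with 99% probability) and `error_to_gq(10^-0.5)`
#' is 5, the calling pipeline's minimum.
#'
#' @param gq phred score(s), `>= 0`.
#' @param p error probability/probabilities in `(0, 1]`.
#' @return numeric vector.
#' @export
gq_to_error <- function(gq) {
  if (any(gq < 0)) stop("GQ must be >= 0")
  10^(-gq / 10)
}

#' @rdname gq_to_error
#' @export
error_to_gq <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  -10 * log10(p)
}

#' Expected restriction fragment count for a genome
#'
#' Under uniform independent base composition a `k`-bp recognition site
#' occurs once every `4^k / degeneracy` bases, where `degeneracy` is the
#' number of concrete sequences matching the (possibly IUPAC-degenerate)
#' site; the expected fragment count for a genome of `G` bp is
#' `G * degeneracy / 4^k`. Fragment and cut-site counts are identified
#' (the per-chromosome end-fragment correction is negligible at genome
#' scale and omitted).
#'
#' @param genome_bp genome length in bp (> 0).
#' @param site_len recognition-site length `k` in bp (>= 1).
#' @param degeneracy number of concrete sequences matching the site
#'   (default 1; e.g. 2 for ApeKI's GCWGC).
#' @return expected fragment count.
#' @examples
#' expected_fragments(2.6e9, 6)       # ~6.3e5 for a 6-bp cutter
#' expected_fragments(2.6e9, 5, 2)    # ApeKI
#' @export
expected_fragments <- function(genome_bp, site_len, degeneracy = 1) {
  stopifnot(genome_bp > 0, site_len >= 1, degeneracy >= 1)
  genome_bp * degeneracy / 4^site_len
}
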