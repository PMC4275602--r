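# Balding-Nichols coancestry-adjusted allele and genotype probabilities.
#
# The sampling formula gives the probability that the next allele drawn
# from a subpopulation is of type a, given that m copies of a have been
# seen among n previously drawn copies:
#
#     P(a | m of n) = (m * theta + (1 - theta) * p_a) / (1 + (n - 1) * theta)
#
# where p_a is the reference-population fraction of a and theta (Fst) is
# the coancestry coefficient.  theta = 0 recovers p_a; summing over an
# allele set whose fractions sum to 1 yields 1 for any (m, n).

#' Balding-Nichols conditional allele probability
#'
#' Probability that the next allele sampled from the subpopulation is of a
#' given type, conditional on the allele copies already observed.
#'
#' @param p Reference-population fraction(s) of the allele(s); vectorised.
#' @param m Number of copies of this allele among those already observed
#'   (recycled against `p`).
#' @param n Total number of allele copies already observed.
#' @param theta Coancestry coefficient, in `[0, 1)`.
#' @return Conditional probabilit(y/ies), same length as `p`.
#' @examples
#' bn_conditional(0.1, m = 2, n = 2, theta = 0.03)  # (0.06 + 0.97*0.1)/1.03
#' @export
bn_conditional <- function(p, m, n, theta) {
  if (theta < 0 || theta >= 1) stop("theta must lie in [0, 1)")
  if (any(m > n)) stop("m cannot exceed n")
  (m * theta + (1 - theta) * p) / (1 + (n - 1) * theta)
}

#' Tabulate allele copies of a conditioning set
#'
#' @param alleles Character vector of allele labels (with repetition, one
#'   entry per copy).
#' @return Named integer vector of copy counts.
#' @export
allele_counts <- function(alleles) {
  if (length(alleles) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(as.character(alleles))
  stats::setNames(as.integer(tab), names(tab))
}

#' Coancestry-adjusted genotype probability
#'
#' Probability of an unordered genotype for the next individual sampled
#' from the subpopulation, conditional on previously observed allele
#' copies.  Computed as two sequential draws from the sampling formula
#' (the second draw conditions additionally on the first), times 2 for a
#' heterozygote.
#'
#' @param genotype Character vector of two allele labels (equal for a
#'   homozygote).
#' @param state Named numeric vector of conditioning allele-copy counts
#'   (as from [allele_counts()]), or `NULL` for no conditioning.
#' @param theta Coancestry coefficient, in `[0, 1)`.
#' @param freqs Named numeric vector of reference allele fractions; every
#'   allele of `genotype` must be present.
#' @return The genotype probability.
#' @export
genotype_prob <- function(genotype, state = NULL, theta, freqs) {
  genotype <- as.character(genotype)
  if (length(genotype) != 2L) stop("genotype must have exactly 2 alleles")
  if (anyNA(match(genotype, names(freqs))))
    stop("allele '", setdiff(genotype, names(freqs))[1L],
         "' absent from the frequency table")
  n <- if (is.null(state)) 0 else sum(state)
  m1 <- if (is.null(state)) 0 else state[genotype[1L]]
  if (is.na(m1)) m1 <- 0
  p1 <- bn_conditional(freqs[[genotype[1L]]], m1, n, theta)
  hom <- genotype[1L] == genotype[2L]
  m2 <- if (hom) m1 + 1 else {
    x <- if (is.null(state)) NA_real_ else state[genotype[2L]]
    if (is.na(x)) 0 else x
  }
  p2 <- bn_conditional(freqs[[genotype[2L]]], m2, n + 1, theta)
  unname(if (hom) p1 * p2 else 2 * p1 * p2)
}

#' Coancestry-adjusted match probability
#'
#' Probability that an untyped individual from the same subpopulation has
#' the genotype of the queried contributor: the genotype probability
#' conditioned on the queried genotype itself.  Non-decreasing in `theta`;
#' `theta = 0` gives the Hardy-Weinberg genotype probability.
#'
#' @inheritParams genotype_prob
#' @return The match probability.
#' @export
match_probability <- function(genotype, theta, freqs) {
  genotype_prob(genotype, state = allele_counts(genotype), theta = theta,
                freqs = freqs)
}
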