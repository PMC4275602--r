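# Simulation of genotypes and crime-scene profiles under Hardy-Weinberg
# and linkage equilibria, and Dirichlet (Balding-Nichols) perturbation of
# allele frequencies to emulate an unsampled subpopulation.

#' Simulate a genotype profile from a frequency database
#'
#' Draws, independently at each locus, two alleles with probabilities
#' proportional to the database counts (Hardy-Weinberg equilibrium within
#' loci, linkage equilibrium across loci).  Randomness comes from R's
#' global RNG stream; set a seed for reproducibility.
#'
#' @param db A [freq_db()].
#' @param sample_id Identifier for the simulated profile.
#' @return An [str_profile()].
#' @export
sample_genotype <- function(db, sample_id = "sim") {
  gts <- lapply(db$tables, function(tab) {
    if (length(tab) == 1L) return(rep(names(tab), 2L))
    sort(names(tab)[sample.int(length(tab), 2L, replace = TRUE, prob = tab)])
  })
  structure(list(sample_id = as.character(sample_id), genotypes = gts),
            class = "str_profile")
}

#' Perturb database frequencies via the Balding-Nichols Dirichlet model
#'
#' Draws, per locus, a fresh frequency vector from a Dirichlet
#' distribution with parameters `p * (1 - fst) / fst`, where `p` are the
#' database fractions: the standard model for a subpopulation differing
#' from its reference population by a given coancestry coefficient.  The
#' draw has mean `p` and allele variance approximately
#' `fst * p * (1 - p)`.  Alleles with zero counts are dropped before
#' drawing (their mass is zero before and after).
#'
#' @param db A [freq_db()].
#' @param fst Differentiation parameter, in `(0, 1)`.
#' @return A `freq_db` named `"<name>.perturbed"` whose counts are
#'   pseudo-counts (`frequency * original total`), suitable for
#'   [sample_genotype()] but not for count-based reporting.
#' @export
perturb_frequencies <- function(db, fst) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1)
    stop("fst must lie strictly between 0 and 1")
  scale <- (1 - fst) / fst
  tables <- lapply(db$tables, function(tab) {
    tab <- tab[tab > 0]
    p <- tab / sum(tab)
    g <- stats::rgamma(length(p), shape = p * scale, rate = 1)
    # guard against all-zero gamma draws at tiny shapes
    while (sum(g) == 0) g <- stats::rgamma(length(p), shape = p * scale, rate = 1)
    stats::setNames(g / sum(g) * sum(tab), names(tab))
  })
  structure(list(name = paste0(db$name, ".perturbed"), tables = tables),
            class = "freq_db")
}

#' Combine contributor profiles into a crime-scene profile
#'
#' With neither dropout nor dropin, the CSP at each locus is exactly the
#' union of the contributors' alleles.
#'
#' @param profiles List of [str_profile()] objects sharing a locus panel.
#' @param sample_id Identifier for the resulting CSP.
#' @return A [csp()].
#' @export
make_csp <- function(profiles, sample_id = "csp") {
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("at least one contributor is required")
  loci <- names(profiles[[1L]]$genotypes)
  for (p in profiles[-1L])
    if (!setequal(names(p$genotypes), loci))
      stop("all contributors must share the same locus panel")
  alleles <- lapply(stats::setNames(loci, loci), function(loc)
    sort(unique(unlist(lapply(profiles, function(p) p$genotypes[[loc]]),
                       use.names = FALSE))))
  structure(list(sample_id = as.character(sample_id), alleles = alleles),
            class = "csp")
}
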