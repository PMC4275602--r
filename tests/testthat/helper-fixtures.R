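# Fixtures are generated in code; no data files.

# A database over one or more loci given as named count vectors.
tiny_db <- function(name = "DB", ...) freq_db(name, list(...))

# Random allele counts over k alleles labelled a, b, c, ...; at least one
# positive count.
rand_counts <- function(k, max_count = 50) {
  repeat {
    cnt <- stats::setNames(sample(0:max_count, k, replace = TRUE),
                           letters[seq_len(k)])
    if (sum(cnt) > 0) return(cnt)
  }
}

# A random single-locus two-contributor case: database counts, Q and a
# second contributor drawn from the allele set, CSP = union.
rand_case <- function(n_alleles = 6) {
  cnt <- rand_counts(n_alleles)
  al <- names(cnt)
  gq <- sort(sample(al, 2, replace = TRUE))
  g2 <- sort(sample(al, 2, replace = TRUE))
  A <- sort(unique(c(gq, g2)))
  list(db = tiny_db("D1", L1 = cnt), db2 = tiny_db("D2", L1 = rand_counts(n_alleles)),
       q = str_profile("Q", list(L1 = gq)),
       other = str_profile("O", list(L1 = g2)),
       csp = csp("C", list(L1 = A)),
       counts = cnt, gq = gq, g2 = g2, A = A)
}

# A random case in the forensically realistic regime: many alleles, none
# common (max frequency about 0.26).  Inside this regime the Fst
# adjustment is guaranteed to favour the defence at every locus; with
# common alleles (frequency sums near 1) it need not be.
rand_case_rare <- function() {
  k <- 8
  cnt <- stats::setNames(sample(10:25, k, replace = TRUE), letters[seq_len(k)])
  al <- names(cnt)
  gq <- sort(sample(al, 2, replace = TRUE))
  g2 <- sort(sample(al, 2, replace = TRUE))
  A <- sort(unique(c(gq, g2)))
  list(db = tiny_db("D1", L1 = cnt),
       db2 = tiny_db("D2", L1 = stats::setNames(sample(10:25, k, TRUE), al)),
       q = str_profile("Q", list(L1 = gq)),
       other = str_profile("O", list(L1 = g2)),
       csp = csp("C", list(L1 = A)),
       counts = cnt, gq = gq, g2 = g2, A = A)
}

# Every unordered genotype over an allele set (no size cap; test-side
# counterpart of the engine's capped enumeration).
all_genotypes <- function(alleles) {
  out <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}

# Frequencies with no common allele (pairwise sums well below the level
# at which the theta adjustment can reverse direction).
rand_rare_freqs <- function(k = 8) {
  p <- stats::runif(k, 0.5, 1.5)
  stats::setNames(p / sum(p), letters[seq_len(k)])
}

# A small synthetic family for cheap experiment tests: 4 loci, 6 alleles.
small_family <- function(seed = 42, fst = 0.02, n_loci = 4) {
  sizes <- matrix(500, nrow = n_loci, ncol = 3,
                  dimnames = list(paste0("L", seq_len(n_loci)),
                                  c("P1", "P2", "P3")))
  generate_family(family_spec(c("P1", "P2", "P3"), sizes, n_alleles = 6,
                              fst = fst, seed = seed))
}
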