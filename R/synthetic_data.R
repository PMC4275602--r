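# Synthetic families of related population allele-frequency databases.
#
# Real forensic frequency databases are rarely redistributable, so the
# simulation study runs on generated families with a controlled level of
# between-population differentiation: ancestral frequencies per locus,
# population frequencies drawn around them from the Balding-Nichols
# Dirichlet model, and observation counts drawn multinomially at
# realistic per-locus sample sizes.

# Per-locus allele-observation totals for the five database family
# (columns IC1, IC3, IC4, IC5, IC6): a 16-locus panel with sample sizes
# ranging from a few hundred to several thousand observations, so the
# generated families span the same spread of database sampling noise.
.default_locus_totals <- function() {
  m <- matrix(c(
    6878, 3941, 520, 599, 1202,
    6816, 3918, 514, 598, 1202,
    6870, 3941, 520, 599, 1199,
    6808, 3930, 520, 600, 1195,
    6818, 3927, 514, 600, 1199,
    6877, 3936, 520, 600, 1201,
    6871, 3941, 520, 600, 1202,
    6853, 3938, 516, 600, 1201,
    6702, 3868, 507, 595, 1197,
    6443, 3758, 491, 594, 1176,
    1816, 2482, 421, 498, 954,
    1827, 2508, 426, 504, 959,
    1815, 2499, 416, 500, 912,
    1800, 2473, 420, 493, 943,
    1857, 2543, 437, 499, 945,
    368,  872,  237, 394, 268), ncol = 5, byrow = TRUE)
  dimnames(m) <- list(
    c("D3S1358", "TH01", "D21S11", "D18S51", "D16S539", "VWA", "D8S1179",
      "FGA", "D19S433", "D2S1338", "D22S1045", "D1S1656", "D10S1248",
      "D2S441", "D12S391", "SE33"),
    c("IC1", "IC3", "IC4", "IC5", "IC6"))
  m
}

#' Specification of a synthetic database family
#'
#' @param pop_names Character vector of population names.
#' @param sample_sizes Numeric matrix of per-locus allele-observation
#'   totals, loci in rows (rownames = locus names), populations in
#'   columns.
#' @param n_alleles Number of alleles per locus (>= 2); a single value or
#'   one per locus.
#' @param fst Between-population differentiation: a single value or one
#'   per population, each in `(0, 1)`.
#' @param concentration Symmetric Dirichlet concentration for the
#'   ancestral frequencies (default 1: uniform over the simplex, heavy on
#'   mid-frequency alleles as in real STR panels).
#' @param seed Integer seed making [generate_family()] deterministic.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(pop_names, sample_sizes, n_alleles = 10, fst = 0.02,
                        concentration = 1, seed = 1) {
  n_pops <- length(pop_names)
  if (n_pops < 2L) stop("at least 2 populations are required")
  if (!is.matrix(sample_sizes) || ncol(sample_sizes) != n_pops)
    stop("sample_sizes must be a loci x populations matrix")
  if (is.null(rownames(sample_sizes)))
    stop("sample_sizes must carry locus names as rownames")
  if (any(sample_sizes <= 0)) stop("sample sizes must be positive")
  n_alleles <- rep_len(as.integer(n_alleles), nrow(sample_sizes))
  if (any(n_alleles < 2L)) stop("n_alleles must be >= 2")
  fst <- rep_len(as.numeric(fst), n_pops)
  if (any(fst <= 0 | fst >= 1)) stop("fst values must lie in (0, 1)")
  colnames(sample_sizes) <- pop_names
  structure(list(pop_names = pop_names, sample_sizes = sample_sizes,
                 n_alleles = n_alleles, fst = stats::setNames(fst, pop_names),
                 concentration = concentration, seed = as.integer(seed)),
            class = "family_spec")
}

#' Default synthetic family specification
#'
#' Five populations (IC1, IC3, IC4, IC5, IC6) over a 16-locus STR panel
#' with realistic per-locus allele-observation totals (from under 300 at
#' SE33 in the smallest database to nearly 7000 at the most-typed loci in
#' the largest), 10 alleles per locus and per-population differentiation
#' 0.02.
#'
#' @inheritParams family_spec
#' @return A [family_spec()].
#' @export
default_family_spec <- function(n_alleles = 10, fst = 0.02, seed = 1) {
  m <- .default_locus_totals()
  family_spec(colnames(m), m, n_alleles = n_alleles, fst = fst, seed = seed)
}

#' @export
print.family_spec <- function(x, ...) {
  cat("Synthetic database family spec: ", length(x$pop_names),
      " populations (", paste(x$pop_names, collapse = ", "), "), ",
      nrow(x$sample_sizes), " loci, ", x$n_alleles[1L],
      " alleles/locus\n  per-population Fst: ",
      paste(format(x$fst), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a family of related allele-frequency databases
#'
#' Per locus, ancestral frequencies are drawn from a symmetric Dirichlet;
#' each population's frequencies are drawn from a Dirichlet with
#' parameters `p_anc * (1 - F) / F` at that population's `F`; observation
#' counts are then drawn multinomially at the specified per-locus sample
#' size.  Deterministic given `spec$seed`.
#'
#' @param spec A [family_spec()].
#' @return Named list of validated [freq_db()] objects, one per
#'   population.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  loci <- rownames(spec$sample_sizes)
  pops <- spec$pop_names
  tabs <- lapply(pops, function(p) stats::setNames(vector("list", length(loci)),
                                                   loci))
  names(tabs) <- pops
  for (il in seq_along(loci)) {
    k <- spec$n_alleles[il]
    labels <- as.character(seq(8L, length.out = k))
    p_anc <- .rdirichlet1(rep(spec$concentration, k))
    for (pop in pops) {
      f <- spec$fst[[pop]]
      p_pop <- .rdirichlet1(p_anc * (1 - f) / f)
      n <- spec$sample_sizes[il, pop]
      cnt <- as.vector(stats::rmultinom(1L, size = n, prob = p_pop))
      tabs[[pop]][[loci[il]]] <- stats::setNames(as.numeric(cnt), labels)
    }
  }
  out <- lapply(pops, function(pop) freq_db(pop, tabs[[pop]]))
  names(out) <- pops
  out
}

#' Moment estimate of between-population differentiation
#'
#' A Weir-Cockerham-style moment estimator: per allele, the variance of
#' the sample frequencies across populations, bias-corrected for the
#' binomial sampling variance of each database, is pooled over alleles
#' and loci against the heterozygosity `p(1-p)` of the mean frequency.
#' Used to verify that generated families carry the differentiation the
#' experiments assume; with per-population `F` values it recovers their
#' average.
#'
#' @param dbs List of [freq_db()] objects sharing a locus panel and
#'   allele sets.
#' @return A single numeric estimate of `Fst`.
#' @export
estimate_fst <- function(dbs) {
  if (length(dbs) < 2L) stop("at least 2 databases are required")
  loci <- db_loci(dbs[[1L]])
  num <- 0
  den <- 0
  for (loc in loci) {
    alleles <- names(dbs[[1L]]$tables[[loc]])
    P <- vapply(dbs, function(db) {
      tab <- db$tables[[loc]]
      p <- tab[match(alleles, names(tab))]
      p[is.na(p)] <- 0
      p / sum(tab)
    }, numeric(length(alleles)))
    N <- vapply(dbs, function(db) sum(db$tables[[loc]]), numeric(1))
    for (a in seq_along(alleles)) {
      pa <- P[a, ]
      pbar <- mean(pa)
      if (pbar <= 0 || pbar >= 1) next
      samp_var <- mean(pa * (1 - pa) / N)
      num <- num + max(stats::var(pa) - samp_var, 0)
      den <- den + pbar * (1 - pbar)
    }
  }
  num / den
}
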