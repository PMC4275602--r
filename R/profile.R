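# Reference profiles and crime-scene profiles.

#' Construct a reference STR profile
#'
#' A profile records, for one individual, an unordered genotype (exactly
#' two allele labels, equal for a homozygote) at each locus of a panel.
#'
#' @param sample_id Single string identifying the individual.
#' @param genotypes Named list, one element per locus, each a character
#'   vector of length 2.
#' @return An object of class `str_profile`.
#' @export
str_profile <- function(sample_id, genotypes) {
  if (length(genotypes) == 0L || is.null(names(genotypes)))
    stop("genotypes must be a non-empty named list")
  genotypes <- lapply(genotypes, function(g) {
    g <- as.character(g)
    if (length(g) != 2L || anyNA(g))
      stop("each genotype must consist of exactly 2 allele labels")
    sort(g)
  })
  structure(list(sample_id = as.character(sample_id), genotypes = genotypes),
            class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat("STR profile '", x$sample_id, "' (", length(x$genotypes), " loci)\n",
      sep = "")
  gt <- vapply(x$genotypes, paste, character(1), collapse = "/")
  cat(paste0("  ", format(names(gt)), "  ", gt, collapse = "\n"), "\n")
  invisible(x)
}

#' Construct a crime-scene profile
#'
#' A crime-scene profile (CSP) is the per-locus set of distinct alleles
#' detected in an evidence sample.  Under the no-dropout/no-dropin model
#' used throughout, the set equals the union of the true contributors'
#' alleles: 1-2 alleles per locus for one contributor, 1-4 for two.
#'
#' @param sample_id Single string identifying the sample.
#' @param alleles Named list, one character vector of distinct allele
#'   labels per locus; every locus must be non-empty.
#' @return An object of class `csp`.
#' @seealso [make_csp()] to form a CSP from contributor profiles.
#' @export
csp <- function(sample_id, alleles) {
  if (length(alleles) == 0L || is.null(names(alleles)))
    stop("alleles must be a non-empty named list")
  alleles <- lapply(alleles, function(a) {
    a <- sort(unique(as.character(a)))
    if (length(a) == 0L) stop("every CSP locus must have at least one allele")
    a
  })
  structure(list(sample_id = as.character(sample_id), alleles = alleles),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat("Crime-scene profile '", x$sample_id, "' (", length(x$alleles),
      " loci)\n", sep = "")
  al <- vapply(x$alleles, paste, character(1), collapse = ",")
  cat(paste0("  ", format(names(al)), "  {", al, "}", collapse = "\n"), "\n")
  invisible(x)
}

#' Read reference profiles from CSV
#'
#' Expects a header `sample_id,locus,allele1,allele2`, one row per
#' (sample, locus).
#'
#' @param path Path to the CSV file.
#' @return A named list of [str_profile()] objects, one per sample.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("sample_id", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
                function(d) {
    str_profile(d$sample_id[1L],
                stats::setNames(Map(c, d$allele1, d$allele2), d$locus))
  })
  out
}

#' Write reference profiles to CSV
#'
#' @param profiles A single [str_profile()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, locus = names(p$genotypes),
               allele1 = vapply(p$genotypes, `[`, character(1), 1L),
               allele2 = vapply(p$genotypes, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read crime-scene profiles from CSV
#'
#' Expects a header `sample_id,locus,alleles` with the detected alleles
#' `;`-separated.
#'
#' @param path Path to the CSV file.
#' @return A named list of [csp()] objects, one per sample.
#' @export
read_csp <- function(path) {
  if (!file.exists(path)) stop("CSP file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("sample_id", "locus", "alleles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSP file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
         function(d) {
    csp(d$sample_id[1L],
        stats::setNames(strsplit(d$alleles, ";", fixed = TRUE), d$locus))
  })
}

#' Write crime-scene profiles to CSV
#'
#' @param csps A single [csp()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csp <- function(csps, path) {
  if (inherits(csps, "csp")) csps <- list(csps)
  rows <- lapply(csps, function(x) {
    data.frame(sample_id = x$sample_id, locus = names(x$alleles),
               alleles = vapply(x$alleles, paste, character(1), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

profile_alleles <- function(p, locus) p$genotypes[[locus]]
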