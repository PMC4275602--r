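# Allele-frequency databases: construction, validation, I/O, and the
# size-bias count adjustment for the alleles of the queried contributor.

#' Construct an allele-frequency database
#'
#' A `freq_db` holds, for one population, a per-locus table of allele
#' observation counts.  Frequencies are always derived as `count / total`
#' at the point of use, so the object stores counts only.  Counts may be
#' non-integral (e.g. pseudo-counts from [perturb_frequencies()]), but must
#' be non-negative with a positive per-locus total.
#'
#' @param name Single string naming the population (e.g. `"IC1"`).
#' @param tables Named list, one element per locus, each a named numeric
#'   vector of allele observation counts.  Allele labels are opaque strings
#'   (STR designations such as `"9.3"`); no numeric interpretation is made.
#' @return An object of class `freq_db`.
#' @seealso [read_freq_db()], [adjust_for_profile()], [allele_freqs()]
#' @export
freq_db <- function(name, tables) {
  db <- structure(list(name = as.character(name), tables = tables),
                  class = "freq_db")
  validate_freq_db(db)
  db
}

#' Validate a frequency database
#'
#' Checks locus-name uniqueness, allele-label uniqueness within each locus,
#' non-negative counts and positive per-locus totals.
#'
#' @param db A `freq_db`.
#' @return `db`, invisibly; errors describe the first violation found.
#' @export
validate_freq_db <- function(db) {
  stopifnot(inherits(db, "freq_db"))
  if (length(db$tables) == 0L)
    stop("database '", db$name, "' has no loci")
  loci <- names(db$tables)
  if (is.null(loci) || anyNA(loci) || any(loci == ""))
    stop("all loci must be named")
  if (anyDuplicated(loci))
    stop("duplicate locus name: ", loci[duplicated(loci)][1L])
  for (loc in loci) {
    cnt <- db$tables[[loc]]
    if (!is.numeric(cnt) || length(cnt) == 0L)
      stop("locus ", loc, ": counts must be a non-empty numeric vector")
    al <- names(cnt)
    if (is.null(al) || anyNA(al) || any(al == ""))
      stop("locus ", loc, ": all alleles must be labelled")
    if (anyDuplicated(al))
      stop("locus ", loc, ": duplicate allele label '",
           al[duplicated(al)][1L], "'")
    if (any(cnt < 0) || anyNA(cnt))
      stop("locus ", loc, ": negative or missing count")
    if (sum(cnt) <= 0)
      stop("locus ", loc, ": total count must be positive")
  }
  invisible(db)
}

#' @export
print.freq_db <- function(x, ...) {
  tot <- vapply(x$tables, sum, numeric(1))
  cat("Allele frequency database '", x$name, "': ",
      length(x$tables), " loci\n", sep = "")
  cat("  total allele observations per locus: ",
      paste0(names(tot), "=", format(tot, trim = TRUE), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Locus names of a database
#' @param db A `freq_db`.
#' @return Character vector of locus names, in storage order.
#' @export
db_loci <- function(db) names(db$tables)

#' Allele frequencies at one locus
#'
#' @param db A `freq_db`.
#' @param locus Locus name.
#' @return Named numeric vector of allele fractions (`count / total`),
#'   summing to 1.
#' @export
allele_freqs <- function(db, locus) {
  tab <- db$tables[[locus]]
  if (is.null(tab))
    stop("locus '", locus, "' not present in database '", db$name, "'")
  tab / sum(tab)
}

#' Add the alleles of the queried contributor to the database counts
#'
#' Implements the size-bias correction: one observation is added to the
#' database count for each allele copy of the queried contributor Q, so a
#' heterozygote adds 1 to each of its two alleles and a homozygote adds 2
#' to its single allele; the per-locus total rises by 2 either way.
#' Alleles of Q absent from the database enter with count 0 before the
#' addition, which guarantees every allele of Q a nonzero frequency in
#' every calculation.
#'
#' @param db A `freq_db`; not modified.
#' @param q A [str_profile()] whose loci must all be present in `db`.
#' @return A new `freq_db` with adjusted counts.
#' @export
adjust_for_profile <- function(db, q) {
  stopifnot(inherits(db, "freq_db"), inherits(q, "str_profile"))
  tables <- db$tables
  for (loc in names(q$genotypes)) {
    tab <- tables[[loc]]
    if (is.null(tab))
      stop("locus '", loc, "' of profile '", q$sample_id,
           "' not present in database '", db$name, "'")
    for (a in q$genotypes[[loc]]) {
      if (is.na(match(a, names(tab)))) tab[a] <- 0
      tab[a] <- tab[a] + 1
    }
    tables[[loc]] <- tab
  }
  structure(list(name = db$name, tables = tables), class = "freq_db")
}

#' Read an allele-frequency database from CSV
#'
#' Expects a header `locus,allele,count` with one row per (locus, allele).
#' Counts must be non-negative integers; duplicated (locus, allele) rows,
#' negative counts and missing columns are rejected with the offending row
#' number.
#'
#' @param path Path to the CSV file.
#' @param name Database name; defaults to the file name without extension.
#' @return A validated `freq_db`.
#' @export
read_freq_db <- function(path, name = NULL) {
  if (!file.exists(path)) stop("database file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("locus", "allele", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("database file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    stop("row ", bad[1L] + 1L, " of ", path,
         ": count must be a non-negative integer (got '",
         df$count[bad[1L]], "')")
  dup <- which(duplicated(paste(df$locus, df$allele, sep = "\r")))
  if (length(dup))
    stop("row ", dup[1L] + 1L, " of ", path, ": duplicate entry for locus ",
         df$locus[dup[1L]], ", allele ", df$allele[dup[1L]])
  tables <- lapply(split(seq_len(nrow(df)), factor(df$locus, levels = unique(df$locus))),
                   function(i) stats::setNames(cnt[i], df$allele[i]))
  freq_db(name, tables)
}

#' Write an allele-frequency database to CSV
#'
#' Columns `locus,allele,count`, loci in storage order and alleles sorted
#' within locus, so that write followed by read is the identity.
#'
#' @param db A validated `freq_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_freq_db <- function(db, path) {
  validate_freq_db(db)
  rows <- lapply(names(db$tables), function(loc) {
    tab <- db$tables[[loc]]
    ord <- order(names(tab))
    data.frame(locus = loc, allele = names(tab)[ord], count = unname(tab)[ord],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
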