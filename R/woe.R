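# Weight-of-evidence engine: per-locus likelihood ratios for the three
# hypothesis pairs (Q vs X; Q+K vs X+K; Q+U vs X+U), the single-database
# heuristic policy and the alternative database-assignment policies.
#
# Conventions used throughout:
#   * WoE is reported in bans: log10 of the likelihood ratio, summed over
#     loci (linkage equilibrium).
#   * The size-bias adjustment (+1 database count per allele copy of Q) is
#     applied to EVERY analysis database before use.
#   * Unknown contributors assigned the database of Q are conditioned on
#     Q's two alleles with the supplied theta; with theta = 0 the
#     conditioning is vacuous, which is exactly the treatment of unknowns
#     assigned any other database.
#   * Alleles of the CSP or of a conditioning profile carrying zero
#     observations in the analysis database are floored to count 1 so that
#     no admissible genotype has probability zero.

# ---- genotype enumeration over <= 4 CSP alleles ------------------------

.gt_cache <- new.env(parent = emptyenv())

# All unordered genotype index pairs over k alleles, with bitmasks of the
# allele set of each genotype, the ordered-pair admissibility matrix for
# the union-covers-all condition, and heterozygote weights.
.gt_pairs <- function(k) {
  key <- as.character(k)
  gp <- .gt_cache[[key]]
  if (!is.null(gp)) return(gp)
  i1 <- rep(seq_len(k), times = k - seq_len(k) + 1L)
  i2 <- unlist(lapply(seq_len(k), function(i) i:k), use.names = FALSE)
  mask <- bitwOr(bitwShiftL(1L, i1 - 1L), bitwShiftL(1L, i2 - 1L))
  full <- bitwShiftL(1L, k) - 1L
  adm <- outer(mask, mask, function(a, b) bitwOr(a, b) == full) + 0
  homi <- as.numeric(i1 == i2)
  gp <- list(k = k, i1 = i1, i2 = i2, mask = mask, full = full, adm = adm,
             homi = homi, w = 2 - homi)
  .gt_cache[[key]] <- gp
  gp
}

# Vectorised sequential genotype probabilities over the genotype list gp,
# conditional on m (allele-copy counts, length k) among n observed copies.
.gt_prob_vec <- function(p, m, n, theta, gp) {
  om <- 1 - theta
  q1 <- (m[gp$i1] * theta + om * p[gp$i1]) / (1 + (n - 1) * theta)
  q2 <- ((m[gp$i2] + gp$homi) * theta + om * p[gp$i2]) / (1 + n * theta)
  gp$w * q1 * q2
}

.allele_mask <- function(alleles, A) {
  j <- match(alleles, A)
  if (anyNA(j)) stop("allele(s) ", paste(alleles[is.na(j)], collapse = ", "),
                     " not among the CSP alleles")
  Reduce(bitwOr, bitwShiftL(1L, unique(j) - 1L), 0L)
}

# Frequencies of the alleles A at one locus after the +1-per-copy
# adjustment for q_al (two allele labels) and the zero-count floor for the
# remaining alleles of A.  Returns p over A plus the floored allele labels.
.locus_freqs <- function(tab, A, q_al, adjust = TRUE) {
  total <- sum(tab)
  cnt <- tab[match(A, names(tab))]
  cnt[is.na(cnt)] <- 0
  if (adjust) {
    j <- match(q_al, A)
    if (anyNA(j)) stop("alleles of Q must be contained in the CSP alleles")
    for (jj in j) cnt[jj] <- cnt[jj] + 1
    total <- total + length(j)
  }
  z <- cnt == 0
  if (any(z)) {
    cnt[z] <- 1
    total <- total + sum(z)
  }
  list(p = unname(cnt / total), floored = A[z])
}

.warn_floored <- function(floored, db_name, quiet) {
  if (!quiet && length(floored))
    warning("allele(s) with zero observations in database '", db_name,
            "' floored to count 1: ", paste(floored, collapse = ", "),
            call. = FALSE)
}

# ---- WoE result object -------------------------------------------------

new_woe <- function(per_locus_ban, policy_label) {
  structure(list(per_locus_ban = per_locus_ban,
                 total_ban = sum(per_locus_ban),
                 policy_label = policy_label),
            class = "woe")
}

#' @export
print.woe <- function(x, digits = 6, ...) {
  cat("Weight of evidence [", x$policy_label, "]\n", sep = "")
  cat("  total: ", formatC(x$total_ban, digits = digits, format = "f"),
      " bans over ", length(x$per_locus_ban), " loci\n", sep = "")
  invisible(x)
}

#' @export
summary.woe <- function(object, ...) {
  cat("Weight of evidence [", object$policy_label, "]\n", sep = "")
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
  cat("  total:", format(object$total_ban), "bans\n")
  invisible(df)
}

#' @export
as.data.frame.woe <- function(x, ...) {
  data.frame(locus = names(x$per_locus_ban), ban = unname(x$per_locus_ban),
             stringsAsFactors = FALSE)
}

# ---- public operations -------------------------------------------------

#' Enumerate candidate genotypes of an unknown contributor
#'
#' All unordered allele pairs drawn from the CSP alleles whose allele set
#' contains a required subset (the CSP alleles not explained by the other
#' contributors).  Any allele outside the CSP would imply dropout, which
#' the model excludes.
#'
#' @param csp_alleles Character vector of distinct CSP alleles (at most 4).
#' @param required Character vector of alleles the genotype must cover;
#'   must be a subset of `csp_alleles`.
#' @return List of character vectors of length 2, in a deterministic
#'   order (pairs `(i, j)`, `i <= j`, over the sorted alleles).
#' @export
enumerate_unknown_genotypes <- function(csp_alleles, required = character(0)) {
  A <- sort(unique(as.character(csp_alleles)))
  if (length(A) > 4L) stop("at most 4 CSP alleles are supported")
  if (anyNA(match(required, A)))
    stop("required alleles must be a subset of the CSP alleles")
  gp <- .gt_pairs(length(A))
  req <- .allele_mask(as.character(required), A)
  keep <- bitwAnd(gp$mask, req) == req
  Map(function(i, j) c(A[i], A[j]), gp$i1[keep], gp$i2[keep])
}

#' Weight of evidence for a single-contributor profile
#'
#' Hypotheses `Hp: Q` versus `Hd: X`.  Per locus the likelihood ratio is
#' the reciprocal of the coancestry-adjusted match probability of Q's
#' genotype; the WoE is the sum of the per-locus log10 LRs.
#'
#' @param q The queried contributor's [str_profile()].
#' @param db The analysis [freq_db()]; its counts receive the
#'   +1-per-allele-copy adjustment for `q` unless `adjust = FALSE`.
#' @param theta Coancestry coefficient for the unknown X: the policy value
#'   (0.03 by default) when `db` is the database of Q, and 0 otherwise.
#' @param adjust Apply the size-bias count adjustment (default `TRUE`).
#' @param quiet Suppress zero-count floor warnings.
#' @return A `woe` object with per-locus and total bans.
#' @export
lr_single <- function(q, db, theta = 0.03, adjust = TRUE, quiet = FALSE) {
  stopifnot(inherits(q, "str_profile"), inherits(db, "freq_db"))
  loci <- names(q$genotypes)
  bans <- numeric(length(loci))
  for (il in seq_along(loci)) {
    loc <- loci[il]
    tab <- db$tables[[loc]]
    if (is.null(tab))
      stop("locus '", loc, "' not present in database '", db$name, "'")
    g <- q$genotypes[[loc]]
    A <- unique(g)
    lf <- .locus_freqs(tab, A, g, adjust = adjust)
    p <- lf$p
    hom <- g[1L] == g[2L]
    if (hom) {
      mp <- bn_conditional(p[1L], 2, 2, theta) * bn_conditional(p[1L], 3, 3, theta)
    } else {
      mp <- 2 * bn_conditional(p[1L], 1, 2, theta) *
        bn_conditional(p[2L], 1, 3, theta)
    }
    if (mp <= 0) stop("zero match probability at locus ", loc)
    bans[il] <- -log10(mp)
  }
  names(bans) <- loci
  new_woe(bans, sprintf("single[db=%s,theta=%g]", db$name, theta))
}

#' Weight of evidence with a known second contributor
#'
#' Hypotheses `Hp: Q+K` versus `Hd: X+K`, where K's reference profile is
#' available.  With no dropout or dropin the CSP is deterministic given
#' the contributor genotypes, so the Hp likelihood is 1 and the Hd
#' likelihood sums the coancestry-adjusted probabilities of every genotype
#' for X, drawn from the CSP alleles, that covers the CSP alleles not
#' carried by K.  X is conditioned on Q's two alleles (vacuous when
#' `theta = 0`); K's alleles never enter the conditioning.
#'
#' @param k The known contributor's [str_profile()].
#' @inheritParams lr_single
#' @param csp_prof The [csp()]; per locus its alleles must equal the union
#'   of the alleles of `q` and `k`.
#' @return A `woe` object.
#' @export
lr_known <- function(q, k, csp_prof, db, theta = 0.03, adjust = TRUE,
                     quiet = FALSE) {
  stopifnot(inherits(q, "str_profile"), inherits(k, "str_profile"),
            inherits(csp_prof, "csp"), inherits(db, "freq_db"))
  loci <- names(csp_prof$alleles)
  bans <- numeric(length(loci))
  floored <- character(0)
  for (il in seq_along(loci)) {
    loc <- loci[il]
    tab <- db$tables[[loc]]
    if (is.null(tab))
      stop("locus '", loc, "' not present in database '", db$name, "'")
    A <- csp_prof$alleles[[loc]]
    gq <- q$genotypes[[loc]]
    gk <- k$genotypes[[loc]]
    if (is.null(gq) || is.null(gk))
      stop("locus '", loc, "' missing from a contributor profile")
    if (!setequal(c(gq, gk), A))
      stop("locus '", loc, "': CSP alleles must equal the union of the ",
           "alleles of Q and K (no dropout/dropin)")
    kk <- length(A)
    gp <- .gt_pairs(kk)
    lf <- .locus_freqs(tab, A, gq, adjust = adjust)
    floored <- c(floored, lf$floored)
    condQ <- numeric(kk)
    jq <- match(gq, A)
    for (jj in jq) condQ[jj] <- condQ[jj] + 1
    req <- bitwAnd(gp$full, bitwNot(.allele_mask(gk, A)))
    probs <- .gt_prob_vec(lf$p, condQ, 2, theta, gp)
    hd <- sum(probs[bitwAnd(gp$mask, req) == req])
    if (hd <= 0) stop("zero defence likelihood at locus ", loc)
    bans[il] <- -log10(hd)
  }
  .warn_floored(unique(floored), db$name, quiet)
  names(bans) <- loci
  new_woe(bans, sprintf("known-K[db=%s,theta=%g]", db$name, theta))
}

#' Weight of evidence with an unknown second contributor
#'
#' Hypotheses `Hp: Q+U` versus `Hd: X+U`, with the uncontested second
#' contributor U unprofiled.  Per locus, the Hp likelihood sums the
#' probabilities of the genotypes of U that, together with Q, explain the
#' CSP exactly; the Hd likelihood sums over ordered genotype pairs
#' `(X, U)` from the CSP alleles whose union equals the CSP allele set.
#' Each unknown is conditioned on Q's two alleles with its own theta
#' (vacuous at `theta = 0`).  When X and U are assigned the same database
#' and `condition_on_unknowns` is `TRUE`, U additionally conditions on the
#' genotype drawn for X (full sequential recursion).
#'
#' @inheritParams lr_known
#' @param db_x,db_u Analysis databases for X and U (both receive the
#'   size-bias adjustment for `q`).
#' @param theta_x,theta_u Coancestry coefficients for X and U: the policy
#'   value when the respective database is the database of Q, else 0.
#' @param condition_on_unknowns Condition U on the genotype of X when both
#'   use the same database (default `TRUE`).
#' @return A `woe` object.
#' @export
lr_unknown <- function(q, csp_prof, db_x, db_u, theta_x = 0, theta_u = 0,
                       condition_on_unknowns = TRUE, adjust = TRUE,
                       quiet = FALSE) {
  stopifnot(inherits(q, "str_profile"), inherits(csp_prof, "csp"),
            inherits(db_x, "freq_db"), inherits(db_u, "freq_db"))
  loci <- names(csp_prof$alleles)
  same_db <- identical(db_x$name, db_u$name)
  cross <- condition_on_unknowns && same_db
  bans <- numeric(length(loci))
  floored <- character(0)
  for (il in seq_along(loci)) {
    loc <- loci[il]
    tab_x <- db_x$tables[[loc]]
    tab_u <- if (same_db) tab_x else db_u$tables[[loc]]
    if (is.null(tab_x) || is.null(tab_u))
      stop("locus '", loc, "' not present in an analysis database")
    A <- csp_prof$alleles[[loc]]
    kk <- length(A)
    if (kk > 4L) stop("locus '", loc, "': more than 4 CSP alleles")
    gq <- q$genotypes[[loc]]
    if (is.null(gq)) stop("locus '", loc, "' missing from the profile of Q")
    jq <- match(gq, A)
    if (anyNA(jq))
      stop("locus '", loc, "': alleles of Q must be contained in the CSP")
    gp <- .gt_pairs(kk)
    lf_x <- .locus_freqs(tab_x, A, gq, adjust = adjust)
    lf_u <- if (same_db) lf_x else .locus_freqs(tab_u, A, gq, adjust = adjust)
    floored <- c(floored, lf_x$floored, lf_u$floored)
    condQ <- numeric(kk)
    for (jj in jq) condQ[jj] <- condQ[jj] + 1
    # Hp: U must cover the CSP alleles not carried by Q
    req_u <- bitwAnd(gp$full, bitwNot(.allele_mask(gq, A)))
    pu0 <- .gt_prob_vec(lf_u$p, condQ, 2, theta_u, gp)
    hp <- sum(pu0[bitwAnd(gp$mask, req_u) == req_u])
    if (hp <= 0)
      stop("locus '", loc, "': no admissible genotype for U under Hp")
    # Hd: ordered pairs (X, U) whose union is the CSP allele set
    px <- .gt_prob_vec(lf_x$p, condQ, 2, theta_x, gp)
    if (!cross || theta_u == 0) {
      hd <- sum(px * as.vector(gp$adm %*% pu0))
    } else {
      hd <- 0
      for (ix in seq_along(px)) {
        mu <- condQ
        mu[gp$i1[ix]] <- mu[gp$i1[ix]] + 1
        mu[gp$i2[ix]] <- mu[gp$i2[ix]] + 1
        pu <- .gt_prob_vec(lf_u$p, mu, 4, theta_u, gp)
        hd <- hd + px[ix] * sum(pu[gp$adm[ix, ] > 0])
      }
    }
    if (hd <= 0) stop("locus '", loc, "': zero defence likelihood")
    bans[il] <- log10(hp) - log10(hd)
  }
  .warn_floored(unique(floored), paste(unique(c(db_x$name, db_u$name)),
                                       collapse = "+"), quiet)
  names(bans) <- loci
  new_woe(bans, sprintf("unknown-U[db_x=%s,db_u=%s,theta_x=%g,theta_u=%g]",
                        db_x$name, db_u$name, theta_x, theta_u))
}

#' Heuristic weight of evidence: database of Q with Fst = 0.03
#'
#' Dispatches to [lr_single()], [lr_known()] or [lr_unknown()], assigning
#' the database of Q to every unknown contributor and applying the policy
#' `theta` (default 0.03) throughout.
#'
#' @inheritParams lr_known
#' @param db_q The database best matching the ancestry of Q.
#' @param k Known second contributor profile, or `NULL`.
#' @param second_unknown If `TRUE` (and `k` is `NULL`), treat the CSP as a
#'   two-contributor profile with an unprofiled second contributor U.
#' @param csp_prof The CSP; may be `NULL` for a single-contributor case
#'   (it is then implied by `q`).
#' @inheritParams lr_unknown
#' @return A `woe` object with a `heuristic` policy label.
#' @export
heuristic_woe <- function(q, csp_prof = NULL, db_q, k = NULL,
                          second_unknown = FALSE, theta = 0.03,
                          condition_on_unknowns = TRUE, quiet = FALSE) {
  res <- if (!is.null(k)) {
    if (is.null(csp_prof)) stop("a CSP is required when K is present")
    lr_known(q, k, csp_prof, db_q, theta = theta, quiet = quiet)
  } else if (second_unknown) {
    if (is.null(csp_prof)) stop("a CSP is required with a second unknown")
    lr_unknown(q, csp_prof, db_q, db_q, theta_x = theta, theta_u = theta,
               condition_on_unknowns = condition_on_unknowns, quiet = quiet)
  } else {
    lr_single(q, db_q, theta = theta, quiet = quiet)
  }
  res$policy_label <- sprintf("heuristic[db=%s,theta=%g] %s", db_q$name,
                              theta, res$policy_label)
  res
}

#' Minimum weight of evidence over alternative database assignments
#'
#' Evaluates the WoE under each alternative database policy and returns
#' the minimum total (most favourable to the defence), ties resolved in
#' favour of the first database in `alt_dbs`.  Alternatives use
#' `theta = 0` unless an assignment coincides with the database of Q (by
#' name), in which case the policy `theta` applies.
#'
#' @inheritParams heuristic_woe
#' @param alt_dbs Non-empty list of candidate [freq_db()] objects for X.
#' @param mode `"single"` (Hd: X), `"known_K"` (Hd: X+K),
#'   `"unknown_U_true"` (Hd: X+U with `fixed_db_u` for U) or
#'   `"unknown_U_same"` (Hd: X+U with each candidate used for both).
#' @param db_q_name Name of the database of Q (drives the theta rule).
#' @param fixed_db_u Database for U in mode `"unknown_U_true"`.
#' @return The minimising `woe` object; its `policy_label` names the
#'   database(s) selected.
#' @export
min_alternative_woe <- function(q, csp_prof = NULL, alt_dbs,
                                mode = c("single", "known_K",
                                         "unknown_U_true", "unknown_U_same"),
                                db_q_name, k = NULL, fixed_db_u = NULL,
                                theta = 0.03, condition_on_unknowns = TRUE,
                                quiet = FALSE) {
  mode <- match.arg(mode)
  if (length(alt_dbs) == 0L) stop("alt_dbs must be non-empty")
  best <- NULL
  best_db <- NULL
  for (db in alt_dbs) {
    th <- if (identical(db$name, db_q_name)) theta else 0
    res <- switch(mode,
      single = lr_single(q, db, theta = th, quiet = quiet),
      known_K = lr_known(q, k, csp_prof, db, theta = th, quiet = quiet),
      unknown_U_true = lr_unknown(q, csp_prof, db, fixed_db_u,
        theta_x = th,
        theta_u = if (identical(fixed_db_u$name, db_q_name)) theta else 0,
        condition_on_unknowns = condition_on_unknowns, quiet = quiet),
      unknown_U_same = lr_unknown(q, csp_prof, db, db,
        theta_x = th, theta_u = th,
        condition_on_unknowns = condition_on_unknowns, quiet = quiet))
    if (is.null(best) || res$total_ban < best$total_ban) {
      best <- res
      best_db <- db$name
    }
  }
  best$policy_label <- sprintf("min-alternative[%s] %s", mode,
                               best$policy_label)
  best$db_choice <- best_db
  best
}
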