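# Shared-preparation evaluators for the two-contributor experiment arms.
#
# One simulated CSP is analysed under many database assignments; the
# per-locus structure (allele indexing, genotype tables, admissibility
# masks, Q's conditioning counts) and each database's adjusted frequency
# vector are identical across those analyses, so they are computed once
# per simulation here.  The public lr_known()/lr_unknown() functions are
# the reference implementation; the evaluators below must agree with
# them to numerical precision (asserted in the test suite).

# Per-locus case structure shared by every analysis of one simulation.
.sim_prep <- function(q, csp_prof, gk = NULL) {
  loci <- names(csp_prof$alleles)
  lapply(stats::setNames(loci, loci), function(loc) {
    A <- csp_prof$alleles[[loc]]
    kk <- length(A)
    gp <- .gt_pairs(kk)
    gq <- q$genotypes[[loc]]
    jq <- match(gq, A)
    if (anyNA(jq))
      stop("locus '", loc, "': alleles of Q must be contained in the CSP")
    condQ <- numeric(kk)
    for (jj in jq) condQ[jj] <- condQ[jj] + 1
    bits <- bitwShiftL(1L, seq_len(kk) - 1L)
    qmask <- bitwOr(bits[jq[1L]], bits[jq[2L]])
    req_u <- bitwAnd(gp$full, bitwNot(qmask))
    out <- list(loc = loc, A = A, kk = kk, gp = gp, gq = gq, condQ = condQ,
                hp_keep = bitwAnd(gp$mask, req_u) == req_u)
    if (!is.null(gk)) {
      jk <- match(gk$genotypes[[loc]], A)
      if (anyNA(jk) || !setequal(c(jq, jk), seq_len(kk)))
        stop("locus '", loc, "': CSP alleles must equal the union of the ",
             "alleles of Q and K")
      kmask <- bitwOr(bits[jk[1L]], bits[jk[2L]])
      req_x <- bitwAnd(gp$full, bitwNot(kmask))
      out$hd_keep <- bitwAnd(gp$mask, req_x) == req_x
    }
    out
  })
}

.locus_p <- function(db, lp) .locus_freqs(db$tables[[lp$loc]], lp$A, lp$gq)$p

# Heuristic and minimum-alternative totals for the known-K pair.
# Returns c(heuristic, comparator, index of the minimising alternative).
.two_known_totals <- function(prep, db_q, alts, theta) {
  n_alt <- length(alts)
  tot <- numeric(1L + n_alt)
  for (lp in prep) {
    gp <- lp$gp
    vq <- .gt_prob_vec(.locus_p(db_q, lp), lp$condQ, 2, theta, gp)
    tot[1L] <- tot[1L] - log10(sum(vq[lp$hd_keep]))
    for (i in seq_len(n_alt)) {
      va <- .gt_prob_vec(.locus_p(alts[[i]], lp), lp$condQ, 2, 0, gp)
      tot[1L + i] <- tot[1L + i] - log10(sum(va[lp$hd_keep]))
    }
  }
  i_min <- which.min(tot[-1L])
  c(tot[1L], tot[1L + i_min], i_min)
}

# Heuristic and three comparator totals for the unknown-U pair:
# (a) correct databases for X and U, (b) minimum over alternatives for X
# with the correct database for U, (c) minimum over alternatives used
# for both X and U.  `diag` marks db_u == db_q.  Returns the totals plus
# the minimising alternative indices for (b) and (c).
.two_unknown_totals <- function(prep, db_q, db_u, alts, theta,
                                condition_on_unknowns) {
  n_alt <- length(alts)
  diag <- identical(db_u$name, db_q$name)
  h <- 0
  a <- 0
  b <- numeric(n_alt)
  cc <- numeric(n_alt)
  for (lp in prep) {
    gp <- lp$gp
    pq <- .locus_p(db_q, lp)
    vq <- .gt_prob_vec(pq, lp$condQ, 2, theta, gp)
    hp_q <- sum(vq[lp$hp_keep])
    # U's genotype vector under its correct database
    vu <- if (diag) vq else
      .gt_prob_vec(.locus_p(db_u, lp), lp$condQ, 2, 0, gp)
    hp_u <- sum(vu[lp$hp_keep])
    valts <- lapply(alts, function(d)
      .gt_prob_vec(.locus_p(d, lp), lp$condQ, 2, 0, gp))

    # heuristic Hd: X and U both on db_q; sequential cross-conditioning
    if (condition_on_unknowns && theta > 0) {
      hd_h <- 0
      for (ix in seq_along(vq)) {
        mu <- lp$condQ
        mu[gp$i1[ix]] <- mu[gp$i1[ix]] + 1
        mu[gp$i2[ix]] <- mu[gp$i2[ix]] + 1
        vu2 <- .gt_prob_vec(pq, mu, 4, theta, gp)
        hd_h <- hd_h + vq[ix] * sum(vu2[gp$adm[ix, ] > 0])
      }
    } else {
      hd_h <- sum(vq * as.vector(gp$adm %*% vq))
    }
    h <- h + log10(hp_q) - log10(hd_h)

    if (!diag) {
      wu <- as.vector(gp$adm %*% vu)
      a <- a + log10(hp_u) - log10(sum(vq * wu))
      for (i in seq_len(n_alt))
        b[i] <- b[i] + log10(hp_u) - log10(sum(valts[[i]] * wu))
    } else {
      # correct database for U is db_q: comparator (a) IS the heuristic,
      # and U's vector for (b) is vq
      wu <- as.vector(gp$adm %*% vq)
      for (i in seq_len(n_alt))
        b[i] <- b[i] + log10(hp_q) - log10(sum(valts[[i]] * wu))
    }
    for (i in seq_len(n_alt)) {
      va <- valts[[i]]
      cc[i] <- cc[i] + log10(sum(va[lp$hp_keep])) -
        log10(sum(va * as.vector(gp$adm %*% va)))
    }
  }
  if (diag) a <- h
  ib <- which.min(b)
  ic <- which.min(cc)
  list(h = h, a = a, b = b[ib], c = cc[ic], ib = ib, ic = ic)
}
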