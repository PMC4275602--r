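# The simulation study: how often is the single-database heuristic
# (database of Q, Fst = 0.03) conservative relative to alternative
# database-assignment policies?
#
# Each experiment simulates contributor genotypes from known databases,
# computes the heuristic WoE and one or more comparator WoEs per
# simulation, and records diff_ban = heuristic - comparator.  A
# simulation is "conservative" iff diff_ban <= 0 (ties included): the
# heuristic reported no more evidential weight than the comparator.

new_woe_experiment <- function(rows, meta) {
  structure(list(rows = rows, meta = meta), class = "woe_experiment")
}

#' @export
print.woe_experiment <- function(x, ...) {
  cat("WoE experiment [", x$meta$experiment, "]: ", nrow(x$rows),
      " (simulation, comparator) rows, seed ", x$meta$seed, "\n", sep = "")
  cat("  fraction conservative (diff <= 0): ",
      format(mean(x$rows$diff_ban <= 0)), "\n", sep = "")
  invisible(x)
}

#' Histogram of heuristic-minus-comparator WoE differences
#'
#' @param x A `woe_experiment`.
#' @param main Plot title.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.woe_experiment <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- paste0("WoE difference (heuristic - comparator): ",
                   x$meta$experiment)
  graphics::hist(x$rows$diff_ban, main = main,
                 xlab = "difference (bans)", ...)
  invisible(x)
}

.empty_rows <- function(n) {
  data.frame(sim_id = integer(n), db_q = character(n),
             db_other = NA_character_, fst = NA_real_,
             comparator = character(n), heuristic_ban = numeric(n),
             comparator_ban = numeric(n), comparator_label = character(n),
             diff_ban = numeric(n), stringsAsFactors = FALSE)
}

#' One-contributor experiment: heuristic vs minimum over other databases
#'
#' For each database, simulates `n_per_db` contributors Q, computes the
#' heuristic WoE (database of Q, policy theta) and the minimum WoE over
#' the remaining databases with `theta = 0` (hypotheses `Hp: Q` vs
#' `Hd: X`).
#'
#' @param dbs Named list of at least two [freq_db()] objects.
#' @param n_per_db Simulations per simulating database.
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param theta Policy coancestry coefficient for the heuristic.
#' @return A `woe_experiment` whose `rows` hold one row per simulation.
#' @export
run_experiment_single <- function(dbs, n_per_db = 2000, seed = 1,
                                  theta = 0.03) {
  stopifnot(length(dbs) >= 2L, n_per_db >= 1L)
  set.seed(seed)
  rows <- .empty_rows(length(dbs) * n_per_db)
  r <- 0L
  for (qn in names(dbs)) {
    db_q <- dbs[[qn]]
    alts <- dbs[names(dbs) != qn]
    for (i in seq_len(n_per_db)) {
      q <- sample_genotype(db_q, paste0(qn, "_", i))
      h <- lr_single(q, db_q, theta = theta, quiet = TRUE)
      cmp <- min_alternative_woe(q, alt_dbs = alts, mode = "single",
                                 db_q_name = qn, theta = theta, quiet = TRUE)
      r <- r + 1L
      rows$sim_id[r] <- i
      rows$db_q[r] <- qn
      rows$comparator[r] <- "min_alt"
      rows$heuristic_ban[r] <- h$total_ban
      rows$comparator_ban[r] <- cmp$total_ban
      rows$comparator_label[r] <- cmp$db_choice
      rows$diff_ban[r] <- h$total_ban - cmp$total_ban
    }
  }
  new_woe_experiment(rows, list(experiment = "single", n_per_db = n_per_db,
                                seed = seed, theta = theta,
                                databases = names(dbs)))
}

#' One-contributor experiment with Fst-perturbed ancestry
#'
#' Simulates contributors whose allele fractions differ from a base
#' database according to each of several Fst values (a fresh
#' Balding-Nichols Dirichlet draw per simulated profile per locus), then
#' analyses with the unperturbed base database (heuristic, policy theta)
#' versus the minimum over the other databases (`theta = 0`).
#'
#' @inheritParams run_experiment_single
#' @param base Name of the base database within `dbs`.
#' @param fst_values Perturbation Fst values.
#' @param n_per_fst Simulations per Fst value.
#' @return A `woe_experiment`; `rows$fst` records the perturbation level.
#' @export
run_experiment_fst <- function(dbs, base = names(dbs)[1L],
                               fst_values = c(0.01, 0.02, 0.03),
                               n_per_fst = 2000, seed = 1, theta = 0.03) {
  stopifnot(length(dbs) >= 2L, base %in% names(dbs))
  set.seed(seed)
  db_base <- dbs[[base]]
  alts <- dbs[names(dbs) != base]
  rows <- .empty_rows(length(fst_values) * n_per_fst)
  r <- 0L
  for (fst in fst_values) {
    for (i in seq_len(n_per_fst)) {
      pdb <- perturb_frequencies(db_base, fst)
      q <- sample_genotype(pdb, paste0(base, "_fst", fst, "_", i))
      h <- lr_single(q, db_base, theta = theta, quiet = TRUE)
      cmp <- min_alternative_woe(q, alt_dbs = alts, mode = "single",
                                 db_q_name = base, theta = theta,
                                 quiet = TRUE)
      r <- r + 1L
      rows$sim_id[r] <- i
      rows$db_q[r] <- base
      rows$fst[r] <- fst
      rows$comparator[r] <- "min_alt"
      rows$heuristic_ban[r] <- h$total_ban
      rows$comparator_ban[r] <- cmp$total_ban
      rows$comparator_label[r] <- cmp$db_choice
      rows$diff_ban[r] <- h$total_ban - cmp$total_ban
    }
  }
  new_woe_experiment(rows, list(experiment = "fst", base = base,
                                fst_values = fst_values,
                                n_per_fst = n_per_fst, seed = seed,
                                theta = theta, databases = names(dbs)))
}

#' Two-contributor experiment with a known second contributor
#'
#' For every ordered pair of databases (for Q and for K), simulates both
#' contributors, forms the CSP as the union of their alleles, and
#' compares the heuristic WoE (`Hp: Q+K` vs `Hd: X+K`, database of Q,
#' policy theta) with the minimum over the other databases for X
#' (`theta = 0`); K's reference profile is used in every analysis.
#'
#' @inheritParams run_experiment_single
#' @param n_per_pair Simulations per ordered database pair.
#' @return A `woe_experiment`; `rows$db_other` records K's database.
#' @export
run_experiment_two_known <- function(dbs, n_per_pair = 2000, seed = 1,
                                     theta = 0.03) {
  stopifnot(length(dbs) >= 2L, n_per_pair >= 1L)
  set.seed(seed)
  nms <- names(dbs)
  rows <- .empty_rows(length(nms)^2 * n_per_pair)
  r <- 0L
  for (qn in nms) {
    db_q <- dbs[[qn]]
    alts <- dbs[nms != qn]
    for (kn in nms) {
      db_k <- dbs[[kn]]
      for (i in seq_len(n_per_pair)) {
        q <- sample_genotype(db_q, "Q")
        kp <- sample_genotype(db_k, "K")
        cspx <- make_csp(list(q, kp))
        prep <- .sim_prep(q, cspx, gk = kp)
        tt <- .two_known_totals(prep, db_q, alts, theta)
        r <- r + 1L
        rows$sim_id[r] <- i
        rows$db_q[r] <- qn
        rows$db_other[r] <- kn
        rows$comparator[r] <- "min_alt"
        rows$heuristic_ban[r] <- tt[1L]
        rows$comparator_ban[r] <- tt[2L]
        rows$comparator_label[r] <- names(alts)[tt[3L]]
        rows$diff_ban[r] <- tt[1L] - tt[2L]
      }
    }
  }
  new_woe_experiment(rows, list(experiment = "two_known",
                                n_per_pair = n_per_pair, seed = seed,
                                theta = theta, databases = nms))
}

#' Two-contributor experiment with an unknown second contributor
#'
#' For every ordered pair of databases (for Q and for U), simulates both
#' contributors and forms the CSP, withholding U's reference profile
#' (`Hp: Q+U` vs `Hd: X+U`).  The heuristic (database of Q for both X and
#' U, policy theta) is compared with three alternatives per simulation:
#'
#' * `true_both`: the correct database for each of X and U (i.e. Q's for
#'   X, U's simulating database for U); identical to the heuristic when
#'   Q and U were simulated from the same database, so the difference is
#'   exactly 0 on those diagonal datasets.
#' * `true_U`: the minimum over the other databases for X, keeping U's
#'   correct database.
#' * `same_db`: the minimum over the other databases used for both X
#'   and U.
#'
#' Whenever an assignment uses the database of Q, the policy theta (with
#' conditioning on Q's alleles) applies; otherwise `theta = 0`.
#'
#' @inheritParams run_experiment_two_known
#' @param condition_on_unknowns Condition U on the genotype drawn for X
#'   when both unknowns share a database (see [lr_unknown()]).
#' @return A `woe_experiment` with three comparator rows per simulation.
#' @export
run_experiment_two_unknown <- function(dbs, n_per_pair = 2000, seed = 1,
                                       theta = 0.03,
                                       condition_on_unknowns = TRUE) {
  stopifnot(length(dbs) >= 2L, n_per_pair >= 1L)
  set.seed(seed)
  nms <- names(dbs)
  rows <- .empty_rows(length(nms)^2 * n_per_pair * 3L)
  r <- 0L
  for (qn in nms) {
    db_q <- dbs[[qn]]
    alts <- dbs[nms != qn]
    for (un in nms) {
      db_u <- dbs[[un]]
      for (i in seq_len(n_per_pair)) {
        q <- sample_genotype(db_q, "Q")
        u <- sample_genotype(db_u, "U")
        cspx <- make_csp(list(q, u))
        prep <- .sim_prep(q, cspx)
        tt <- .two_unknown_totals(prep, db_q, db_u, alts, theta,
                                  condition_on_unknowns)
        for (cc in list(list("true_both", tt$a,
                             if (un == qn) qn else un),
                        list("true_U", tt$b, names(alts)[tt$ib]),
                        list("same_db", tt$c, names(alts)[tt$ic]))) {
          r <- r + 1L
          rows$sim_id[r] <- i
          rows$db_q[r] <- qn
          rows$db_other[r] <- un
          rows$comparator[r] <- cc[[1L]]
          rows$heuristic_ban[r] <- tt$h
          rows$comparator_ban[r] <- cc[[2L]]
          rows$comparator_label[r] <- cc[[3L]]
          rows$diff_ban[r] <- tt$h - cc[[2L]]
        }
      }
    }
  }
  new_woe_experiment(rows, list(experiment = "two_unknown",
                                n_per_pair = n_per_pair, seed = seed,
                                theta = theta,
                                condition_on_unknowns = condition_on_unknowns,
                                databases = nms))
}

#' Summarise an experiment's WoE differences
#'
#' Per group (by default per comparator), reports the mean heuristic and
#' comparator WoE, their mean difference, the mean difference as a
#' percentage of the average of the two means, the fraction of
#' conservative simulations (difference <= 0, ties counting as
#' conservative), and upper-tail fractions `P(diff > x)` at the given
#' thresholds.
#'
#' @param x A `woe_experiment` (or its `rows` data frame).
#' @param thresholds Tail thresholds in bans.
#' @param by Grouping columns of the rows (default `"comparator"`).
#' @return A data frame with one row per group.
#' @export
summarize_experiment <- function(x, thresholds = c(0, 1, 2),
                                 by = "comparator") {
  rows <- if (inherits(x, "woe_experiment")) x$rows else x
  stopifnot(is.data.frame(rows), nrow(rows) > 0L, all(by %in% names(rows)))
  grp <- interaction(rows[by], drop = TRUE, lex.order = TRUE, sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(rows)), grp), function(idx) {
    d <- rows[idx, , drop = FALSE]
    mh <- mean(d$heuristic_ban)
    mc <- mean(d$comparator_ban)
    md <- mean(d$diff_ban)
    s <- data.frame(d[1L, by, drop = FALSE], n = nrow(d),
                    mean_heuristic = mh, mean_comparator = mc,
                    mean_diff = md,
                    pct_diff = 100 * abs(md) / mean(c(mh, mc)),
                    frac_conservative = mean(d$diff_ban <= 0),
                    stringsAsFactors = FALSE)
    for (x0 in thresholds)
      s[[paste0("p_gt_", x0)]] <- mean(d$diff_ban > x0)
    s
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.woe_experiment <- function(object, thresholds = c(0, 1, 2),
                                   by = "comparator", ...) {
  summarize_experiment(object, thresholds = thresholds, by = by)
}

#' Run the full conservativeness study
#'
#' Runs the one-contributor, Fst-perturbed, known-K and unknown-U
#' experiments on one database family and pools their rows (the unknown-U
#' arm contributes its three comparators), tagging each row with its arm.
#' Seeds for the four experiments are derived from `seed` by consecutive
#' offsets.
#'
#' @inheritParams run_experiment_two_unknown
#' @param n_per_cell Simulations per cell (per simulating database for
#'   the one-contributor arms; per ordered database pair for the
#'   two-contributor arms).
#' @param fst_values Perturbation levels for the Fst arm.
#' @param base Base database for the Fst arm.
#' @return A list of class `woe_study` with elements `single`, `fst`,
#'   `two_known`, `two_unknown` (each a `woe_experiment`) and `pooled`
#'   (all rows, with an `arm` column).
#' @export
run_conservativeness_study <- function(dbs, n_per_cell = 2000, seed = 1,
                                       theta = 0.03,
                                       fst_values = c(0.01, 0.02, 0.03),
                                       base = names(dbs)[1L],
                                       condition_on_unknowns = TRUE) {
  e1 <- run_experiment_single(dbs, n_per_db = n_per_cell, seed = seed,
                              theta = theta)
  e2 <- run_experiment_fst(dbs, base = base, fst_values = fst_values,
                           n_per_fst = n_per_cell, seed = seed + 1L,
                           theta = theta)
  e3 <- run_experiment_two_known(dbs, n_per_pair = n_per_cell,
                                 seed = seed + 2L, theta = theta)
  e4 <- run_experiment_two_unknown(dbs, n_per_pair = n_per_cell,
                                   seed = seed + 3L, theta = theta,
                                   condition_on_unknowns =
                                     condition_on_unknowns)
  pooled <- rbind(cbind(e1$rows, arm = "single", stringsAsFactors = FALSE),
                  cbind(e2$rows, arm = "fst", stringsAsFactors = FALSE),
                  cbind(e3$rows, arm = "two_known", stringsAsFactors = FALSE),
                  cbind(e4$rows, arm = "two_unknown",
                        stringsAsFactors = FALSE))
  structure(list(single = e1, fst = e2, two_known = e3, two_unknown = e4,
                 pooled = pooled,
                 meta = list(n_per_cell = n_per_cell, seed = seed,
                             theta = theta)),
            class = "woe_study")
}

#' @export
print.woe_study <- function(x, ...) {
  cat("Conservativeness study: ", nrow(x$pooled),
      " pooled (simulation, comparator) rows\n", sep = "")
  cat("  overall fraction conservative: ",
      format(mean(x$pooled$diff_ban <= 0)), "\n", sep = "")
  for (arm in c("single", "fst", "two_known", "two_unknown"))
    cat("  ", format(arm, width = 12), " frac conservative ",
        format(mean(x[[arm]]$rows$diff_ban <= 0)), "\n", sep = "")
  invisible(x)
}
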