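fam3 <- small_family(seed = 42)

test_that("experiments have the documented shape and are bit-reproducible", {
  e1 <- run_experiment_single(fam3, n_per_db = 2, seed = 7)
  expect_equal(nrow(e1$rows), 3 * 2)
  expect_identical(run_experiment_single(fam3, n_per_db = 2, seed = 7)$rows,
                   e1$rows)

  e2 <- run_experiment_fst(fam3, base = "P1", fst_values = c(0.01, 0.03),
                           n_per_fst = 3, seed = 7)
  expect_equal(nrow(e2$rows), 2 * 3)
  expect_equal(unique(e2$rows$fst), c(0.01, 0.03))
  expect_identical(run_experiment_fst(fam3, base = "P1",
                                      fst_values = c(0.01, 0.03),
                                      n_per_fst = 3, seed = 7)$rows, e2$rows)

  e3 <- run_experiment_two_known(fam3, n_per_pair = 2, seed = 7)
  expect_equal(nrow(e3$rows), 9 * 2)
  e4 <- run_experiment_two_unknown(fam3, n_per_pair = 2, seed = 7)
  expect_equal(nrow(e4$rows), 9 * 2 * 3)
  expect_identical(run_experiment_two_unknown(fam3, n_per_pair = 2,
                                              seed = 7)$rows, e4$rows)
  # every reported WoE is finite and the difference is consistent
  all_rows <- rbind(e1$rows, e2$rows, e3$rows, e4$rows)
  expect_true(all(is.finite(all_rows$heuristic_ban)))
  expect_true(all(is.finite(all_rows$comparator_ban)))
  expect_equal(all_rows$diff_ban,
               all_rows$heuristic_ban - all_rows$comparator_ban,
               tolerance = 1e-9)
})

test_that("experiment evaluators agree with the reference LR functions", {
  set.seed(99)
  theta <- 0.03
  for (rep in 1:15) {
    qn <- sample(names(fam3), 1)
    on <- sample(names(fam3), 1)
    db_q <- fam3[[qn]]
    alts <- fam3[names(fam3) != qn]
    q <- sample_genotype(db_q, "Q")
    other <- sample_genotype(fam3[[on]], "O")
    cspx <- make_csp(list(q, other))

    # known-K evaluator vs lr_known / min_alternative_woe
    tt <- .two_known_totals(.sim_prep(q, cspx, gk = other), db_q, alts, theta)
    expect_equal(tt[1L],
                 lr_known(q, other, cspx, db_q, theta, quiet = TRUE)$total_ban,
                 tolerance = 1e-12)
    ref <- min_alternative_woe(q, cspx, alt_dbs = alts, mode = "known_K",
                               db_q_name = qn, k = other, theta = theta,
                               quiet = TRUE)
    expect_equal(tt[2L], ref$total_ban, tolerance = 1e-12)
    expect_equal(names(alts)[tt[3L]], ref$db_choice)

    # unknown-U evaluator vs lr_unknown / min_alternative_woe
    tu <- .two_unknown_totals(.sim_prep(q, cspx), db_q, fam3[[on]], alts,
                              theta, condition_on_unknowns = TRUE)
    expect_equal(tu$h,
                 lr_unknown(q, cspx, db_q, db_q, theta, theta,
                            quiet = TRUE)$total_ban, tolerance = 1e-12)
    ref_a <- if (on == qn) tu$h else
      lr_unknown(q, cspx, db_q, fam3[[on]], theta, 0,
                 quiet = TRUE)$total_ban
    expect_equal(tu$a, ref_a, tolerance = 1e-12)
    ref_b <- min_alternative_woe(q, cspx, alt_dbs = alts,
                                 mode = "unknown_U_true", db_q_name = qn,
                                 fixed_db_u = fam3[[on]], theta = theta,
                                 quiet = TRUE)
    expect_equal(tu$b, ref_b$total_ban, tolerance = 1e-12)
    ref_c <- min_alternative_woe(q, cspx, alt_dbs = alts,
                                 mode = "unknown_U_same", db_q_name = qn,
                                 theta = theta, quiet = TRUE)
    expect_equal(tu$c, ref_c$total_ban, tolerance = 1e-12)
  }
})

test_that("with identical databases the heuristic is strictly conservative", {
  # alternatives differ only in name, so any difference comes from theta
  clones <- lapply(c("C1", "C2", "C3"), function(nm) {
    db <- fam3$P1
    db$name <- nm
    db
  })
  names(clones) <- c("C1", "C2", "C3")
  e1 <- run_experiment_single(clones, n_per_db = 10, seed = 8)
  expect_true(all(e1$rows$diff_ban < 0))
  e3 <- run_experiment_two_known(clones, n_per_pair = 3, seed = 8)
  expect_true(all(e3$rows$diff_ban < 0))
})

test_that("the true-databases comparator coincides with the heuristic on the diagonal", {
  e4 <- run_experiment_two_unknown(fam3, n_per_pair = 3, seed = 9)
  rows <- e4$rows
  diag_a <- rows$comparator == "true_both" & rows$db_q == rows$db_other
  expect_true(any(diag_a))
  expect_true(all(rows$diff_ban[diag_a] == 0))
  off_a <- rows$comparator == "true_both" & rows$db_q != rows$db_other
  expect_true(any(rows$diff_ban[off_a] != 0))
})

test_that("summaries implement the percent-difference and tail definitions", {
  rows <- data.frame(sim_id = 1:4, db_q = "A", db_other = NA, fst = NA,
                     comparator = "min_alt",
                     heuristic_ban = c(20.0, 20.6, 20.3, 20.3),
                     comparator_ban = c(24.2, 24.8, 24.5, 24.5),
                     comparator_label = "B",
                     diff_ban = c(-4.2, -4.2, -4.2, -4.2))
  s <- summarize_experiment(rows, thresholds = c(0, 1))
  expect_equal(s$mean_heuristic, 20.3)
  expect_equal(s$mean_comparator, 24.5)
  expect_equal(s$mean_diff, -4.2)
  expect_equal(s$pct_diff, 18.75, tolerance = 1e-9)
  expect_equal(s$frac_conservative, 1)
  expect_equal(s$p_gt_0, 0)

  # aggregation identity on a real experiment
  e1 <- run_experiment_single(fam3, n_per_db = 5, seed = 10)
  s1 <- summarize_experiment(e1, by = c("comparator", "db_q"))
  for (i in seq_len(nrow(s1))) {
    d <- e1$rows[e1$rows$db_q == s1$db_q[i], ]
    expect_equal(s1$mean_heuristic[i], mean(d$heuristic_ban))
    expect_equal(s1$frac_conservative[i],
                 1 - sum(d$diff_ban > 0) / nrow(d))
  }
  expect_error(summarize_experiment(e1$rows[0, ]), "nrow")
})

test_that("the pooled study tags rows by arm and reuses the arm results", {
  st <- run_conservativeness_study(fam3, n_per_cell = 2, seed = 11)
  expect_s3_class(st, "woe_study")
  expect_equal(nrow(st$pooled),
               nrow(st$single$rows) + nrow(st$fst$rows) +
                 nrow(st$two_known$rows) + nrow(st$two_unknown$rows))
  expect_equal(unique(st$pooled$arm),
               c("single", "fst", "two_known", "two_unknown"))
  expect_identical(st$pooled$diff_ban[st$pooled$arm == "single"],
                   st$single$rows$diff_ban)
})
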