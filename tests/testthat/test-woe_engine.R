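test_that("unknown-genotype enumeration covers exactly the admissible pairs", {
  expect_equal(enumerate_unknown_genotypes(c("a", "b")),
               list(c("a", "a"), c("a", "b"), c("b", "b")))
  # brute-force check of the required-subset filter
  got <- enumerate_unknown_genotypes(c("a", "b", "c"), required = "c")
  expect_length(got, 3)
  expect_true(all(vapply(got, function(g) "c" %in% g, logical(1))))
  expect_equal(enumerate_unknown_genotypes("a", required = "a"),
               list(c("a", "a")))
  expect_error(enumerate_unknown_genotypes(c("a", "b"), required = "z"),
               "subset")
})

test_that("single-contributor WoE is the log reciprocal match probability", {
  q <- str_profile("Q", list(L1 = c("a", "b")))
  # frequencies already include the size-bias adjustment: p_a = p_b = 0.1
  db <- tiny_db(L1 = c(a = 10, b = 10, c = 80))
  w <- lr_single(q, db, theta = 0, adjust = FALSE)
  expect_equal(10^w$total_ban, 50, tolerance = 1e-12)
  expect_equal(w$total_ban, 1.698970004336019, tolerance = 1e-12)

  q_hom <- str_profile("Q", list(L1 = c("a", "a")))
  db_hom <- tiny_db(L1 = c(a = 20, b = 80))
  w2 <- lr_single(q_hom, db_hom, theta = 0.03, adjust = FALSE)
  expect_equal(10^w2$total_ban, 15.13529998890984, tolerance = 1e-9)
  expect_equal(w2$total_ban, 1.179991033302967, tolerance = 1e-12)

  # additivity across loci: 16 identical loci
  gts <- rep(list(c("a", "b")), 16)
  names(gts) <- paste0("L", 1:16)
  tabs <- rep(list(c(a = 10, b = 10, c = 80)), 16)
  names(tabs) <- paste0("L", 1:16)
  w16 <- lr_single(str_profile("Q", gts), freq_db("DB", tabs),
                   theta = 0, adjust = FALSE)
  expect_equal(w16$total_ban, 16 * w$total_ban, tolerance = 1e-9)
  expect_equal(w16$total_ban, sum(w16$per_locus_ban))
})

test_that("explicit pre-adjustment and internal adjustment agree", {
  set.seed(21)
  for (rep in 1:10) {
    cs <- rand_case()
    pre <- adjust_for_profile(cs$db, cs$q)
    expect_equal(lr_single(cs$q, cs$db, theta = 0.03)$total_ban,
                 lr_single(cs$q, pre, theta = 0.03,
                           adjust = FALSE)$total_ban,
                 tolerance = 1e-12)
  }
})

test_that("known-contributor WoE matches closed forms and the oracle", {
  # K carries both CSP alleles: X unconstrained within {a, b}; at theta=0
  # the defence likelihood is (p_a + p_b)^2
  q <- str_profile("Q", list(L1 = c("a", "b")))
  k <- str_profile("K", list(L1 = c("a", "b")))
  cx <- csp("C", list(L1 = c("a", "b")))
  db <- tiny_db(L1 = c(a = 10, b = 20, c = 70))
  w <- lr_known(q, k, cx, db, theta = 0)
  f <- allele_freqs(adjust_for_profile(db, q), "L1")
  expect_equal(10^(-w$total_ban), (f[["a"]] + f[["b"]])^2, tolerance = 1e-12)

  # four distinct CSP alleles force X = genotype of Q exactly
  q4 <- str_profile("Q", list(L1 = c("a", "b")))
  k4 <- str_profile("K", list(L1 = c("c", "d")))
  cx4 <- csp("C", list(L1 = c("a", "b", "c", "d")))
  db4 <- tiny_db(L1 = c(a = 5, b = 10, c = 15, d = 20, e = 50))
  w4 <- lr_known(q4, k4, cx4, db4, theta = 0.03)
  f4 <- oracle_freqs(db4$tables$L1, cx4$alleles$L1, c("a", "b"))
  expect_equal(10^(-w4$total_ban),
               oracle_genotype_prob(c("a", "b"), f4, oracle_cond_of(c("a", "b")),
                                    2, 0.03),
               tolerance = 1e-12)

  # CSP must equal the union of Q's and K's alleles
  expect_error(lr_known(q4, k4, csp("C", list(L1 = c("a", "b", "c"))), db4),
               "union")
})

test_that("the Fst adjustment on Q's database never raises known-K WoE", {
  # asserted in the rare-allele regime; with common alleles the theta
  # adjustment can reverse at isolated loci (see test-genotype_model)
  set.seed(22)
  for (rep in 1:30) {
    cs <- rand_case_rare()
    w0 <- lr_known(cs$q, cs$other, cs$csp, cs$db, theta = 0, quiet = TRUE)
    w3 <- lr_known(cs$q, cs$other, cs$csp, cs$db, theta = 0.03, quiet = TRUE)
    expect_lte(w3$total_ban, w0$total_ban + 1e-12)
  }
})

test_that("unknown-contributor WoE agrees with exhaustive enumeration", {
  # the ordered genotype-pair count for a 3-allele CSP
  A <- c("a", "b", "c")
  gts <- enumerate_unknown_genotypes(A)
  n_pairs <- 0
  for (gx in gts) for (gu in gts)
    if (setequal(union(gx, gu), A)) n_pairs <- n_pairs + 1
  expect_equal(n_pairs, 12)

  # CSP equal to Q's alleles, theta = 0, both databases identical
  q <- str_profile("Q", list(L1 = c("a", "b")))
  cx <- csp("C", list(L1 = c("a", "b")))
  db <- tiny_db(L1 = c(a = 30, b = 50, c = 20))
  w <- lr_unknown(q, cx, db, db, theta_x = 0, theta_u = 0)
  f <- oracle_freqs(db$tables$L1, c("a", "b"), c("a", "b"))
  o <- oracle_lik_unknown(f, f, c("a", "b"), c("a", "b"), 0, 0, cross = TRUE)
  expect_equal(w$total_ban, log10(o$hp) - log10(o$hd), tolerance = 1e-12)

  # single-allele locus: Hp = P(aa), Hd = P(aa)^2, LR = 1/P(aa)
  q1 <- str_profile("Q", list(L1 = c("a", "a")))
  cx1 <- csp("C", list(L1 = "a"))
  db1 <- tiny_db(L1 = c(a = 40, b = 60))
  w1 <- lr_unknown(q1, cx1, db1, db1, theta_x = 0, theta_u = 0)
  f1 <- oracle_freqs(db1$tables$L1, "a", c("a", "a"))
  expect_equal(10^w1$total_ban, 1 / f1[["a"]]^2, tolerance = 1e-12)
})

test_that("per-locus likelihoods are invariant to allele relabelling", {
  set.seed(23)
  cs <- rand_case()
  relabel <- stats::setNames(paste0(rev(letters)[1:6], ".2"), letters[1:6])
  swap <- function(x) unname(relabel[x])
  db_r <- tiny_db("D1", L1 = stats::setNames(cs$counts, swap(names(cs$counts))))
  q_r <- str_profile("Q", list(L1 = swap(cs$gq)))
  o_r <- str_profile("O", list(L1 = swap(cs$g2)))
  c_r <- csp("C", list(L1 = swap(cs$A)))
  expect_equal(lr_known(cs$q, cs$other, cs$csp, cs$db, 0.03,
                        quiet = TRUE)$total_ban,
               lr_known(q_r, o_r, c_r, db_r, 0.03, quiet = TRUE)$total_ban,
               tolerance = 1e-12)
  expect_equal(lr_unknown(cs$q, cs$csp, cs$db, cs$db, 0.03, 0.03,
                          quiet = TRUE)$total_ban,
               lr_unknown(q_r, c_r, db_r, db_r, 0.03, 0.03,
                          quiet = TRUE)$total_ban,
               tolerance = 1e-12)
})

test_that("zero-observation CSP alleles are floored with a warning", {
  q <- str_profile("Q", list(L1 = c("a", "a")))
  k <- str_profile("K", list(L1 = c("b", "b")))
  cx <- csp("C", list(L1 = c("a", "b")))
  db <- tiny_db(L1 = c(a = 10, c = 90))  # allele b unobserved
  expect_warning(w <- lr_known(q, k, cx, db, theta = 0), "floored")
  expect_true(is.finite(w$total_ban))
  expect_silent(lr_known(q, k, cx, db, theta = 0, quiet = TRUE))
})

test_that("the heuristic dispatches to the matching hypothesis pair", {
  set.seed(24)
  cs <- rand_case()
  db_q <- cs$db
  # single-contributor CSP
  expect_equal(heuristic_woe(q = cs$q, db_q = db_q)$total_ban,
               lr_single(cs$q, db_q, theta = 0.03)$total_ban)
  # known second contributor
  expect_equal(heuristic_woe(cs$q, cs$csp, db_q, k = cs$other,
                             quiet = TRUE)$total_ban,
               lr_known(cs$q, cs$other, cs$csp, db_q, theta = 0.03,
                        quiet = TRUE)$total_ban)
  # unknown second contributor
  expect_equal(heuristic_woe(cs$q, cs$csp, db_q, second_unknown = TRUE,
                             quiet = TRUE)$total_ban,
               lr_unknown(cs$q, cs$csp, db_q, db_q, 0.03, 0.03,
                          quiet = TRUE)$total_ban)
  # theta-monotonicity: the heuristic never exceeds the theta = 0 analysis
  # (rare-allele regime)
  for (rep in 1:20) {
    cs <- rand_case_rare()
    expect_lte(heuristic_woe(q = cs$q, db_q = cs$db)$total_ban,
               lr_single(cs$q, cs$db, theta = 0)$total_ban + 1e-12)
  }
})

test_that("minimum-alternative search honours the theta rule and min property", {
  set.seed(25)
  cs <- rand_case()
  # a lone alternative that IS the database of Q gets theta = 0.03
  solo <- min_alternative_woe(cs$q, alt_dbs = list(cs$db), mode = "single",
                              db_q_name = "D1")
  expect_equal(solo$total_ban, lr_single(cs$q, cs$db, theta = 0.03)$total_ban)
  expect_equal(solo$db_choice, "D1")

  # the minimum is <= every element
  alts <- list(cs$db2, tiny_db("D3", L1 = rand_counts(6)),
               tiny_db("D4", L1 = rand_counts(6)))
  best <- min_alternative_woe(cs$q, alt_dbs = alts, mode = "single",
                              db_q_name = "D1", quiet = TRUE)
  each <- vapply(alts, function(d)
    lr_single(cs$q, d, theta = 0, quiet = TRUE)$total_ban, numeric(1))
  expect_equal(best$total_ban, min(each), tolerance = 1e-12)
  # ties resolve to the first database in list order
  twin <- cs$db2
  twin$name <- "TWIN"
  tie <- min_alternative_woe(cs$q, alt_dbs = list(cs$db2, twin),
                             mode = "single", db_q_name = "D1", quiet = TRUE)
  expect_equal(tie$db_choice, "D2")
})
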