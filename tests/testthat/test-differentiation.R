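test_that("pairing scheme is the five distinct rotations", {
  sch <- pairing_scheme()
  expect_length(sch, 5)
  expect_equal(sch[[1]], 1:5)
  expect_equal(sch[[2]], c(2:5, 1L))
  expect_equal(length(unique(lapply(sch, identity))), 5)
  for (s in sch) expect_setequal(s, 1:5)  # each pairing is a bijection
})

test_that("CMH agrees with the stratified-test reference on small tables", {
  # exhaustive sweep of single-stratum tables with margins <= 6
  for (a in 0:3) for (b in 0:3) for (c_ in 0:3) for (d in 0:3) {
    tab <- array(c(a, c_, b, d), c(2, 2, 1))
    ours <- cmh_test(tab)
    if (any(rowSums(tab[, , 1]) == 0) || any(colSums(tab[, , 1]) == 0) ||
        sum(tab) < 2) {
      expect_true(ours$degenerate)
      expect_equal(ours$p.value, 1)
    } else {
      # single-stratum CMH equals Pearson chi-square scaled by (n-1)/n
      n <- sum(tab)
      ref <- suppressWarnings(chisq.test(tab[, , 1], correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic) * (n - 1) / n,
                   tolerance = 1e-12)
      expect_equal(ours$p.value,
                   pchisq(unname(ref$statistic) * (n - 1) / n, 1,
                          lower.tail = FALSE), tolerance = 1e-12)
    }
  }
  # random multi-stratum tables
  set.seed(42)
  for (k in c(2, 5, 6)) {
    for (rep in 1:25) {
      tab <- array(rbinom(4 * k, 12, 0.4) + 1L, c(2, 2, k))
      ours <- cmh_test(tab)
      ref <- mantelhaen.test(tab, correct = FALSE)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
  }
  # continuity-corrected variant matches R's corrected default (K = 2)
  tab <- array(rep(c(8, 2, 2, 8), 2), c(2, 2, 2))
  expect_equal(cmh_test(tab, correct = TRUE)$p.value,
               mantelhaen.test(tab, correct = TRUE)$p.value, tolerance = 1e-12)
})

test_that("CMH evidence accumulates over strata and vanishes without association", {
  flat <- array(rep(10, 24), c(2, 2, 6))
  expect_equal(cmh_test(flat)$statistic, 0)
  expect_equal(cmh_test(flat)$p.value, 1)
  one <- cmh_test(array(c(8, 2, 2, 8), c(2, 2, 1)))$p.value
  six <- cmh_test(array(rep(c(8, 2, 2, 8), 6), c(2, 2, 6)))$p.value
  expect_lt(six, one)
})

test_that("Benjamini-Yekutieli q-values match the closed form", {
  expect_equal(by_adjust(0.01), 0.01)           # m = 1, c(1) = 1
  q <- by_adjust(c(0.5, 0.001))                 # m = 2, c(2) = 1.5
  expect_equal(q, c(0.75, 0.003))
  # all-equal p: q = min(1, p * m * c(m) / m) = min(1, p * c(m))
  for (m in c(3, 10, 57)) {
    cm <- sum(1 / seq_len(m))
    expect_equal(by_adjust(rep(0.02, m)), rep(min(1, 0.02 * cm), m))
  }
  expect_equal(by_adjust(numeric(0)), numeric(0))
  expect_error(by_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

scan_fixture <- function(minor_fun, cov = 20, n = 4) {
  man <- default_manifest()
  minor <- matrix(0L, n, nrow(man))
  covm <- matrix(cov, n, nrow(man))
  for (j in seq_len(nrow(man))) minor[, j] <- minor_fun(man$population[j], n)
  make_design_bi(minor, covm)
}

test_that("scan of identical groups yields p = q = 1 and no beta calls", {
  bi <- scan_fixture(function(pop, n) rep(8L, n))
  res <- scan_pair(bi, "Salt", "Cad", ancestor1 = "AS", ancestor2 = "AC")
  expect_true(all(res$p_comb == 1))
  expect_true(all(res$q_comb == 1))
  expect_true(all(res$dp == 0))
  expect_false(any(call_beta(res)))
})

test_that("replicate-symmetric data gives identical p across pairings", {
  bi <- scan_fixture(function(pop, n) {
    if (grepl("^Salt|^AS", pop)) rep(15L, n) else rep(5L, n)
  })
  res <- scan_pair(bi, "Salt", "Cad", ancestor1 = "AS", ancestor2 = "AC")
  for (j in 2:5) expect_equal(res[[sprintf("p%d", j)]], res$p1)
  expect_equal(res$p_comb, res$p1)  # geometric mean of equal values
  expect_equal(res$dp, rep(0.5, nrow(res)))
})

test_that("a strongly differentiated planted site is called beta", {
  # 0.9 vs 0.1 at coverage 20 in all twelve populations
  bi <- scan_fixture(function(pop, n) {
    base <- if (grepl("^Salt|^AS", pop)) 18L else 2L
    rep(base, n)
  }, n = 6)
  res <- scan_pair(bi, "Salt", "Cad", ancestor1 = "AS", ancestor2 = "AC")
  expect_true(all(res$q_comb < 1e-5))
  expect_true(all(call_beta(res)))
  expect_true(all(call_beta(res, rule = "per_pairing")))
})

test_that("beta calling rules behave per definition", {
  res <- data.table::data.table(
    q1 = c(1e-6, 1e-6), q2 = c(1e-6, 1e-6), q3 = c(1e-6, 1e-6),
    q4 = c(1e-6, 1e-6), q5 = c(1e-6, 1e-4), q_comb = c(1e-6, 1e-6))
  expect_equal(call_beta(res, "per_pairing"), c(TRUE, FALSE))
  expect_equal(call_beta(res, "combined"), c(TRUE, TRUE))
  expect_error(call_beta(res, "nope"))
  expect_equal(call_beta(res[0]), logical(0))
})

test_that("pseudo-treatment splits are deterministic and null on copies", {
  # every population identical: no split can find differentiation
  bi <- scan_fixture(function(pop, n) rep(7L, n), n = 10)
  ps <- pseudo_treatment_null(bi, n_combinations = 4, seed = 11)
  expect_equal(ps$beta_count, rep(0L, 4))
  ps2 <- pseudo_treatment_null(bi, n_combinations = 4, seed = 11)
  expect_identical(ps$beta_count, ps2$beta_count)
  expect_equal(attr(ps, "mean"), 0)
  man <- population_manifest(c("a", "b"), c("Salt", "Cad"), c(1L, 1L))
  bad <- make_design_bi(matrix(1, 2, 22), matrix(10, 2, 22), include_ga = FALSE)
  bad$manifest <- population_manifest(
    bad$manifest$population, c("Salt", rep("Cad", 21)),
    c(1L, seq_len(21)), 140)
  expect_error(pseudo_treatment_null(bad), "at least two")
})

test_that("window summaries use 5 kb half-open arithmetic", {
  res <- data.table::data.table(
    chrom = "2L", pos = c(1L, 4999L, 5000L, 5001L),
    q_comb = c(0.01, 0.1, 0.001, 0.5), dp = c(0.1, 0.2, 0.3, 0.4))
  w <- window_differentiation(res)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(1L, 5001L))
  expect_equal(w$end, c(5000L, 10000L))
  # sites at 5000 and 5001 land in different windows
  expect_equal(w$n, c(3L, 1L))
  # mean of -log10(q): window 1 holds q = 0.01, 0.1, 0.001 -> mean 2
  expect_equal(w$mean_neglogq[1], 2)
  one <- window_differentiation(data.table::data.table(
    chrom = "2L", pos = 1L, q_comb = 0.01, dp = 0))
  expect_equal(one$mean_neglogq, 2)
  expect_equal(c(one$start, one$end), c(1L, 5000L))
})
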