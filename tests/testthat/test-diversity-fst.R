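test_that("heterozygosities follow the within/total definitions", {
  h <- heterozygosities(matrix(c(1, 0), 1))
  expect_equal(h$H_S, 0)
  expect_equal(h$H_T, 0.5)
  h2 <- heterozygosities(matrix(rep(0.3, 5), 1))
  expect_equal(h2$H_S, 0.42)
  expect_equal(h2$H_T, 0.42)
  h3 <- heterozygosities(matrix(c(0.2, 0.4), 1))
  expect_equal(h3$H_S, 0.40)
  expect_equal(h3$H_T, 0.42)
})

test_that("Nei F_ST is the ratio of averaged heterozygosities", {
  h <- heterozygosities(matrix(c(1, 0, 1, 0, 1), 1))
  expect_equal(fst_nei(h$H_S, h$H_T), 1)
  expect_equal(fst_nei(c(0.3, 0.4), c(0.3, 0.4)), 0)
  expect_equal(fst_nei(c(0.40, 0.48), c(0.42, 0.48)), 1 - 0.88 / 0.90)
  # mean-of-ratios variant differs in general
  expect_equal(fst_nei(c(0.40, 0.48), c(0.42, 0.48), "mean_of_ratios"),
               mean(c(1 - 0.40 / 0.42, 0)))
  expect_error(fst_nei(0, 0), "undefined")
  # H_T = 0 sites are excluded from both means
  expect_equal(fst_nei(c(0.40, 0), c(0.42, 0)), 1 - 0.40 / 0.42)
})

test_that("windowed pi matches a direct per-site computation", {
  # population with one SNP (10/10 at coverage 20) and 99 invariant sites
  n <- 100
  cm <- matrix(0, n, 6)
  cm[, 1] <- 20            # invariant A sites at 20x
  cm[50, ] <- c(10, 0, 10, 0, 0, 0)
  s <- make_sync(list(p1 = cm), pos = 1:100, pool_size = 140)
  w <- window_pi(s, "p1", window = 100, min_fraction = 0.6)
  site_pi <- 0.5 * (20 / 19) * (140 / 139)   # nested correction oracle
  expect_equal(w$pi, site_pi / 100)
  expect_equal(w$n_sites, 100L)
  expect_true(w$valid)
  # raw mode drops the correction
  w_raw <- window_pi(s, "p1", window = 100, corrected = FALSE)
  expect_equal(w_raw$pi, 0.5 / 100)
  # a monomorphic window has pi 0
  s0 <- make_sync(list(p1 = matrix(rep(c(20, 0, 0, 0, 0, 0), each = 70),
                                   70)), pos = 1:70)
  expect_equal(window_pi(s0, "p1", window = 70)$pi, 0)
})

test_that("window validity needs 60% of positions at 4x", {
  n <- 100
  cm <- matrix(0, n, 6)
  cm[1:50, 1] <- 10        # only half the window covered
  s <- make_sync(list(p1 = cm), pos = 1:100)
  w <- window_pi(s, "p1", window = 100)
  expect_false(w$valid)
  expect_equal(w$fraction, 0.5)
  # below min_count the site is treated as invariant
  cm2 <- matrix(0, 70, 6)
  cm2[, 1] <- 19
  cm2[1, 3] <- 1           # singleton minor read: not a SNP at min_count 2
  s2 <- make_sync(list(p1 = cm2), pos = 1:70)
  expect_equal(window_pi(s2, "p1", window = 70)$pi, 0)
  expect_error(window_pi(s2, "p1", pool_size = 1), "pool_size")
})

test_that("windowed pi is deterministic and per-population", {
  set.seed(5)
  cm <- matrix(0, 200, 6)
  cm[, 1] <- rpois(200, 15)
  cm[, 3] <- rpois(200, 5)
  s <- make_sync(list(p1 = cm, p2 = cm), pos = 1:200)
  w1 <- window_pi(s, "p1", window = 100)
  w2 <- window_pi(s, "p2", window = 100)
  expect_equal(w1$pi, w2$pi)
})

test_that("one-way ANOVA and Tukey HSD match closed-form sums of squares", {
  vals <- c(1.1, 0.9, 1.0, 1.2, 0.8,
            2.0, 2.1, 1.9, 2.2, 1.8,
            1.5, 1.4, 1.6, 1.5, 1.5,
            1.0, 1.1, 0.9, 1.0, 1.0)
  grp <- rep(c("Salt", "Cad", "Temp", "Spatial"), each = 5)
  res <- anova_tukey(vals, grp)
  # hand computation of the F statistic
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- 5 * sum((means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_hand <- (ssb / 3) / (ssw / 16)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$df, c(3, 16))
  expect_equal(res$p.value, pf(f_hand, 3, 16, lower.tail = FALSE))
  # Tukey adjusted p from the studentized range, for one pair
  se <- sqrt(ssw / 16 * 2 / 5)
  qstat <- abs(means["Cad"] - means["Salt"]) / (se / sqrt(2))
  expect_equal(res$tukey[pair == "Salt-Cad"]$p_adj,
               unname(ptukey(qstat, 4, 16, lower.tail = FALSE)),
               tolerance = 1e-8)

  expect_equal(anova_tukey(rep(1, 20), grp)$F, 0)
  expect_equal(anova_tukey(rep(1, 20), grp)$p.value, 1)
  deg <- anova_tukey(rep(c(0, 1), each = 5), rep(c("a", "b"), each = 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "at least 2")
})

test_that("per-treatment pi by stratum averages replicates then treatments", {
  pi_mat <- matrix(0, 1, 23)
  man <- default_manifest()
  colnames(pi_mat) <- man$population
  pi_mat[1, paste0("Salt", 1:5)] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  strat <- factor("low", levels = c("low", "mid", "high"))
  out <- pi_by_stratum(pi_mat, strat, man, treatments = "Salt")
  expect_equal(out[stratum == "low"]$mean_pi, 0.3)
  expect_equal(out[stratum == "low"]$se, sqrt(0.025) / sqrt(5))
  # identical replicates: SE exactly 0
  pi_mat[1, paste0("Salt", 1:5)] <- 0.2
  out2 <- pi_by_stratum(pi_mat, strat, man, treatments = "Salt")
  expect_equal(out2[stratum == "low"]$se, 0)
  # empty stratum is flagged undefined, not zero
  expect_true(out[stratum == "high"]$empty)
  expect_true(is.na(out[stratum == "high"]$mean_pi))
})

test_that("coverage matching reduces to plain F_ST at equal coverage", {
  set.seed(9)
  n <- 60
  man <- default_manifest()
  minor <- matrix(rbinom(n * 23, 20, 0.4), n, 23)
  cov <- matrix(20L, n, 23)
  bi <- make_design_bi(minor, cov)
  cm <- coverage_matched_fst(bi, treatments = c("Salt", "Cad"),
                             repeats = 3, seed = 1)
  # with all coverages equal the subsample is the full sample: exact equality
  fr <- allele_freq(bi)
  for (tr in c("Salt", "Cad")) {
    h <- heterozygosities(fr[, paste0(tr, 1:5)])
    expect_equal(cm[treatment == tr]$fst, fst_nei(h$H_S, h$H_T),
                 tolerance = 1e-12)
    expect_equal(cm[treatment == tr]$sd_fst, 0)
  }
  # determinism under a fixed seed with genuinely unequal coverage
  cov2 <- matrix(sample(10:30, n * 23, TRUE), n, 23)
  minor2 <- matrix(rbinom(n * 23, 10, 0.4), n, 23)
  bi2 <- make_design_bi(minor2, cov2)
  a <- coverage_matched_fst(bi2, repeats = 4, seed = 7)
  b <- coverage_matched_fst(bi2, repeats = 4, seed = 7)
  expect_identical(a, b)
  expect_true(all(is.finite(a$fst)))
})

test_that("region assignment follows the printed boundaries", {
  expect_equal(assign_region("2L", 5000000), "2L-left")
  expect_equal(assign_region("2L", 7307159), "2L-left")
  expect_equal(assign_region("2L", 8000000), "none")
  expect_equal(assign_region("2R", 10368692), "2R-right")
  expect_equal(assign_region("2R", 10368691), "none")
  expect_equal(assign_region("3L", 7753554), "none")
  expect_equal(assign_region("3R", 17055561), "3R-right")
  expect_equal(assign_region("X", 1), "X")
  expect_error(assign_region("4", 1), "unknown")
})

test_that("X-autosome contrast is a paired t-test across treatments", {
  ft <- data.table::data.table(
    treatment = rep(c("Salt", "Cad", "Temp", "Spatial"), each = 2),
    region = rep(c("X", "2L-left"), 4),
    fst = c(0.11, 0.10, 0.12, 0.10, 0.12, 0.10, 0.13, 0.10))
  res <- x_autosome_contrast(ft)
  d <- c(0.01, 0.02, 0.02, 0.03)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(res$df, 3)
  # identical values: t = 0, p = 1
  ft0 <- data.table::copy(ft)[, fst := 0.1]
  expect_equal(x_autosome_contrast(ft0)$t, 0)
  expect_equal(x_autosome_contrast(ft0)$p.value, 1)
  # constant nonzero difference: degenerate
  ftc <- data.table::copy(ft)[, fst := rep(c(0.12, 0.10), 4)]
  expect_true(x_autosome_contrast(ftc)$degenerate)
  expect_error(x_autosome_contrast(ft[1:2]), "two treatments")
})
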