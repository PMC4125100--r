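test_that("enrichment ratios standardize to mean 1 over usable bins", {
  # equal ratio everywhere: all standardized ratios exactly 1
  set.seed(3)
  q <- rep(10^-(seq(0.05, 10.95, length.out = 11)), each = 3)
  cls <- rep(c("genic", "genic", "intergenic"), 11)
  e <- enrichment_by_bin(q, factor(cls, levels = c("genic", "intergenic")))
  expect_equal(e$ratio, rep(2, 11))
  expect_equal(e$std_ratio, rep(1, 11))
  # ratios (2, 1 x 10): mean 12/11, first standardized ratio 11/6
  q2 <- 10^-(rep(seq(0.5, 10.5), each = 2))
  cls2 <- rep(c("a", "b"), 11)
  q2 <- c(q2, 10^-0.5)  # one extra class-a site in the first bin
  cls2 <- c(cls2, "a")
  e2 <- enrichment_by_bin(q2, factor(cls2, levels = c("a", "b")))
  expect_equal(e2$ratio[1], 2)
  expect_equal(e2$std_ratio[1], 2 / (12 / 11), tolerance = 1e-12)
  # empty denominator bins are flagged and excluded from the mean
  e3 <- enrichment_by_bin(c(0.5, 0.5, 1e-11), factor(c("a", "b", "a"),
                                                     levels = c("a", "b")))
  expect_true(e3$flagged[11])
  expect_equal(mean(e3$std_ratio[!e3$flagged], na.rm = TRUE), 1)
  expect_error(enrichment_by_bin(numeric(0), factor(character(0))), "no sites")
})

test_that("clustered beta-sites exceed the permutation band, uniform ones do not", {
  set.seed(14)
  n <- 800
  pos <- sort(sample.int(2e6, n))
  # extreme clustering: all beta in one contiguous run
  beta <- logical(n)
  beta[400:439] <- TRUE
  st <- data.table::data.table(chrom = "2L", pos = pos, beta = beta)
  out <- beta_clustering(st, window_lengths = c(50000), n_focal = 40,
                         n_perm = 40, seed = 2)
  expect_gt(out$observed, out$perm_hi)
  expect_gt(out$observed, 0.5)
  # uniformly scattered labels stay inside the band
  beta_u <- logical(n)
  beta_u[sample(n, 40)] <- TRUE
  st_u <- data.table::data.table(chrom = "2L", pos = pos, beta = beta_u)
  out_u <- beta_clustering(st_u, window_lengths = c(50000), n_focal = 40,
                           n_perm = 60, seed = 2)
  expect_gte(out_u$observed, out_u$perm_lo)
  expect_lte(out_u$observed, out_u$perm_hi)
  expect_error(beta_clustering(data.table::data.table(
    chrom = "2L", pos = 1:3, beta = FALSE)), "no beta")
})

test_that("F_ST decay bins are variance-weighted and exclude the focal site", {
  focal <- data.table::data.table(chrom = "2L", pos = 1000L)
  sites <- data.table::data.table(
    chrom = "2L", pos = c(1000L, 1010L, 1030L, 1070L),
    fst = c(0.9, 0.1, 0.5, 0.3), weight = c(5, 1, 3, 2))
  out <- fst_decay(focal, sites, window = 50, max_dist = 2000)
  # first bin: sites at distance 10 and 30 (focal excluded), weights 1 and 3
  expect_equal(out$mean_fst[1], 0.4)
  expect_equal(out$mean_fst[2], 0.3)  # distance 70 -> second bin
  expect_true(all(is.na(out$mean_fst[3:40])))
  # constant F_ST: every usable bin equals the constant
  sites2 <- data.table::data.table(chrom = "2L", pos = seq(900L, 3100L, 25L),
                                   fst = 0.3, weight = 1)
  out2 <- fst_decay(focal, sites2)
  expect_true(all(abs(out2$mean_fst - 0.3) < 1e-12, na.rm = TRUE))
})

test_that("inversion frequencies are coverage-weighted marker means", {
  # markers at freq 0.2 (10x) and 0.5 (30x) -> 0.425
  cm <- matrix(0, 2, 6)
  cm[1, ] <- c(8, 2, 0, 0, 0, 0)    # T allele at 0.2, coverage 10
  cm[2, ] <- c(15, 15, 0, 0, 0, 0)  # T allele at 0.5, coverage 30
  s <- make_sync(list(p1 = cm), pos = c(100L, 200L))
  mk <- data.table::data.table(inversion = "In(2L)t", chrom = "2L",
                               pos = c(100L, 200L), allele = "T")
  out <- inversion_frequency(mk, s)
  expect_equal(out$frequency, 0.425)
  # equal frequencies at any coverages stay put
  cm2 <- rbind(c(9, 1, 0, 0, 0, 0), c(90, 10, 0, 0, 0, 0))
  s2 <- make_sync(list(p1 = cm2), pos = c(100L, 200L))
  expect_equal(inversion_frequency(mk, s2)$frequency, 0.1)
  # splitting a marker's counts into two markers at the same position/freq
  cm3 <- rbind(c(45, 5, 0, 0, 0, 0), c(45, 5, 0, 0, 0, 0))
  s3 <- make_sync(list(p1 = cm3), pos = c(100L, 200L))
  expect_equal(inversion_frequency(mk, s3)$frequency,
               inversion_frequency(mk[1], s3)$frequency)
  # no covered marker: undefined
  cm4 <- matrix(0, 2, 6)
  s4 <- make_sync(list(p1 = cm4), pos = c(100L, 200L))
  expect_true(is.na(inversion_frequency(mk, s4)$frequency))
})

test_that("conditional-neutrality classification applies both printed rules", {
  # cad side: |p_AC - p_GA| < 0.1 and |p_Cad - p_ini| < 0.1
  expect_equal(as.character(classify_conditional_neutrality(
    p_GA = 0.45, p_AC = 0.50, p_AS = 0.50, p_Cad = 0.52, p_Salt = 0.9)),
    "CN-in-cad")
  expect_equal(as.character(classify_conditional_neutrality(
    p_GA = 0.30, p_AC = 0.50, p_AS = 0.50, p_Cad = 0.52, p_Salt = 0.9)),
    "neither")
  expect_equal(as.character(classify_conditional_neutrality(
    p_GA = 0.5, p_AC = 0.5, p_AS = 0.5, p_Cad = 0.5, p_Salt = 0.5)),
    "both")
  lab <- classify_conditional_neutrality(
    p_GA = c(0.45, 0.45), p_AC = c(0.5, 0.5), p_AS = c(0.5, 0.45),
    p_Cad = c(0.52, 0.5), p_Salt = c(0.9, 0.47))
  expect_equal(as.character(lab), c("CN-in-cad", "both"))
})

test_that("standardized correlation is a difference of Pearson correlations", {
  set.seed(21)
  n <- 200
  pA <- runif(n)
  pB <- pA + rnorm(n, 0, 0.05)
  sel <- 1:100
  ctl <- 101:200
  out <- standardized_correlation(pA, pB, sel, ctl)
  expect_equal(out$diff_cor, cor(pA[sel], pB[sel]) - cor(pA[ctl], pB[ctl]))
  # identical sets: exactly zero
  expect_equal(standardized_correlation(pA, pB, sel, sel)$diff_cor, 0)
  # antisymmetry under swapping selected and control
  sw <- standardized_correlation(pA, pB, ctl, sel)
  expect_equal(sw$diff_cor, -out$diff_cor)
  # constructed anticorrelation: selected pB = 1 - pA, control independent
  pB2 <- pB
  pB2[sel] <- 1 - pA[sel]
  pB2[ctl] <- runif(100)
  out2 <- standardized_correlation(pA, pB2, sel, ctl)
  expect_lt(out2$cor_selected, -0.999)
  expect_lt(abs(out2$cor_control), 0.3)
  # degenerate inputs flagged
  expect_true(standardized_correlation(rep(0.5, n), pB, sel, ctl)$degenerate)
  expect_error(standardized_correlation(pA, pB, 1:2, ctl), "at least 3")
})

test_that("control matching reproduces the pi_ini profile of selected sites", {
  set.seed(8)
  pi_ini <- c(runif(300, 0, 0.5), runif(300, 0.3, 0.5))
  sel <- 301:600
  ctl <- match_control_sites(1:300, sel, pi_ini, method = "pi_ini", seed = 4)
  expect_true(all(ctl <= 300))
  expect_lt(abs(mean(pi_ini[ctl]) - mean(pi_ini[sel])), 0.05)
  ctl2 <- match_control_sites(1:300, sel, pi_ini, method = "none", seed = 4)
  expect_length(ctl2, 300)
})

test_that("Fisher screen p-values match the hypergeometric enumeration", {
  # identical ancestors: p = 1
  bi <- make_design_bi(matrix(5, 1, 23), matrix(20, 1, 23))
  expect_equal(fisher_screen(bi)$p, 1)
  # complete separation (20,0 / 0,20)
  minor <- matrix(5, 1, 23); cov <- matrix(20, 1, 23)
  minor[1, 2] <- 20; minor[1, 3] <- 0   # AS all minor, AC none
  bi2 <- make_design_bi(minor, cov)
  expect_equal(fisher_screen(bi2)$p, 2 / choose(40, 20), tolerance = 1e-12)
  # random tables against a direct two-sided hypergeometric-sum oracle
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    supp <- max(0, k - n):min(k, m)
    dens <- dhyper(supp, m, n, k)
    sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(31)
  for (i in 1:20) {
    a <- rbinom(1, 15, 0.5); b <- 15 - a
    c_ <- rbinom(1, 12, 0.3); d <- 12 - c_
    minor <- matrix(3, 1, 23); cov <- matrix(20, 1, 23)
    minor[1, 2] <- a; cov[1, 2] <- a + b
    minor[1, 3] <- c_; cov[1, 3] <- c_ + d
    bi3 <- make_design_bi(minor, cov)
    expect_equal(fisher_screen(bi3)$p[1], fisher_oracle(a, b, c_, d),
                 tolerance = 1e-7)
  }
  # all-zero allelic coverage in an ancestor: degenerate p = 1
  minor <- matrix(4, 1, 23); cov <- matrix(20, 1, 23)
  minor[1, 2] <- 0; cov[1, 2] <- 0
  expect_equal(fisher_screen(make_design_bi(minor, cov))$p, 1)
})
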