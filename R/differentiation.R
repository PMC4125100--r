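# Replicated Cochran-Mantel-Haenszel differentiation scans between treatment
# groups, Benjamini-Yekutieli control, beta-site calling, the
# pseudo-treatment permutation null, and 5 kb window summaries.

#' Replicate pairing scheme for stratified tests
#'
#' The CMH test pairs one replicate of each group per stratum. Because the
#' pairing of replicates is arbitrary, the scan is repeated under five
#' distinct rotational pairings: the j-th pairing matches replicate `i` of
#' group 1 with replicate `((i + j - 2) mod n) + 1` of group 2.
#'
#' @param n_replicates replicates per group (default 5).
#' @return list of `n_replicates` integer vectors; element `j` gives, for
#'   each group-1 replicate, the index of its group-2 partner.
#' @export
pairing_scheme <- function(n_replicates = 5) {
  lapply(seq_len(n_replicates) - 1L, function(shift) {
    ((seq_len(n_replicates) - 1L + shift) %% n_replicates) + 1L
  })
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Continuity-correction-free CMH chi-square statistic with 1 df and its
#' upper-tail p-value. Strata with a zero row or column margin are
#' uninformative and contribute nothing; if every stratum is degenerate the
#' test returns statistic 0 and p = 1 with `degenerate = TRUE`.
#'
#' @param tables a `2 x 2 x K` integer array of counts (rows = groups,
#'   columns = alleles).
#' @param correct apply the 0.5 continuity correction (default `FALSE`).
#' @return list with `statistic`, `p.value`, `df` and `degenerate`.
#' @export
#' @examples
#' cmh_test(array(c(10, 0, 0, 10), c(2, 2, 1)))
cmh_test <- function(tables, correct = FALSE) {
  if (length(dim(tables)) == 2) dim(tables) <- c(dim(tables), 1L)
  stopifnot(length(dim(tables)) == 3, all(dim(tables)[1:2] == 2))
  k <- dim(tables)[3]
  a <- matrix(tables[1, 1, ], 1, k); b <- matrix(tables[1, 2, ], 1, k)
  c_ <- matrix(tables[2, 1, ], 1, k); d <- matrix(tables[2, 2, ], 1, k)
  res <- cmh_stat(a, b, c_, d, correct = correct)
  list(statistic = res$stat[1], p.value = res$p[1], df = 1L,
       degenerate = res$degenerate[1])
}

# vectorised CMH over sites: a, b, c, d are site x stratum matrices holding
# the 2x2 cells (a = group1/minor, b = group1/major, c = group2/minor,
# d = group2/major)
cmh_stat <- function(a, b, c_, d, correct = FALSE) {
  n <- a + b + c_ + d
  r1 <- a + b
  c1 <- a + c_
  informative <- n >= 2 & r1 > 0 & (n - r1) > 0 & c1 > 0 & (n - c1) > 0
  e <- ifelse(informative, r1 * c1 / n, 0)
  v <- ifelse(informative,
              r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1)), 0)
  num <- rowSums(ifelse(informative, a, 0) - e)
  den <- rowSums(v)
  if (correct) num <- sign(num) * pmax(abs(num) - 0.5, 0)
  stat <- ifelse(den > 0, num^2 / den, 0)
  p <- ifelse(den > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(stat = stat, p = p, degenerate = den <= 0)
}

#' Benjamini-Yekutieli q-values
#'
#' FDR adjustment valid under arbitrary dependence:
#' `q(i) = min_{j >= i} min(1, p(j) * m * c(m) / j)` for sorted p-values,
#' with `c(m) = sum_{k=1}^m 1/k`; results are returned in input order.
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
by_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BY")
}

#' Subset biallelic sites
#'
#' @param bi a [reduce_biallelic()] result.
#' @param idx logical or integer index over sites.
#' @return the subsetted `biallelic` object.
#' @export
subset_biallelic <- function(bi, idx) {
  structure(
    list(sites = bi$sites[idx],
         minor_count = bi$minor_count[idx, , drop = FALSE],
         allelic_cov = bi$allelic_cov[idx, , drop = FALSE],
         coverage = bi$coverage[idx, , drop = FALSE],
         manifest = bi$manifest),
    class = "biallelic")
}

#' Differentiation scan between two population groups
#'
#' Runs, at every site, the CMH test under each of the five replicate
#' pairings (optionally pinning the two ancestral populations as a fixed
#' stratum in every pairing), combines the five p-values by their geometric
#' mean, and converts both the combined p and each per-pairing p-vector to
#' Benjamini-Yekutieli q-values across sites.
#'
#' @param bi a [reduce_biallelic()] result, usually already restricted to
#'   screened sites via [subset_biallelic()].
#' @param treatment1,treatment2 treatment labels of the two groups.
#' @param ancestor1,ancestor2 optional ancestral population ids appended to
#'   group 1 and group 2 as a fixed stratum (`NULL` to scan replicates
#'   only).
#' @param scheme a [pairing_scheme()].
#' @param correct CMH continuity correction flag.
#' @return `data.table` with chrom, pos, per-pairing p (`p1..p5`) and q
#'   (`q1..q5`) columns, combined `p_comb`/`q_comb`, and `dp`, the absolute
#'   difference in mean minor-allele frequency between the groups.
#' @export
scan_pair <- function(bi, treatment1, treatment2,
                      ancestor1 = NULL, ancestor2 = NULL,
                      scheme = pairing_scheme(), correct = FALSE) {
  pops1 <- treatment_pops(bi$manifest, treatment1)
  pops2 <- treatment_pops(bi$manifest, treatment2)
  if (length(pops1) != length(pops2))
    stop("groups have different replicate counts")
  if (length(scheme) != length(pops1))
    stop("pairing scheme does not match the replicate count")
  n <- nrow(bi$sites)
  pvals <- matrix(NA_real_, n, length(scheme))
  for (j in seq_along(scheme)) {
    pair2 <- pops2[scheme[[j]]]
    a <- bi$minor_count[, pops1, drop = FALSE]
    b <- bi$allelic_cov[, pops1, drop = FALSE] - a
    c_ <- bi$minor_count[, pair2, drop = FALSE]
    d <- bi$allelic_cov[, pair2, drop = FALSE] - c_
    if (!is.null(ancestor1)) {
      a <- cbind(a, bi$minor_count[, ancestor1])
      b <- cbind(b, bi$allelic_cov[, ancestor1] - bi$minor_count[, ancestor1])
      c_ <- cbind(c_, bi$minor_count[, ancestor2])
      d <- cbind(d, bi$allelic_cov[, ancestor2] - bi$minor_count[, ancestor2])
    }
    pvals[, j] <- cmh_stat(a, b, c_, d, correct = correct)$p
  }
  # geometric-mean combination; p floored to dodge log underflow
  p_comb <- exp(rowMeans(log(pmax(pvals, 1e-320))))
  fr <- allele_freq(bi)
  g1 <- rowMeans(fr[, c(pops1, ancestor1), drop = FALSE])
  g2 <- rowMeans(fr[, c(pops2, ancestor2), drop = FALSE])
  out <- data.table(chrom = bi$sites$chrom, pos = bi$sites$pos)
  for (j in seq_along(scheme)) set(out, j = sprintf("p%d", j), value = pvals[, j])
  out[, p_comb := p_comb]
  for (j in seq_along(scheme))
    set(out, j = sprintf("q%d", j), value = by_adjust(pvals[, j]))
  out[, q_comb := by_adjust(p_comb)]
  out[, dp := abs(g1 - g2)]
  out[]
}

#' Call significantly differentiated (beta) sites
#'
#' Two calling rules are supported. `"combined"` thresholds the q-value of
#' the geometric-mean p (the default for the main scan); `"per_pairing"`
#' requires every one of the five per-pairing q-values to pass the cutoff
#' (the rule used for pairwise treatment contrasts).
#'
#' @param results a [scan_pair()] table.
#' @param rule `"combined"` or `"per_pairing"`.
#' @param cutoff q-value cutoff (default `1e-5`, i.e. FDR 0.001%).
#' @return logical vector of beta flags.
#' @export
call_beta <- function(results, rule = c("combined", "per_pairing"),
                      cutoff = 1e-5) {
  rule <- match.arg(rule)
  if (!nrow(results)) return(logical(0))
  if (rule == "combined") {
    results$q_comb <= cutoff
  } else {
    qcols <- grep("^q[0-9]+$", names(results), value = TRUE)
    rowSums(as.matrix(results[, qcols, with = FALSE]) <= cutoff) == length(qcols)
  }
}

#' Pseudo-treatment permutation null
#'
#' Randomly assigns half of each environment's replicate populations to
#' pseudo-treatment "A" and the other half to "B", runs the identical
#' five-pairing scan between the pseudo-treatments, and counts beta calls.
#' Repeated for `n_combinations` random splits; with no differential
#' selection between the environments the counts estimate the scan's
#' false-positive yield.
#'
#' @param bi a [reduce_biallelic()] result restricted to scan-eligible
#'   sites.
#' @param treatment1,treatment2 the two environment labels whose replicates
#'   are shuffled.
#' @param n_combinations number of random splits (default 15).
#' @param rule,cutoff beta-calling rule and cutoff, as in [call_beta()].
#' @param seed RNG seed for the splits.
#' @return `data.table` with one row per combination (`beta_count`) plus
#'   attributes `mean` and `max`.
#' @export
pseudo_treatment_null <- function(bi, treatment1 = "Salt", treatment2 = "Cad",
                                  n_combinations = 15,
                                  rule = "combined", cutoff = 1e-5,
                                  seed = 1L) {
  pops1 <- treatment_pops(bi$manifest, treatment1)
  pops2 <- treatment_pops(bi$manifest, treatment2)
  if (length(pops1) < 2 || length(pops2) < 2)
    stop("need at least two replicate populations per environment")
  set.seed(seed)
  counts <- integer(n_combinations)
  for (k in seq_len(n_combinations)) {
    n1a <- if (length(pops1) %% 2 == 0) length(pops1) / 2 else
      sample(c(floor(length(pops1) / 2), ceiling(length(pops1) / 2)), 1)
    n2a <- length(pops1) - n1a  # keeps both pseudo-groups at 5 populations
    ga <- c(sample(pops1, n1a), sample(pops2, n2a))
    gb <- setdiff(c(pops1, pops2), ga)
    # relabel the split as two pseudo-treatments inside a manifest copy
    m <- as.data.table(bi$manifest)
    m <- m[population %in% c(ga, gb)]
    m[, treatment := ifelse(population %in% ga, "pseudoA", "pseudoB")]
    m[, replicate := seq_len(.N), by = treatment]
    bi2 <- bi
    bi2$manifest <- population_manifest(m$population, m$treatment,
                                        m$replicate, m$pool_size)
    res <- scan_pair(bi2, "pseudoA", "pseudoB",
                     scheme = pairing_scheme(length(ga)))
    counts[k] <- sum(call_beta(res, rule = rule, cutoff = cutoff))
  }
  out <- data.table(combination = seq_len(n_combinations), beta_count = counts)
  setattr(out, "mean", mean(counts))
  setattr(out, "max", max(counts))
  out
}

#' Window summaries of a differentiation scan
#'
#' Non-overlapping windows (1-based, `[k*window + 1, (k+1)*window]`) with
#' the mean `-log10(q)`, the mean allele-frequency difference and the site
#' count; windows without sites are omitted.
#'
#' @param results a [scan_pair()] table.
#' @param window window width in bp (default 5000).
#' @return `data.table` with chrom, start, end, n, mean_neglogq, mean_dp.
#' @export
window_differentiation <- function(results, window = 5000) {
  r <- as.data.table(results)
  r[, start := ((pos - 1L) %/% as.integer(window)) * as.integer(window) + 1L]
  out <- r[, .(n = .N,
               mean_neglogq = mean(-log10(q_comb)),
               mean_dp = mean(dp)),
           by = .(chrom, start)]
  out[, end := start + as.integer(window) - 1L]
  setcolorder(out, c("chrom", "start", "end", "n", "mean_neglogq", "mean_dp"))
  setorder(out, chrom, start)
  out[]
}
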