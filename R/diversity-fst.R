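# Windowed nucleotide diversity with pool-size correction, diversity by
# ancestral-differentiation stratum, Nei F_ST with coverage-matched
# resampling, genomic regions, and the ANOVA / paired-t comparisons.

#' Windowed nucleotide diversity for one population
#'
#' Non-overlapping windows of Tajima's pi. A position qualifies when its
#' (non-N) read coverage lies in `[min_cov, max_cov]`; a qualifying position
#' contributes its per-site pi when its minor allele-category count reaches
#' `min_count` (otherwise it is treated as invariant, contributing 0). The
#' per-site estimate applies the nested pool-sequencing correction
#' `pi_hat = (1 - sum f^2) * c/(c-1) * n/(n-1)` for coverage `c` reads drawn
#' from a pool of `n` chromosomes (disable with `corrected = FALSE` to get
#' the raw `1 - sum f^2`). A window is valid when at least `min_fraction` of
#' its positions qualify.
#'
#' @param sync a [sync_table()].
#' @param pop population id.
#' @param window window width in bp (1-based inclusive windows
#'   `[k*window + 1, (k+1)*window]`).
#' @param min_count minimum minor-category count to call a site variable.
#' @param min_cov,max_cov qualifying coverage range.
#' @param pool_size pool size in chromosomes; overrides the manifest value
#'   when supplied.
#' @param min_fraction minimum fraction of qualifying positions for a valid
#'   window.
#' @param corrected apply the pool-size/coverage correction.
#' @return `data.table` with chrom, start, end, n_sites (qualifying
#'   positions present in the table), pi (mean per-site pi over qualifying
#'   positions), fraction and valid.
#' @export
window_pi <- function(sync, pop, window = 10000, min_count = 2,
                      min_cov = 4, max_cov = 400, pool_size = NULL,
                      min_fraction = 0.6, corrected = TRUE) {
  if (is.null(pool_size)) {
    m <- as.data.table(sync$manifest)
    pool_size <- m[population == pop]$pool_size
    if (!length(pool_size)) stop(sprintf("population '%s' not in manifest", pop))
  }
  if (pool_size < 2) stop("pool_size must be at least 2")
  j <- match(pop, sync$manifest$population)
  if (is.na(j)) stop(sprintf("population '%s' not in manifest", pop))
  cats <- c("A", "T", "C", "G", "D")
  cm <- sync$counts[, cats, j, drop = FALSE]
  dim(cm) <- c(nrow(sync$sites), length(cats))
  cov <- rowSums(cm)
  qual <- cov >= min_cov & cov <= max_cov
  # minor category count = coverage minus the largest single category
  maxc <- do.call(pmax, lapply(seq_len(ncol(cm)), function(b) cm[, b]))
  minor2 <- cov - maxc
  f <- cm / cov
  pi_raw <- 1 - rowSums(f^2)
  pi_corr <- if (corrected) {
    pi_raw * ifelse(cov > 1, cov / (cov - 1), 0) * pool_size / (pool_size - 1)
  } else pi_raw
  pi_used <- ifelse(qual & minor2 >= min_count, pi_corr, 0)
  dt <- data.table(chrom = sync$sites$chrom, pos = sync$sites$pos,
                   qual = qual, pi = pi_used)
  dt[, start := ((pos - 1L) %/% as.integer(window)) * as.integer(window) + 1L]
  out <- dt[, .(n_sites = sum(qual),
                pi = if (sum(qual)) mean(pi[qual]) else NA_real_),
            by = .(chrom, start)]
  out[, end := start + as.integer(window) - 1L]
  out[, fraction := n_sites / window]
  out[, valid := fraction >= min_fraction]
  setcolorder(out, c("chrom", "start", "end", "n_sites", "pi", "fraction", "valid"))
  setorder(out, chrom, start)
  out[]
}

#' Mean diversity per treatment and differentiation stratum
#'
#' Averages per-site diversity within each ancestral-differentiation stratum
#' separately for every replicate population, then summarises each
#' treatment by the mean of its replicate means and the standard error
#' across replicates.
#'
#' @param pi_mat site x population matrix of per-site diversities (e.g.
#'   [pi_sites_by_pop()] restricted to chi-screened sites).
#' @param stratum factor over sites (e.g. `stratify_d()$stratum` or
#'   `$bin`).
#' @param manifest a [population_manifest()] matching the columns.
#' @param treatments treatment labels to summarise.
#' @return `data.table` with treatment, stratum, n_sites, mean_pi, se
#'   (`NA` with `empty = TRUE` for strata without sites).
#' @export
pi_by_stratum <- function(pi_mat, stratum, manifest,
                          treatments = c("Salt", "Cad", "Temp", "Spatial")) {
  stopifnot(nrow(pi_mat) == length(stratum))
  out <- list()
  for (tr in treatments) {
    pops <- treatment_pops(manifest, tr)
    for (lev in levels(stratum)) {
      idx <- which(stratum == lev)
      if (!length(idx)) {
        out[[length(out) + 1]] <- data.table(
          treatment = tr, stratum = lev, n_sites = 0L,
          mean_pi = NA_real_, se = NA_real_, empty = TRUE)
        next
      }
      rep_means <- colMeans(pi_mat[idx, pops, drop = FALSE], na.rm = TRUE)
      out[[length(out) + 1]] <- data.table(
        treatment = tr, stratum = lev, n_sites = length(idx),
        mean_pi = mean(rep_means),
        se = sd(rep_means) / sqrt(length(rep_means)), empty = FALSE)
    }
  }
  rbindlist(out)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values numeric response (e.g. one diversity value per replicate
#'   population).
#' @param groups factor of group labels (e.g. treatments).
#' @return list with `F`, `df` (numerator, denominator), `p.value`,
#'   `degenerate` (within-group mean square of zero) and `tukey`, a
#'   `data.table` of pairwise adjusted p-values.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  cnt <- table(groups)
  if (any(cnt < 2)) stop("every group needs at least 2 values")
  if (var(values) == 0) {            # a flat response carries no signal
    pairs <- utils::combn(levels(groups), 2)
    tukey <- data.table(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                        diff = 0, p_adj = 1)
    return(list(F = 0, df = c(nlevels(groups) - 1L,
                              length(values) - nlevels(groups)),
                p.value = 1, degenerate = FALSE, tukey = tukey))
  }
  degenerate <- all(tapply(values, groups, var) == 0)
  fit <- aov(values ~ groups)
  tab <- if (degenerate) suppressWarnings(anova(fit)) else anova(fit)
  fstat <- tab[1, "F value"]
  pval <- tab[1, "Pr(>F)"]
  if (degenerate) {                  # zero within-group mean square
    fstat <- Inf; pval <- 0
  }
  tk <- TukeyHSD(fit)$groups
  tukey <- data.table(pair = rownames(tk), diff = unname(tk[, "diff"]),
                      p_adj = unname(tk[, "p adj"]))
  list(F = fstat, df = c(tab[1, "Df"], tab[2, "Df"]), p.value = pval,
       degenerate = degenerate, tukey = tukey)
}

#' Within-treatment expected heterozygosities at each site
#'
#' `H_S` is the mean over populations of `2 p (1-p)`; `H_T` is
#' `2 p_bar (1 - p_bar)` with `p_bar` the unweighted mean frequency.
#'
#' @param p site x population matrix (or vector, one site) of allele
#'   frequencies.
#' @return list with vectors `H_S` and `H_T`.
#' @export
#' @examples
#' heterozygosities(matrix(c(0.2, 0.4), 1))  # H_S 0.40, H_T 0.42
heterozygosities <- function(p) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  hs <- rowMeans(2 * p * (1 - p))
  pbar <- rowMeans(p)
  list(H_S = hs, H_T = 2 * pbar * (1 - pbar))
}

#' Nei's F_ST over a set of sites
#'
#' The ratio-of-averages estimator `1 - mean(H_S) / mean(H_T)`, with means
#' over sites having `H_T > 0`. The average-of-ratios variant
#' (`mean(1 - H_S/H_T)`) is available for sensitivity checks.
#'
#' @param H_S,H_T per-site heterozygosities, as from [heterozygosities()].
#' @param variant `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return scalar F_ST estimate.
#' @export
fst_nei <- function(H_S, H_T, variant = c("ratio_of_means", "mean_of_ratios")) {
  variant <- match.arg(variant)
  keep <- !is.na(H_T) & H_T > 0
  if (!any(keep)) stop("F_ST undefined: no site with H_T > 0")
  if (variant == "ratio_of_means") {
    1 - mean(H_S[keep]) / mean(H_T[keep])
  } else {
    mean(1 - H_S[keep] / H_T[keep])
  }
}

#' Coverage-matched F_ST among replicates within treatments
#'
#' Unequal coverage biases F_ST comparisons between treatments, so reads
#' are subsampled to a common coverage profile first: at each site the
#' replicate populations of every treatment are ranked by allelic coverage;
#' the i-th ranked populations across treatments are matched and subsampled
#' (without replacement) to the minimum coverage `n_i` of that rank; F_ST
#' is then computed per treatment from the resampled frequencies. The whole
#' procedure is repeated `repeats` times and averaged.
#'
#' @param bi a [reduce_biallelic()] result restricted to the site set of
#'   interest.
#' @param treatments treatment labels (each needs the same replicate
#'   count).
#' @param repeats resampling repeats (default 10).
#' @param seed RNG seed.
#' @param variant F_ST variant, see [fst_nei()].
#' @return `data.table` with treatment, fst (mean over repeats), sd_fst,
#'   n_sites (sites used; sites with any matched coverage of zero are
#'   skipped), repeats.
#' @export
coverage_matched_fst <- function(bi, treatments = c("Salt", "Cad", "Temp", "Spatial"),
                                 repeats = 10, seed = 1L,
                                 variant = "ratio_of_means") {
  pops_by_tr <- lapply(treatments, treatment_pops, manifest = bi$manifest)
  k <- length(pops_by_tr[[1]])
  if (any(lengths(pops_by_tr) != k)) stop("treatments differ in replicate count")
  n <- nrow(bi$sites)
  # per-treatment coverage and minor counts ordered by within-site coverage rank
  cov_rank <- lapply(pops_by_tr, function(pops) {
    cv <- bi$allelic_cov[, pops, drop = FALSE]
    mc <- bi$minor_count[, pops, drop = FALSE]
    ord <- t(apply(cv, 1, order, decreasing = TRUE))
    idx <- cbind(rep(seq_len(n), k), as.vector(ord))
    list(cov = matrix(cv[idx], n, k), minor = matrix(mc[idx], n, k))
  })
  # matched coverage n_i = min over treatments of the i-th ranked coverage
  n_i <- Reduce(pmin, lapply(cov_rank, `[[`, "cov"))
  usable <- rowSums(n_i > 0) == k
  if (!any(usable)) stop("no usable sites (a matched coverage is zero everywhere)")
  set.seed(seed)
  res <- matrix(NA_real_, repeats, length(treatments),
                dimnames = list(NULL, treatments))
  for (r in seq_len(repeats)) {
    for (t in seq_along(treatments)) {
      cv <- cov_rank[[t]]$cov[usable, , drop = FALSE]
      mc <- cov_rank[[t]]$minor[usable, , drop = FALSE]
      ni <- n_i[usable, , drop = FALSE]
      sub <- matrix(rhyper(length(ni), as.vector(mc),
                           as.vector(cv - mc), as.vector(ni)),
                    nrow(ni), k)
      p <- sub / ni
      h <- heterozygosities(p)
      res[r, t] <- fst_nei(h$H_S, h$H_T, variant = variant)
    }
  }
  data.table(treatment = treatments,
             fst = colMeans(res),
             sd_fst = apply(res, 2, sd),
             n_sites = sum(usable), repeats = repeats)
}

# boundaries of the five approximately recombinationally independent regions
REGION_BOUNDS <- list(
  `2L` = c(1, 7307159), `2R` = c(10368692, Inf),
  `3L` = c(1, 7753553), `3R` = c(17055561, Inf))

#' Assign sites to recombinationally independent genomic regions
#'
#' Five regions: the distal halves of the four major autosome arms
#' (2L:1-7,307,159; 2R:10,368,692-end; 3L:1-7,753,553; 3R:17,055,561-end)
#' and the whole X chromosome; positions outside these bounds map to
#' `"none"`.
#'
#' @param chrom chromosome-arm names (2L, 2R, 3L, 3R or X).
#' @param pos 1-based positions.
#' @return character vector of region labels (`"2L-left"`, `"2R-right"`,
#'   `"3L-left"`, `"3R-right"`, `"X"`, `"none"`).
#' @export
assign_region <- function(chrom, pos) {
  known <- c(names(REGION_BOUNDS), "X")
  bad <- setdiff(unique(chrom), known)
  if (length(bad)) stop(sprintf("unknown chromosome arm(s): %s",
                                paste(bad, collapse = ", ")))
  out <- rep("none", length(chrom))
  out[chrom == "X"] <- "X"
  for (arm in names(REGION_BOUNDS)) {
    b <- REGION_BOUNDS[[arm]]
    side <- if (b[1] == 1) "left" else "right"
    hit <- chrom == arm & pos >= b[1] & pos <= b[2]
    out[hit] <- paste0(arm, "-", side)
  }
  out
}

#' Paired contrast of X versus autosomal F_ST across treatments
#'
#' Pairs, within each treatment, the X-chromosome F_ST with the mean
#' autosomal F_ST and applies a two-sided paired t-test.
#'
#' @param fst_table `data.table` with columns treatment, region, fst (as
#'   produced by running [coverage_matched_fst()] per region).
#' @param x_region label of the X region (default `"X"`).
#' @return list with `t`, `df`, `p.value`, `mean_diff` (X minus autosome)
#'   and `degenerate` (TRUE when the paired differences have zero
#'   variance).
#' @export
x_autosome_contrast <- function(fst_table, x_region = "X") {
  ft <- as.data.table(fst_table)
  wide <- ft[, .(x = mean(fst[region == x_region]),
                 auto = mean(fst[region != x_region])), by = treatment]
  if (nrow(wide) < 2) stop("need at least two treatments for a paired test")
  diffs <- wide$x - wide$auto
  if (sd(diffs) == 0) {
    if (all(diffs == 0))   # no contrast at all: t = 0 by convention
      return(list(t = 0, df = length(diffs) - 1L, p.value = 1,
                  mean_diff = 0, degenerate = FALSE))
    return(list(t = NA_real_, df = length(diffs) - 1L, p.value = NA_real_,
                mean_diff = mean(diffs), degenerate = TRUE))
  }
  tt <- t.test(wide$x, wide$auto, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_diff = mean(diffs), degenerate = FALSE)
}
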