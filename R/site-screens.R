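# Biallelic reduction of sync sites, per-site diversity, and the coverage /
# initial-diversity screens that define the alpha- and chi-site sets.

#' Screen configuration
#'
#' Thresholds for the two site screens and the ancestral-differentiation
#' strata. Defaults follow the two-ancestor experimental design: the
#' alpha screen (differentiation scan between the constant treatments)
#' requires 5-fold coverage in the 12 salt/cadmium populations and initial
#' diversity above 5%; the stricter chi screen (diversity and F_ST work
#' across all 22 populations) requires 15-fold ancestral and 10-fold
#' treatment coverage and drops sites whose local median coverage exceeds
#' twice the global median.
#'
#' @param alpha_min_coverage minimum read coverage for the alpha screen.
#' @param alpha_min_pi_ini minimum initial diversity `2*p*(1-p)` for the
#'   alpha screen (exclusive bound).
#' @param chi_min_ancestor_coverage minimum ancestral coverage, chi screen.
#' @param chi_min_treatment_coverage minimum treatment coverage, chi screen.
#' @param chi_median_factor multiple of the global median coverage above
#'   which a site is excluded.
#' @param chi_min_pi_ini minimum initial diversity for the chi screen.
#' @param high_pi_threshold "high initial diversity" cutoff used to control
#'   for starting heterozygosity.
#' @param d_low,d_high bounds of the weak/strong ancestral-differentiation
#'   strata (`d < d_low` weak, `d > d_high` strong).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(alpha_min_coverage = 5, alpha_min_pi_ini = 0.05,
                          chi_min_ancestor_coverage = 15,
                          chi_min_treatment_coverage = 10,
                          chi_median_factor = 2, chi_min_pi_ini = 0.05,
                          high_pi_threshold = 0.4, d_low = 0.3, d_high = 0.7) {
  cfg <- list(alpha_min_coverage = alpha_min_coverage,
              alpha_min_pi_ini = alpha_min_pi_ini,
              chi_min_ancestor_coverage = chi_min_ancestor_coverage,
              chi_min_treatment_coverage = chi_min_treatment_coverage,
              chi_median_factor = chi_median_factor,
              chi_min_pi_ini = chi_min_pi_ini,
              high_pi_threshold = high_pi_threshold,
              d_low = d_low, d_high = d_high)
  if (any(unlist(cfg) < 0)) stop("screen thresholds must be non-negative")
  if (d_low >= d_high) stop("d_low must be below d_high")
  class(cfg) <- "screen_config"
  cfg
}

#' Reduce sync sites to biallelic form
#'
#' The major and minor allele at a site are the two nucleotides (A/C/G/T;
#' never N or deletion) with the largest read counts summed over all
#' populations; ties are broken by the fixed base order A < C < G < T.
#' Frequencies downstream use the allelic coverage (major + minor counts
#' only), so reads of a third base or deletions do not enter the
#' denominator. Sites with fewer than two observed nucleotides are dropped.
#'
#' @param sync a [sync_table()].
#' @return An object of class `biallelic` with elements `sites` (a
#'   `data.table` of chrom, pos, ref, major, minor and `sync_row`, the row
#'   index into the source sync table), `minor_count` and
#'   `allelic_cov` (site x population matrices), `coverage` (total read
#'   coverage), and `manifest`.
#' @export
reduce_biallelic <- function(sync) {
  # base totals across populations, in tie-break order A < C < G < T
  tie_order <- c("A", "C", "G", "T")
  tot <- vapply(tie_order, function(b) {
    m <- sync$counts[, b, , drop = FALSE]
    dim(m) <- c(dim(sync$counts)[1], dim(sync$counts)[3])
    rowSums(m)
  }, numeric(nrow(sync$sites)))
  if (nrow(sync$sites) == 1) tot <- matrix(tot, nrow = 1, dimnames = list(NULL, tie_order))
  n_obs <- rowSums(tot > 0)
  keep <- which(n_obs >= 2)
  # rank bases per site: by decreasing count, ties by base order
  top2 <- t(vapply(keep, function(i) {
    ord <- order(-tot[i, ], seq_len(4))
    ord[1:2]
  }, integer(2)))
  major <- tie_order[top2[, 1]]
  minor <- tie_order[top2[, 2]]
  npop <- dim(sync$counts)[3]
  n <- length(keep)
  minor_count <- matrix(0L, n, npop, dimnames = list(NULL, sync$manifest$population))
  major_count <- matrix(0L, n, npop, dimnames = list(NULL, sync$manifest$population))
  for (b in tie_order) {
    sel_min <- minor == b
    sel_maj <- major == b
    if (any(sel_min)) {
      m <- sync$counts[keep[sel_min], b, , drop = FALSE]
      dim(m) <- c(sum(sel_min), npop)
      minor_count[sel_min, ] <- m
    }
    if (any(sel_maj)) {
      m <- sync$counts[keep[sel_maj], b, , drop = FALSE]
      dim(m) <- c(sum(sel_maj), npop)
      major_count[sel_maj, ] <- m
    }
  }
  cov_all <- sync_coverage(sync)[keep, , drop = FALSE]
  structure(
    list(sites = cbind(sync$sites[keep],
                       data.table(major = major, minor = minor,
                                  sync_row = keep)),
         minor_count = minor_count,
         allelic_cov = major_count + minor_count,
         coverage = cov_all,
         manifest = sync$manifest),
    class = "biallelic")
}

#' @export
print.biallelic <- function(x, ...) {
  cat(sprintf("biallelic sites: %d sites x %d populations\n",
              nrow(x$sites), ncol(x$minor_count)))
  invisible(x)
}

#' Minor-allele frequencies of biallelic sites
#'
#' @param bi a [reduce_biallelic()] result.
#' @return site x population matrix of minor-allele frequencies (NaN where
#'   the allelic coverage is zero).
#' @export
allele_freq <- function(bi) {
  bi$minor_count / bi$allelic_cov
}

#' Per-site nucleotide diversity from allele-category frequencies
#'
#' `pi = 1 - (A^2 + G^2 + C^2 + T^2 + D^2)`, where the five frequencies are
#' the raw count ratios of the four nucleotides and the deletion category.
#'
#' @param freqs numeric vector of 5 frequencies (A, G, C, T, deletion), or a
#'   matrix with 5 columns.
#' @param tol tolerance on the requirement that frequencies sum to at most 1.
#' @return per-site diversity in `[0, 0.8]`.
#' @export
#' @examples
#' pi_site(c(0.5, 0, 0.5, 0, 0))  # 0.5
pi_site <- function(freqs, tol = 1e-8) {
  m <- if (is.matrix(freqs)) freqs else matrix(freqs, nrow = 1)
  if (ncol(m) != 5) stop("expected 5 allele-category frequencies (A, G, C, T, deletion)")
  if (any(m < -tol | m > 1 + tol, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
  s <- rowSums(m)
  if (any(s > 1 + tol, na.rm = TRUE)) stop("allele frequencies sum to more than 1")
  out <- 1 - rowSums(m^2)
  if (!is.matrix(freqs)) out <- out[1]
  out
}

#' Per-site, per-population diversity of a sync table
#'
#' Applies the five-category site formula (see [pi_site()]) to every site
#' and population, with frequencies computed from read counts over the
#' non-N coverage (A, T, C, G and deletion reads).
#'
#' @param sync a [sync_table()].
#' @return site x population matrix of diversities; `NA` where a population
#'   has no non-N reads.
#' @export
pi_sites_by_pop <- function(sync) {
  npop <- dim(sync$counts)[3]
  n <- nrow(sync$sites)
  out <- matrix(NA_real_, n, npop, dimnames = list(NULL, sync$manifest$population))
  cats <- c("A", "T", "C", "G", "D")
  for (j in seq_len(npop)) {
    cm <- sync$counts[, cats, j, drop = FALSE]
    dim(cm) <- c(n, length(cats))
    denom <- rowSums(cm)
    f <- cm / denom
    out[, j] <- 1 - rowSums(f^2)
  }
  out
}

#' Ancestral allele-frequency statistics of biallelic sites
#'
#' Computes the minor-allele frequency in each ancestral population, the
#' initial frequency `p_ini`, the initial diversity
#' `pi_ini = 2 p_ini (1 - p_ini)` and the ancestral differentiation
#' `d = |p_AC - p_AS|`.
#'
#' @param bi a [reduce_biallelic()] result.
#' @param as_pop,ac_pop population ids of the two ancestors.
#' @param p_ini_mode `"count"` pools read counts across the two ancestors
#'   (used by the alpha screen); `"freq"` averages the two ancestral
#'   frequencies (used by the chi screen and all `p_ini`-based statistics).
#' @return `data.table` with columns `p_AS`, `p_AC`, `p_ini`, `pi_ini`, `d`.
#' @export
ancestral_stats <- function(bi, as_pop = "AS", ac_pop = "AC",
                            p_ini_mode = c("freq", "count")) {
  p_ini_mode <- match.arg(p_ini_mode)
  for (p in c(as_pop, ac_pop))
    if (!p %in% colnames(bi$minor_count))
      stop(sprintf("population '%s' not present", p))
  p_as <- bi$minor_count[, as_pop] / bi$allelic_cov[, as_pop]
  p_ac <- bi$minor_count[, ac_pop] / bi$allelic_cov[, ac_pop]
  p_ini <- if (p_ini_mode == "count") {
    (bi$minor_count[, as_pop] + bi$minor_count[, ac_pop]) /
      (bi$allelic_cov[, as_pop] + bi$allelic_cov[, ac_pop])
  } else {
    (p_as + p_ac) / 2
  }
  data.table(p_AS = p_as, p_AC = p_ac, p_ini = p_ini,
             pi_ini = 2 * p_ini * (1 - p_ini), d = abs(p_ac - p_as))
}

#' Alpha screen: sites eligible for the constant-treatment differentiation scan
#'
#' A site passes when every one of the 12 populations involved in the scan
#' (both ancestors plus the five replicates of each constant treatment) has
#' read coverage at or above `alpha_min_coverage`, and the initial diversity
#' exceeds `alpha_min_pi_ini`, with `p_ini` the minor-allele frequency
#' pooling read counts across the two ancestors.
#'
#' @param bi a [reduce_biallelic()] result.
#' @param cfg a [screen_config()].
#' @param treatments the two constant-treatment labels.
#' @param as_pop,ac_pop ancestral population ids.
#' @return logical vector, one flag per biallelic site.
#' @export
screen_alpha <- function(bi, cfg = screen_config(),
                         treatments = c("Salt", "Cad"),
                         as_pop = "AS", ac_pop = "AC") {
  pops <- c(as_pop, ac_pop,
            unlist(lapply(treatments, treatment_pops, manifest = bi$manifest)))
  missing <- setdiff(pops, colnames(bi$coverage))
  if (length(missing))
    stop(sprintf("missing populations: %s", paste(missing, collapse = ", ")))
  cov_ok <- rowSums(bi$coverage[, pops, drop = FALSE] >= cfg$alpha_min_coverage) ==
    length(pops)
  st <- ancestral_stats(bi, as_pop, ac_pop, p_ini_mode = "count")
  cov_ok & !is.na(st$pi_ini) & st$pi_ini > cfg$alpha_min_pi_ini
}

#' Chi screen: sites eligible for diversity and F_ST analyses
#'
#' Requires ancestral coverage of at least `chi_min_ancestor_coverage`,
#' coverage of at least `chi_min_treatment_coverage` in every treatment
#' population, initial diversity above `chi_min_pi_ini` (ancestral
#' frequencies averaged), and a local median coverage (across the two
#' ancestors and the treatment populations) no higher than
#' `chi_median_factor` times the global median of those local medians.
#'
#' @param bi a [reduce_biallelic()] result.
#' @param cfg a [screen_config()].
#' @param treatments treatment labels whose replicates are screened.
#' @param as_pop,ac_pop ancestral population ids.
#' @param global_median optionally, a precomputed global median coverage; by
#'   default the median of the per-site local medians of `bi` itself.
#' @return logical vector, one flag per biallelic site.
#' @export
screen_chi <- function(bi, cfg = screen_config(),
                       treatments = c("Salt", "Cad", "Temp", "Spatial"),
                       as_pop = "AS", ac_pop = "AC", global_median = NULL) {
  trt_pops <- unlist(lapply(treatments, treatment_pops, manifest = bi$manifest))
  pops <- c(as_pop, ac_pop, trt_pops)
  missing <- setdiff(pops, colnames(bi$coverage))
  if (length(missing))
    stop(sprintf("missing populations: %s", paste(missing, collapse = ", ")))
  covm <- bi$coverage[, pops, drop = FALSE]
  anc_ok <- bi$coverage[, as_pop] >= cfg$chi_min_ancestor_coverage &
    bi$coverage[, ac_pop] >= cfg$chi_min_ancestor_coverage
  trt_ok <- rowSums(bi$coverage[, trt_pops, drop = FALSE] >=
                      cfg$chi_min_treatment_coverage) == length(trt_pops)
  local_median <- apply(covm, 1, median)
  if (is.null(global_median)) global_median <- median(local_median)
  med_ok <- local_median <= cfg$chi_median_factor * global_median
  st <- ancestral_stats(bi, as_pop, ac_pop, p_ini_mode = "freq")
  anc_ok & trt_ok & med_ok & !is.na(st$pi_ini) & st$pi_ini > cfg$chi_min_pi_ini
}

#' Stratify sites by ancestral differentiation
#'
#' Partitions sites into weak (`d < d_low`), intermediate
#' (`d_low <= d <= d_high`) and strong (`d > d_high`) ancestral
#' differentiation; boundary values fall in the intermediate stratum. Also
#' assigns equal-width `d` bins for diversity-by-differentiation curves.
#'
#' @param d vector of ancestral differentiation values in `[0, 1]`.
#' @param cfg a [screen_config()] providing `d_low` and `d_high`.
#' @param bin_width width of the fine `d` bins (default 0.1).
#' @return `data.table` with columns `stratum` (factor low/mid/high) and
#'   `bin` (factor of `[lo, hi)` bins; the last bin is closed).
#' @export
stratify_d <- function(d, cfg = screen_config(), bin_width = 0.1) {
  stratum <- factor(ifelse(d < cfg$d_low, "low",
                    ifelse(d > cfg$d_high, "high", "mid")),
                    levels = c("low", "mid", "high"))
  edges <- seq(0, 1, by = bin_width)
  if (tail(edges, 1) < 1) edges <- c(edges, 1)
  bin <- cut(d, breaks = edges, include.lowest = TRUE, right = FALSE)
  # cut() with right = FALSE leaves d = 1 unassigned unless the top bin closes
  top <- !is.na(d) & d == 1
  bin[top] <- levels(bin)[length(levels(bin))]
  data.table(stratum = stratum, bin = bin)
}
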