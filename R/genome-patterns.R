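# Genome-scale diagnostics: annotation-class enrichment along the
# significance axis, clustering of significant sites, F_ST decay around
# focal sites, inversion-marker frequencies, conditional-neutrality
# classification, and standardized allele-frequency correlations.

#' Annotation-class enrichment by significance bin
#'
#' Splits the observed `-log10(q)` range into equal-width bins and, per
#' bin, computes the ratio of class-A to class-B site counts. Ratios are
#' standardized by the mean ratio over bins so that values above 1 mark
#' enrichment of class A among the more strongly differentiated sites.
#'
#' @param q q-values in (0, 1].
#' @param class factor or character with exactly two levels; the first
#'   level is the numerator class.
#' @param n_bins number of bins (default 11).
#' @return `data.table` with bin edges, class counts, ratio, standardized
#'   ratio and a `flagged` column for bins with an empty denominator class
#'   (excluded from the standardizing mean).
#' @export
enrichment_by_bin <- function(q, class, n_bins = 11) {
  if (!length(q)) stop("no sites supplied")
  class <- factor(class)
  if (nlevels(class) != 2) stop("class must have exactly two levels")
  nl <- -log10(q)
  rng <- range(nl)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(nl, breaks = edges, include.lowest = TRUE)
  tab <- table(bin, class)
  ratio <- tab[, 1] / tab[, 2]
  flagged <- tab[, 2] == 0
  ratio[flagged] <- NA_real_
  std <- ratio / mean(ratio[!flagged])
  data.table(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             n_a = as.integer(tab[, 1]), n_b = as.integer(tab[, 2]),
             ratio = as.numeric(ratio), std_ratio = as.numeric(std),
             flagged = as.logical(flagged))
}

# counts of positions inside [lo, hi] for each row, given sorted positions
count_between <- function(sorted_pos, lo, hi) {
  findInterval(hi, sorted_pos) - findInterval(lo - 1L, sorted_pos)
}

#' Clustering of significant sites relative to the tested background
#'
#' For windows of several lengths centred on randomly chosen significant
#' (beta) sites, measures the average fraction of beta-sites among
#' background (alpha) sites in the window, the focal site excluded. The
#' null expectation under no clustering comes from permuting the beta
#' labels uniformly over the alpha positions.
#'
#' @param sites `data.table` with columns chrom, pos and logical `beta`;
#'   rows are the alpha-sites (beta-sites must be a subset).
#' @param window_lengths window lengths in bp.
#' @param n_focal number of random focal beta-sites per window length.
#' @param n_perm number of label permutations for the null band.
#' @param seed RNG seed.
#' @return `data.table` per window length: observed mean fraction, number
#'   of usable focal sites (those with at least one non-focal alpha-site in
#'   the window), permutation mean and 2.5%/97.5% band.
#' @export
beta_clustering <- function(sites, window_lengths = c(50, 100, 500, 1000,
                                                      5000, 10000, 50000),
                            n_focal = 5000, n_perm = 100, seed = 1L) {
  st <- as.data.table(sites)[order(chrom, pos)]
  if (!any(st$beta)) stop("no beta-sites supplied")
  set.seed(seed)
  by_chrom <- split(st, st$chrom)

  mean_fraction <- function(dt_list, beta_flags_list, focal_rows) {
    # focal_rows: data.table(chrom, pos) of focal sites
    fracs <- numeric(0)
    for (ch in names(dt_list)) {
      fc <- focal_rows[chrom == ch]
      if (!nrow(fc)) next
      ap <- dt_list[[ch]]$pos
      bp <- dt_list[[ch]]$pos[beta_flags_list[[ch]]]
      lo <- fc$pos - fc$half
      hi <- fc$pos + fc$half
      n_alpha <- count_between(ap, lo, hi) - 1L   # exclude the focal site
      n_beta <- count_between(bp, lo, hi) - 1L
      ok <- n_alpha >= 1
      fracs <- c(fracs, n_beta[ok] / n_alpha[ok])
    }
    list(mean = if (length(fracs)) mean(fracs) else NA_real_,
         usable = length(fracs))
  }

  out <- list()
  beta_flags <- lapply(by_chrom, `[[`, "beta")
  for (L in window_lengths) {
    beta_rows <- st[beta == TRUE]
    pick <- beta_rows[sample(.N, min(n_focal, .N))]
    pick[, half := as.integer(L / 2)]
    obs <- mean_fraction(by_chrom, beta_flags, pick)
    perm_means <- numeric(n_perm)
    n_beta_tot <- sum(st$beta)
    for (k in seq_len(n_perm)) {
      lab <- logical(nrow(st))
      lab[sample(nrow(st), n_beta_tot)] <- TRUE
      stp <- copy(st)[, beta := lab]
      by_chrom_p <- split(stp, stp$chrom)
      flags_p <- lapply(by_chrom_p, `[[`, "beta")
      beta_rows_p <- stp[beta == TRUE]
      pick_p <- beta_rows_p[sample(.N, min(n_focal, .N))]
      pick_p[, half := as.integer(L / 2)]
      perm_means[k] <- mean_fraction(by_chrom_p, flags_p, pick_p)$mean
    }
    out[[length(out) + 1]] <- data.table(
      window = L, observed = obs$mean, usable_focal = obs$usable,
      perm_mean = mean(perm_means),
      perm_lo = quantile(perm_means, 0.025, names = FALSE),
      perm_hi = quantile(perm_means, 0.975, names = FALSE))
  }
  rbindlist(out)
}

#' Per-site F_ST between two population groups
#'
#' Site-wise `1 - H_S / H_T` over the pooled set of populations, with a
#' weight proportional to the total allelic variance `p_bar (1 - p_bar)`
#' across populations (sites with `H_T = 0` get `NA`).
#'
#' @param p site x population matrix of allele frequencies.
#' @return `data.table` with columns `fst` and `weight`.
#' @export
site_fst <- function(p) {
  h <- heterozygosities(p)
  pbar <- rowMeans(p)
  data.table(fst = ifelse(h$H_T > 0, 1 - h$H_S / h$H_T, NA_real_),
             weight = pbar * (1 - pbar))
}

#' F_ST decay with distance from focal sites
#'
#' Around each focal site, non-overlapping 50 bp windows out to
#' `max_dist` bp on both sides collect the variance-weighted mean F_ST of
#' the sites they contain; the focal site itself is excluded from the
#' first window. Windows with total weight below `min_weight` are dropped,
#' and the remaining window means are averaged across focal sites per
#' distance bin.
#'
#' @param focal `data.table` with chrom, pos of focal sites.
#' @param sites `data.table` with chrom, pos, fst, weight (see
#'   [site_fst()]).
#' @param window distance-bin width in bp (default 50).
#' @param max_dist maximum distance in bp (default 2000).
#' @param min_weight minimum summed weight for a window to be used.
#' @return `data.table` with dist_lo, dist_hi, mean_fst, n_windows.
#' @export
fst_decay <- function(focal, sites, window = 50, max_dist = 2000,
                      min_weight = 0) {
  fc <- as.data.table(focal)
  st <- as.data.table(sites)[!is.na(fst)]
  n_bins <- max_dist %/% window
  acc_sum <- numeric(n_bins)
  acc_n <- integer(n_bins)
  for (ch in unique(fc$chrom)) {
    sc <- st[chrom == ch]
    if (!nrow(sc)) next
    setorder(sc, pos)
    for (fp in fc[chrom == ch]$pos) {
      d <- abs(sc$pos - fp)
      sel <- d <= max_dist & !(d == 0)
      if (!any(sel)) next
      bin <- pmin(d[sel] %/% window + 1L, n_bins)
      w <- sc$weight[sel]
      f <- sc$fst[sel]
      for (b in unique(bin)) {
        i <- bin == b
        if (sum(w[i]) <= min_weight) next
        acc_sum[b] <- acc_sum[b] + sum(w[i] * f[i]) / sum(w[i])
        acc_n[b] <- acc_n[b] + 1L
      }
    }
  }
  data.table(dist_lo = (seq_len(n_bins) - 1L) * window,
             dist_hi = seq_len(n_bins) * window,
             mean_fst = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
             n_windows = acc_n)
}

#' Inversion frequency from marker SNPs
#'
#' Estimates an inversion's frequency in a population as the
#' coverage-weighted mean frequency of its inversion-specific marker
#' alleles: total marker-allele reads over total reads at the marker
#' positions.
#'
#' @param markers `data.table` with columns inversion, chrom, pos, allele
#'   (the inversion-specific base, one of A/T/C/G).
#' @param sync a [sync_table()] containing the marker positions.
#' @param pops population ids (default: all).
#' @return `data.table` with inversion, population, frequency (`NA` when no
#'   marker has coverage) and n_markers.
#' @export
inversion_frequency <- function(markers, sync, pops = NULL) {
  mk <- as.data.table(markers)
  if (is.null(pops)) pops <- sync$manifest$population
  key <- paste(sync$sites$chrom, sync$sites$pos)
  idx <- match(paste(mk$chrom, mk$pos), key)
  if (anyNA(idx)) stop("marker position missing from the sync table")
  out <- list()
  for (inv in unique(mk$inversion)) {
    rows <- which(mk$inversion == inv)
    for (pp in pops) {
      allele_reads <- vapply(rows, function(r)
        sync$counts[idx[r], mk$allele[r], pp], numeric(1))
      cats <- c("A", "T", "C", "G", "D")
      cov <- vapply(rows, function(r)
        sum(sync$counts[idx[r], cats, pp]), numeric(1))
      tot <- sum(cov)
      out[[length(out) + 1]] <- data.table(
        inversion = inv, population = pp,
        frequency = if (tot > 0) sum(allele_reads) / tot else NA_real_,
        n_markers = length(rows))
    }
  }
  rbindlist(out)
}

#' Ad hoc conditional-neutrality classification
#'
#' A differentiated site looks conditionally neutral in the cadmium
#' environment when the cadmium-ancestor frequency stayed close to the
#' grand ancestor (`|p_AC - p_GA| < threshold`) and the evolved cadmium
#' populations stayed close to the cross's initial frequency
#' (`|p_Cad - p_ini| < threshold`, `p_ini = (p_AC + p_AS)/2`); and
#' symmetrically for salt.
#'
#' @param p_GA,p_AC,p_AS grand-ancestor and ancestor frequencies (vectors).
#' @param p_Cad,p_Salt mean evolved frequency per treatment.
#' @param threshold differentiation threshold (default 0.1).
#' @return factor with levels `CN-in-cad`, `CN-in-salt`, `both`, `neither`.
#' @export
classify_conditional_neutrality <- function(p_GA, p_AC, p_AS, p_Cad, p_Salt,
                                            threshold = 0.1) {
  p_ini <- (p_AC + p_AS) / 2
  cn_cad <- abs(p_AC - p_GA) < threshold & abs(p_Cad - p_ini) < threshold
  cn_salt <- abs(p_AS - p_GA) < threshold & abs(p_Salt - p_ini) < threshold
  lab <- ifelse(cn_cad & cn_salt, "both",
         ifelse(cn_cad, "CN-in-cad",
         ifelse(cn_salt, "CN-in-salt", "neither")))
  factor(lab, levels = c("CN-in-cad", "CN-in-salt", "both", "neither"))
}

#' Standardized allele-frequency correlation between treatments
#'
#' Pearson correlation of treatment-mean allele frequencies over putatively
#' selected sites, minus the same correlation over non-differentiated
#' control sites. The subtraction removes the correlation induced purely by
#' variance in initial frequency.
#'
#' @param pA,pB mean allele frequency per site in the two treatments
#'   (aligned vectors; one orientation genome-wide).
#' @param selected,control index vectors (logical or integer) of the two
#'   site sets.
#' @return list with `diff_cor`, `cor_selected`, `cor_control` and
#'   `degenerate` (zero variance in any input vector).
#' @export
standardized_correlation <- function(pA, pB, selected, control) {
  sel_a <- pA[selected]; sel_b <- pB[selected]
  ctl_a <- pA[control]; ctl_b <- pB[control]
  if (length(sel_a) < 3 || length(ctl_a) < 3)
    stop("need at least 3 sites per set")
  if (sd(sel_a) == 0 || sd(sel_b) == 0 || sd(ctl_a) == 0 || sd(ctl_b) == 0)
    return(list(diff_cor = NA_real_, cor_selected = NA_real_,
                cor_control = NA_real_, degenerate = TRUE))
  cs <- cor(sel_a, sel_b)
  cc <- cor(ctl_a, ctl_b)
  list(diff_cor = cs - cc, cor_selected = cs, cor_control = cc,
       degenerate = FALSE)
}

#' Control sites matched on initial diversity
#'
#' Samples, from a candidate pool, a control set the same size as the
#' selected set whose initial-diversity distribution matches the selected
#' sites by decile-stratified sampling (`method = "pi_ini"`), or a simple
#' random sample (`method = "none"`).
#'
#' @param candidates integer indices of candidate control sites.
#' @param selected integer indices of selected sites.
#' @param pi_ini per-site initial diversity (full-length vector).
#' @param method `"pi_ini"` or `"none"`.
#' @param seed RNG seed.
#' @return integer vector of control-site indices.
#' @export
match_control_sites <- function(candidates, selected, pi_ini,
                                method = c("pi_ini", "none"), seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  candidates <- setdiff(candidates, selected)
  if (method == "none")
    return(sample(candidates, min(length(selected), length(candidates))))
  edges <- quantile(pi_ini[selected], probs = seq(0, 1, 0.1), names = FALSE)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  edges <- unique(edges)   # tied quantiles collapse to wider strata
  sel_bin <- cut(pi_ini[selected], edges)
  cand_bin <- cut(pi_ini[candidates], edges)
  out <- integer(0)
  for (b in levels(sel_bin)) {
    need <- sum(sel_bin == b)
    pool <- candidates[!is.na(cand_bin) & cand_bin == b]
    if (!need) next
    out <- c(out, sample(pool, min(need, length(pool))))
  }
  out
}

#' Fisher's exact screen for ancestral differentiation
#'
#' Two-sided Fisher's exact test on the minor/major x AS/AC table at every
#' site, with Benjamini-Yekutieli q-values across sites; sites with
#' `q < q_cutoff` are flagged as putatively differentially selected.
#'
#' @param bi a [reduce_biallelic()] result.
#' @param as_pop,ac_pop ancestral population ids.
#' @param q_cutoff q-value cutoff (default 0.001).
#' @return `data.table` with p, q and selected flag per site.
#' @export
fisher_screen <- function(bi, as_pop = "AS", ac_pop = "AC", q_cutoff = 0.001) {
  a <- bi$minor_count[, as_pop]
  b <- bi$allelic_cov[, as_pop] - a
  c_ <- bi$minor_count[, ac_pop]
  d <- bi$allelic_cov[, ac_pop] - c_
  p <- vapply(seq_along(a), function(i) {
    tab <- matrix(c(a[i], b[i], c_[i], d[i]), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
  }, numeric(1))
  p <- pmin(p, 1)
  q <- by_adjust(p)
  data.table(p = p, q = q, selected = q < q_cutoff)
}
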