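# Synthetic evolve-and-resequence datasets with known ground truth: a grand
# ancestor, two ancestors diverging in opposite environments, an F1 cross
# founding 4 treatments x 5 replicates, and pooled sequencing of everything.

#' Synthetic experiment configuration
#'
#' The generator emulates the two-ancestor experimental design: grand
#' ancestor standing variation, divergence of the two ancestors under
#' their environments, an F1 cross founding twenty populations of 448
#' diploids that evolve 42 generations under four regimes, then pooled
#' sequencing of 140 chromosomes per population at Poisson read coverage.
#'
#' Site classes: `eas` (environmentally antagonistic: alternative alleles
#' favoured in the two environments), `cn_a`/`cn_b` (conditionally
#' neutral: selected only in environment A = salt, or only in B =
#' cadmium), `uniform` (same direction in both environments) and
#' `neutral`.
#'
#' @param n_sites total number of SNP sites.
#' @param n_arms,arm_length synthetic chromosome arms and their length in
#'   bp.
#' @param mode `"linked"` simulates whole-arm haplotypes individual-based
#'   (at most 4096 sites per arm), producing physical linkage and admixture
#'   LD from the cross; `"independent"` simulates each site separately
#'   (binomial Wright-Fisher with deterministic selection response), which
#'   scales to very large site counts.
#' @param frac_eas,frac_cn_a,frac_cn_b,frac_uniform class fractions
#'   (remainder neutral).
#' @param s_eas,s_cn,s_uniform selection coefficients per class.
#' @param N diploid size of each treatment population.
#' @param generations experimental generations.
#' @param anc_N diploid size of the ancestral populations.
#' @param anc_generations divergence generations of each ancestor.
#' @param ga_freq function drawing grand-ancestor SNP frequencies.
#' @param recomb_rate recombination rate per bp (Morgans/bp), linked mode.
#' @param pool_size sequenced pool size in chromosomes.
#' @param mean_coverage mean of the Poisson read coverage.
#' @param spatial_mode how the spatially heterogeneous regime regulates the
#'   two habitats: `"viability"` (offspring develop and are selected inside
#'   one habitat, equal numbers of survivors pooled -- the experimental
#'   life cycle) or `"deme"` (adults breed within their habitat).
#' @param seed RNG seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_sites = 300, n_arms = 5, arm_length = 2e6,
                              mode = c("linked", "independent"),
                              frac_eas = 0.01, frac_cn_a = 0.01,
                              frac_cn_b = 0.01, frac_uniform = 0,
                              s_eas = 0.1, s_cn = 0.1, s_uniform = 0.05,
                              N = 448, generations = 42,
                              anc_N = 1000, anc_generations = 50,
                              ga_freq = function(n) runif(n, 0.05, 0.95),
                              recomb_rate = 2e-8, pool_size = 140,
                              mean_coverage = 17.5,
                              spatial_mode = c("viability", "deme"),
                              seed = 1L) {
  mode <- match.arg(mode)
  spatial_mode <- match.arg(spatial_mode)
  fr <- c(frac_eas, frac_cn_a, frac_cn_b, frac_uniform)
  if (any(fr < 0) || sum(fr) > 1)
    stop("class fractions must be non-negative and sum to at most 1")
  if (mode == "linked" && n_sites > 4096 * n_arms)
    stop("linked mode supports at most 4096 sites per arm")
  if (pool_size > 2 * N) stop("pool size cannot exceed 2N chromosomes")
  structure(list(n_sites = n_sites, n_arms = n_arms, arm_length = arm_length,
                 mode = mode, frac_eas = frac_eas, frac_cn_a = frac_cn_a,
                 frac_cn_b = frac_cn_b, frac_uniform = frac_uniform,
                 s_eas = s_eas, s_cn = s_cn, s_uniform = s_uniform,
                 N = N, generations = generations, anc_N = anc_N,
                 anc_generations = anc_generations, ga_freq = ga_freq,
                 recomb_rate = recomb_rate, pool_size = pool_size,
                 mean_coverage = mean_coverage, spatial_mode = spatial_mode,
                 seed = seed),
            class = "experiment_config")
}

#' Pooled sequencing of a population
#'
#' Two-stage sampling: `k ~ Hypergeometric(2N, 2N p, pool_size)`
#' chromosomes enter the pool, then `reads ~ Binomial(coverage, k /
#' pool_size)`. The read-frequency variance is approximately
#' `p (1-p) (1/pool_size + 1/coverage - 1/(pool_size * coverage))`.
#'
#' @param p true allele frequencies (multiples of `1/(2N)`).
#' @param pool_size chromosomes sampled into the pool.
#' @param coverage read coverage per site (recycled).
#' @param two_n population chromosome count.
#' @return integer vector of allele read counts.
#' @export
emulate_pool_sequencing <- function(p, pool_size, coverage, two_n) {
  if (pool_size > two_n) stop("pool size cannot exceed the population")
  stopifnot(all(p >= 0 & p <= 1))
  k <- rhyper(length(p), round(p * two_n), two_n - round(p * two_n), pool_size)
  rbinom(length(p), coverage, k / pool_size)
}

# per-class log fitness of allele 1 per copy in environments A and B
class_thetas <- function(class, cfg) {
  th <- function(s) log((1 + s) / (1 - s))
  a <- b <- numeric(length(class))
  a[class == "eas"] <- th(cfg$s_eas);      b[class == "eas"] <- -th(cfg$s_eas)
  a[class == "cn_a"] <- th(cfg$s_cn)       # selected in A, neutral in B
  b[class == "cn_b"] <- th(cfg$s_cn)       # selected in B, neutral in A
  a[class == "uniform"] <- th(cfg$s_uniform)
  b[class == "uniform"] <- th(cfg$s_uniform)
  list(a = a, b = b)
}

treatment_regimes <- function(cfg) {
  c(Salt = "constant_A", Cad = "constant_B", Temp = "temporal",
    Spatial = if (cfg$spatial_mode == "viability") "spatial_viability"
              else "spatial")
}

# deterministic per-site selection step for the independent-site mode;
# vectorised over sites, env is a scalar code
step_freq <- function(p, theta_a, theta_b, env) {
  one <- function(p, th) p * exp(th) / (p * exp(th) + (1 - p))
  if (env == 1) one(p, theta_a)
  else if (env == -1) one(p, theta_b)
  else if (env == 2 || env == 3) (one(p, theta_a) + one(p, theta_b)) / 2
  else p
}

#' Generate a synthetic evolve-and-resequence experiment
#'
#' Returns a sync table for the 23 populations (GA, AS, AC and 4
#' treatments x 5 replicates), the matching manifest, and a ground-truth
#' ledger with the class, selection coefficient and true final allele
#' frequency of every site.
#'
#' @param cfg an [experiment_config()].
#' @return list with elements `sync`, `manifest` and `truth` (a list of
#'   `sites`, a `data.table`, and `final_freq`, the site x population
#'   matrix of true frequencies).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  manifest <- default_manifest(pool_size = cfg$pool_size)
  pops <- manifest$population
  npop <- length(pops)

  # site layout
  arm_names <- paste0("arm", seq_len(cfg$n_arms))
  arm_of <- sort(rep_len(seq_len(cfg$n_arms), cfg$n_sites))
  pos <- integer(cfg$n_sites)
  for (a in seq_len(cfg$n_arms)) {
    idx <- which(arm_of == a)
    pos[idx] <- sort(sample.int(cfg$arm_length, length(idx)))
  }
  classes <- sample(c("eas", "cn_a", "cn_b", "uniform", "neutral"),
                    cfg$n_sites, replace = TRUE,
                    prob = c(cfg$frac_eas, cfg$frac_cn_a, cfg$frac_cn_b,
                             cfg$frac_uniform,
                             1 - cfg$frac_eas - cfg$frac_cn_a -
                               cfg$frac_cn_b - cfg$frac_uniform))
  s_of <- c(eas = cfg$s_eas, cn_a = cfg$s_cn, cn_b = cfg$s_cn,
            uniform = cfg$s_uniform, neutral = 0)[classes]
  th <- class_thetas(classes, cfg)
  p0 <- cfg$ga_freq(cfg$n_sites)
  final <- matrix(NA_real_, cfg$n_sites, npop, dimnames = list(NULL, pops))
  two_n_of <- setNames(rep(2 * cfg$N, npop), pops)
  two_n_of[c("GA", "AS", "AC")] <- 2 * cfg$anc_N

  if (cfg$mode == "linked") {
    for (a in seq_len(cfg$n_arms)) {
      idx <- which(arm_of == a)
      L <- length(idx)
      gaps <- diff(pos[idx]) * cfg$recomb_rate          # Morgans
      r_gaps <- 0.5 * (1 - exp(-2 * gaps))              # Haldane
      H_ga <- init_haplotypes(2 * cfg$anc_N, p0[idx], NULL)
      final[idx, "GA"] <- colMeans(H_ga)
      anc_pool <- list()
      for (anc in c("AS", "AC")) {
        sched <- env_schedule(if (anc == "AS") "constant_A" else "constant_B",
                              cfg$anc_generations)
        H0 <- H_ga[sample(nrow(H_ga), 2 * cfg$anc_N, replace = TRUE), ,
                   drop = FALSE]
        res <- evolve_pool(H0, th$a[idx], th$b[idx], sched, r_gaps)
        anc_pool[[anc]] <- res$haplotypes
        final[idx, anc] <- res$freq
      }
      regimes <- treatment_regimes(cfg)
      for (tr in names(regimes)) {
        sched <- env_schedule(regimes[[tr]], cfg$generations)
        for (repl in 1:5) {
          pop <- paste0(tr, repl)
          # F1 cross: every founder carries one AS and one AC haplotype
          h_as <- anc_pool$AS[sample(nrow(anc_pool$AS), cfg$N, TRUE), ,
                              drop = FALSE]
          h_ac <- anc_pool$AC[sample(nrow(anc_pool$AC), cfg$N, TRUE), ,
                              drop = FALSE]
          H0 <- matrix(0L, 2 * cfg$N, L)
          H0[seq(1, 2 * cfg$N, by = 2), ] <- h_as
          H0[seq(2, 2 * cfg$N, by = 2), ] <- h_ac
          final[idx, pop] <- evolve_pool(H0, th$a[idx], th$b[idx],
                                         sched, r_gaps)$freq
        }
      }
    }
  } else {
    evolve_site_freqs <- function(p, schedule, two_n) {
      for (env in schedule) {
        p <- step_freq(p, th$a, th$b, env)
        p <- rbinom(length(p), two_n, p) / two_n
      }
      p
    }
    final[, "GA"] <- round(p0 * 2 * cfg$anc_N) / (2 * cfg$anc_N)
    final[, "AS"] <- evolve_site_freqs(final[, "GA"],
                                       env_schedule("constant_A", cfg$anc_generations),
                                       2 * cfg$anc_N)
    final[, "AC"] <- evolve_site_freqs(final[, "GA"],
                                       env_schedule("constant_B", cfg$anc_generations),
                                       2 * cfg$anc_N)
    regimes <- treatment_regimes(cfg)
    for (tr in names(regimes)) {
      sched <- env_schedule(regimes[[tr]], cfg$generations)
      for (repl in 1:5) {
        pop <- paste0(tr, repl)
        k <- rbinom(cfg$n_sites, cfg$N, final[, "AS"]) +
          rbinom(cfg$n_sites, cfg$N, final[, "AC"])
        final[, pop] <- evolve_site_freqs(k / (2 * cfg$N), sched, 2 * cfg$N)
      }
    }
  }

  # pooled sequencing: Poisson coverage, hypergeometric pool, binomial reads
  ref_alt <- cbind(ref = sample(c("A", "T", "C", "G"), cfg$n_sites, TRUE),
                   alt = NA_character_)
  ref_alt[, "alt"] <- vapply(ref_alt[, "ref"], function(r)
    sample(setdiff(c("A", "T", "C", "G"), r), 1), character(1))
  counts <- array(0L, c(cfg$n_sites, 6, npop))
  for (j in seq_len(npop)) {
    pop <- pops[j]
    cov <- rpois(cfg$n_sites, cfg$mean_coverage)
    alt_reads <- emulate_pool_sequencing(final[, pop],
                                         min(cfg$pool_size, two_n_of[pop]),
                                         cov, two_n_of[pop])
    ref_reads <- cov - alt_reads
    for (b in c("A", "T", "C", "G")) {
      bi <- match(b, SYNC_BASES)
      sel <- ref_alt[, "ref"] == b
      if (any(sel)) counts[sel, bi, j] <- counts[sel, bi, j] + ref_reads[sel]
      sel <- ref_alt[, "alt"] == b
      if (any(sel)) counts[sel, bi, j] <- counts[sel, bi, j] + alt_reads[sel]
    }
  }
  sync <- sync_table(arm_names[arm_of], pos, ref_alt[, "ref"], counts, manifest)
  truth_sites <- data.table(chrom = arm_names[arm_of], pos = pos,
                            class = classes, s = unname(s_of),
                            ref = ref_alt[, "ref"], alt = ref_alt[, "alt"],
                            p0 = p0)
  list(sync = sync, manifest = manifest,
       truth = list(sites = truth_sites, final_freq = final))
}
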