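# Forward Wright-Fisher simulation of linked loci under environmentally
# antagonistic selection in constant, temporally fluctuating and spatially
# heterogeneous regimes, with a linked neutral site.

#' Simulation configuration
#'
#' Defaults describe a population of 448 diploids carrying 40
#' environmentally antagonistic loci (alternative alleles favoured in the
#' two environments, genic fitness `1 + s` / `1 - s` per allele copy,
#' multiplicative across loci) spaced 0.05 recombination units apart, with
#' initial allele frequencies drawn uniformly and initial linkage
#' disequilibrium induced by a random correlation structure. The simulated
#' span of 100 generations covers the divergence of the two ancestral
#' populations in their respective environments followed by the
#' experimental phase.
#'
#' @param regime `"constant_A"`, `"constant_B"`, `"temporal"`, `"spatial"`
#'   (soft selection with within-deme breeding), `"spatial_viability"`
#'   (soft selection on offspring viability, the experimental life cycle)
#'   or `"neutral"`.
#' @param s selection coefficient per locus and environment.
#' @param n_selected number of selected loci.
#' @param N diploid population size.
#' @param generations generations to simulate.
#' @param r_adj recombination fraction between adjacent selected loci.
#' @param r_neutral recombination fraction between the neutral site and the
#'   nearest selected locus; `NULL` simulates no neutral site.
#' @param n_reps replicate simulations.
#' @param init_freq function drawing initial allele frequencies (`n` ->
#'   vector), default uniform on (0, 1).
#' @param ld `"random"` (Gaussian-copula haplotypes with a random
#'   correlation matrix) or `"none"` (linkage equilibrium at start).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(regime = "constant_A", s = 0.05, n_selected = 40,
                       N = 448, generations = 100, r_adj = 0.05,
                       r_neutral = NULL, n_reps = 100,
                       init_freq = function(n) runif(n),
                       ld = c("random", "none"), seed = 1L) {
  regime <- match.arg(regime, c("constant_A", "constant_B", "temporal",
                                "spatial", "spatial_viability", "neutral"))
  ld <- match.arg(ld)
  stopifnot(s >= 0, N >= 2, generations >= 1, n_selected >= 0,
            is.null(r_neutral) || (r_neutral > 0 & r_neutral <= 0.5))
  structure(list(regime = regime, s = s, n_selected = n_selected, N = N,
                 generations = generations, r_adj = r_adj,
                 r_neutral = r_neutral, n_reps = n_reps,
                 init_freq = init_freq, ld = ld, seed = seed),
            class = "sim_config")
}

#' Environment schedule for a selection regime
#'
#' @param regime regime name, see [sim_config()].
#' @param generations number of generations.
#' @return integer vector of per-generation environment codes (1 = A,
#'   -1 = B, 0 = none, 2 = spatial deme breeding, 3 = spatial offspring
#'   viability).
#' @export
env_schedule <- function(regime, generations) {
  switch(regime,
    constant_A = rep(1L, generations),
    constant_B = rep(-1L, generations),
    temporal = rep(c(1L, -1L), length.out = generations),
    spatial = rep(2L, generations),
    spatial_viability = rep(3L, generations),
    neutral = rep(0L, generations),
    stop(sprintf("unknown regime '%s'", regime)))
}

#' Random correlation matrix
#'
#' `cov2cor(W W')` for a square standard-normal `W`: a full-rank random
#' correlation structure whose off-diagonal entries concentrate around zero
#' (spread about `1/sqrt(d)`) as the dimension grows.
#'
#' @param d dimension.
#' @return `d x d` correlation matrix.
#' @export
random_corr_matrix <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  W <- matrix(rnorm(d * d), d, d)
  stats::cov2cor(tcrossprod(W))
}

#' Pairwise linkage disequilibria from a correlation structure
#'
#' Converts correlations to two-locus disequilibria
#' `D_ij = rho_ij * sqrt(p_i q_i p_j q_j)` and clips every pair into its
#' feasibility box so that all four haplotype frequencies stay in
#' `[0, 1]`.
#'
#' @param p allele frequencies.
#' @param R correlation matrix (default: a fresh [random_corr_matrix()]).
#' @return list with matrix `D` and the count of `clipped` pairs.
#' @export
random_ld_structure <- function(p, R = random_corr_matrix(length(p))) {
  q <- 1 - p
  sdp <- sqrt(p * q)
  D <- R * tcrossprod(sdp)
  lower <- pmax(-tcrossprod(p), -tcrossprod(q))
  upper <- pmin(outer(p, q), outer(q, p))
  clipped <- sum(D < lower | D > upper) / 2
  D <- pmin(pmax(D, lower), upper)
  diag(D) <- p * q
  list(D = D, clipped = clipped)
}

#' Two-locus haplotype frequencies from allele frequencies and D
#'
#' @param p,q allele-1 frequencies at the two loci.
#' @param D linkage disequilibrium.
#' @return named vector `(AB, Ab, aB, ab)` summing to 1.
#' @export
#' @examples
#' haplotypes_from_freq_ld(0.5, 0.5, 0.25)  # (0.5, 0, 0, 0.5)
haplotypes_from_freq_ld <- function(p, q, D) {
  h <- c(AB = p * q + D, Ab = p * (1 - q) - D,
         aB = (1 - p) * q - D, ab = (1 - p) * (1 - q) + D)
  if (any(h < -1e-12) || any(h > 1 + 1e-12))
    stop("infeasible D for the given allele frequencies")
  pmin(pmax(h, 0), 1)
}

#' Initial haplotype pool with random LD
#'
#' Draws `two_n` haplotypes whose marginal allele frequencies are `p` and
#' whose pairwise associations follow the Gaussian copula with correlation
#' matrix `R` (thresholding latent normals at `qnorm(p)`).
#'
#' @param two_n number of haplotypes.
#' @param p allele frequencies.
#' @param R correlation matrix, or `NULL` for linkage equilibrium.
#' @return integer 0/1 matrix `two_n x length(p)`.
#' @export
init_haplotypes <- function(two_n, p, R = NULL) {
  L <- length(p)
  if (is.null(R)) {
    # linkage equilibrium with exact initial allele counts, so the founder
    # heterozygosity is 2p(1-p) without a sampling deficit
    H <- matrix(0L, two_n, L)
    for (l in seq_len(L)) {
      k <- round(p[l] * two_n)
      if (k > 0) H[sample.int(two_n, k), l] <- 1L
    }
  } else {
    Z <- matrix(rnorm(two_n * L), two_n, L) %*% chol(R)
    H <- sweep(Z, 2, qnorm(p), "<") * 1L
  }
  storage.mode(H) <- "integer"
  H
}

#' Evolve a haplotype pool under a regime
#'
#' Thin wrapper over the individual-based engine: genic multiplicative
#' selection with per-locus, per-environment log-fitness coefficients,
#' recombination without interference, and Wright-Fisher resampling of N
#' diploids per generation (the spatial code splits adults into two demes
#' of N/2 with opposite environments and equal contributions).
#'
#' @param H0 0/1 haplotype matrix (`2N x L`, rows 2i-1, 2i = individual i).
#' @param theta_a,theta_b per-locus log fitness per allele-1 copy in
#'   environments A and B.
#' @param schedule environment codes from [env_schedule()].
#' @param r_adj recombination fractions between adjacent loci (length
#'   `L - 1`).
#' @param track_freq also return the per-generation frequency trajectory.
#' @return list with `haplotypes`, `freq` and optionally `freq_track`.
#' @export
evolve_pool <- function(H0, theta_a, theta_b, schedule, r_adj,
                        track_freq = FALSE) {
  .wf_evolve_cpp(H0, as.numeric(theta_a), as.numeric(theta_b),
                 as.integer(schedule), as.numeric(r_adj), track_freq)
}

#' One deterministic (infinite-N, linkage-free) generation
#'
#' The single-locus allele-frequency recursion used as the drift-off
#' reference: with genic fitnesses `1 + s` and `1 - s`,
#' `p' = p (1 + s) / (1 + (2p - 1) s)` in environment A, the mirror image
#' in B, and the unweighted mean of the two deme recursions under the
#' spatial (soft selection) code.
#'
#' @param p allele frequency (vectorised).
#' @param s selection coefficient.
#' @param env `"A"`, `"B"`, `"none"` or `"spatial"`.
#' @return next-generation frequency.
#' @export
deterministic_step <- function(p, s, env = c("A", "B", "none", "spatial")) {
  env <- match.arg(env)
  stepA <- function(p) p * (1 + s) / (1 + (2 * p - 1) * s)
  stepB <- function(p) p * (1 - s) / (1 - (2 * p - 1) * s)
  switch(env,
    A = stepA(p), B = stepB(p), none = p,
    spatial = (stepA(p) + stepB(p)) / 2)
}

#' Harmonic-mean effective recombination distance
#'
#' Summarises the neutral site's distances to the selected loci (additive
#' map distances `r_neutral, r_neutral + r_adj, ...`) by their harmonic
#' mean, the axis used to report linked neutral diversity.
#'
#' @param r_neutral distance to the nearest selected locus.
#' @param r_adj adjacent-locus spacing.
#' @param n_selected number of selected loci.
#' @return harmonic mean distance.
#' @export
effective_distance <- function(r_neutral, r_adj, n_selected) {
  d <- r_neutral + (seq_len(n_selected) - 1) * r_adj
  n_selected / sum(1 / d)
}

#' Run replicate forward simulations
#'
#' Simulates `n_reps` independent populations under the configured regime
#' and returns endpoint diversity summaries: the mean (over loci and
#' replicates) final diversity `2 p (1 - p)` at the selected loci and, if a
#' neutral site is configured, at the neutral site.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result` with elements `cfg`,
#'   `pi_selected` (mean), `pi_selected_se` (SE over replicates),
#'   `pi_neutral`, `pi_neutral_se`, `log10_r_eff`, and `finals`, the
#'   replicate x locus matrix of final allele frequencies (neutral site
#'   first when present).
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  has_neutral <- !is.null(cfg$r_neutral)
  L <- cfg$n_selected + has_neutral
  if (L > 512) stop("the random-LD initialiser supports at most 512 loci")
  sel_idx <- seq_len(cfg$n_selected) + has_neutral
  theta <- log((1 + cfg$s) / (1 - cfg$s))
  theta_a <- theta_b <- numeric(L)
  theta_a[sel_idx] <- theta
  theta_b[sel_idx] <- -theta
  r_gaps <- if (L > 1) {
    c(if (has_neutral) cfg$r_neutral,
      rep(cfg$r_adj, max(cfg$n_selected - 1, 0)))
  } else numeric(0)
  schedule <- env_schedule(cfg$regime, cfg$generations)
  finals <- matrix(NA_real_, cfg$n_reps, L)
  for (rep in seq_len(cfg$n_reps)) {
    p0 <- cfg$init_freq(L)
    R <- if (cfg$ld == "random") random_corr_matrix(L) else NULL
    H0 <- init_haplotypes(2 * cfg$N, p0, R)
    finals[rep, ] <- evolve_pool(H0, theta_a, theta_b, schedule, r_gaps)$freq
  }
  pi_mat <- 2 * finals * (1 - finals)
  out <- list(cfg = cfg, finals = finals)
  if (cfg$n_selected > 0) {
    rep_mean <- rowMeans(pi_mat[, sel_idx, drop = FALSE])
    out$pi_selected <- mean(rep_mean)
    out$pi_selected_se <- sd(rep_mean) / sqrt(cfg$n_reps)
  }
  if (has_neutral) {
    out$pi_neutral <- mean(pi_mat[, 1])
    out$pi_neutral_se <- sd(pi_mat[, 1]) / sqrt(cfg$n_reps)
    out$log10_r_eff <- log10(effective_distance(cfg$r_neutral, cfg$r_adj,
                                                max(cfg$n_selected, 1)))
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: regime %s, s = %g, %d reps, %d generations\n",
              x$cfg$regime, x$cfg$s, x$cfg$n_reps, x$cfg$generations))
  if (!is.null(x$pi_selected))
    cat(sprintf("  mean selected-locus pi: %.4f (se %.4f)\n",
                x$pi_selected, x$pi_selected_se))
  if (!is.null(x$pi_neutral))
    cat(sprintf("  neutral-site pi: %.4f (se %.4f) at log10(r) = %.2f\n",
                x$pi_neutral, x$pi_neutral_se, x$log10_r_eff))
  invisible(x)
}
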