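---
title: "Methods: Pool-seq analysis of alternative selection regimes"
author: "evoregime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pool-seq analysis of alternative selection regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoregime)
```

## The experimental design this package models

evoregime analyses pooled resequencing (Pool-seq) data from
evolve-and-resequence experiments in which replicate populations evolve
under alternative selection regimes. The reference design has two
ancestral populations adapted to opposite stressful environments ("salt",
environment A, and "cadmium", environment B), crossed to found twenty
populations of N = 448 diploids that evolve for 42 generations under four
regimes with five replicates each:

* **Salt** / **Cad** — constant exposure to one environment;
* **Temp** — the environment alternates every generation;
* **Spatial** — each generation the population is split between the two
  environments and equal numbers of survivors from each are pooled (soft
  selection).

At the end, 70 females (140 chromosomes) are pooled and sequenced per
population, so allele frequencies are estimated from read counts. All
input flows through popoolation2-style `sync` tables (per-site
`A:T:C:G:N:del` read counts per population) and a population manifest
binding columns to treatments, replicates and pool sizes.

## Site reduction and screens

SNPs are treated as biallelic. The major and minor allele at a site are
the two nucleotides with the largest read counts summed over every
population; ties break by the fixed base order A < C < G < T, and
frequencies use the allelic coverage (major + minor reads) as the
denominator, so third alleles, N calls and deletions never dilute a
frequency. Deletions do, however, count as an allele class for the
per-site diversity formula (below), because a segregating deletion is
real variation.

Two screens define the analysis site sets:

* **alpha-sites** (differentiation scan): read coverage of at least 5 in
  both ancestors and all ten constant-treatment populations, and initial
  diversity `pi_ini = 2 p_ini (1 - p_ini) > 0.05`, where `p_ini` is the
  minor-allele frequency *pooling read counts* across the two ancestors.
* **chi-sites** (diversity and F_ST): coverage of at least 15 in both
  ancestors and at least 10 in all twenty treatment populations,
  `pi_ini > 0.05` with `p_ini` the *average* of the two ancestral
  frequencies, and a local median coverage (across those 22 populations)
  no higher than twice the global median of local medians — a guard
  against collapsed repeats.

The two `p_ini` conventions differ deliberately: count-pooling weights
the better-covered ancestor more and is the natural choice when the
screen itself conditions on coverage; frequency-averaging treats the
ancestors symmetrically and matches how `p_ini` enters every downstream
statistic. Both are available in `ancestral_stats()`.

Ancestral differentiation `d = |p_AC - p_AS|` stratifies sites into weak
(`d < 0.3`), intermediate and strong (`d > 0.7`) classes; the boundary
values land in the intermediate stratum because the defining
inequalities are strict on both sides. High-`d` sites are candidates for
differential ecological selection; low-`d` sites serve as the neutral
reference, and the `pi_ini > 0.4` restriction puts both classes on equal
initial-diversity footing.

## The differentiation scan

Differentiation between the two constant environments is tested per site
with the Cochran–Mantel–Haenszel statistic over paired 2×2 tables
(minor/major read counts × population pair). The ancestors form one
natural stratum (AS with AC); the five replicates of each treatment have
no natural pairing, so the scan is repeated under five rotational
pairings (`Salt_i` with `Cad_i`, then `Cad_{i+1}`, ...). Per pairing the
statistic is

    X^2 = ( sum_k (a_k - E[a_k]) )^2 / sum_k Var(a_k),  df = 1,

without continuity correction; strata with a zero margin are
uninformative and are dropped. The five p-values are combined by their
geometric mean (floored at 1e-320 before the log to dodge underflow) and
converted to q-values with the Benjamini–Yekutieli adjustment, which
controls FDR under arbitrary dependence — appropriate because linked
sites are strongly correlated. A site is a **beta-site** when its
combined q-value passes the cutoff (default 1e-5, i.e. FDR 0.001%). A
second calling rule — every one of the five per-pairing q-values must
pass — is used for pairwise treatment contrasts and available as
`call_beta(rule = "per_pairing")`; the two aggregation orders are
genuinely different procedures and both are exposed rather than silently
merged.

Raw read counts act as the CMH cell counts. Reads are pseudo-replicates
of the 140 pooled chromosomes, so nominal p-values are anticonservative
when coverage exceeds the pool size; at the coverages this design
produces (mean ~17.5×) the approximation is standard practice, and the
**pseudo-treatment null** quantifies the realised false-positive yield
directly: half of each environment's replicates are relabelled "A", the
rest "B", the identical scan is run, and the beta count under this null
is reported for (default) 15 random splits.

Window summaries average `-log10(q)` and the between-group allele
frequency difference in non-overlapping 5 kb windows.

## Diversity

Per-site diversity uses the five-category formula
`pi = 1 - (A^2 + G^2 + C^2 + T^2 + D^2)` on raw count ratios — the
uncorrected site statistic used for stratified treatment comparisons,
where only *differences* between treatments matter and every population
enters with the same coverage screen.

Windowed diversity (`window_pi()`) follows the Pool-seq convention:
non-overlapping 10 kb windows; a position qualifies at coverage 4–400;
a site contributes its diversity only when the minor category has at
least 2 reads (below that it is indistinguishable from sequencing error
and counts as invariant); and the per-site estimate carries the nested
two-stage correction

    pi_hat = (1 - sum f^2) * c/(c-1) * n/(n-1)

for `c` reads drawn from a pool of `n` chromosomes, unbiasing the
sample heterozygosity for both sampling layers. A window is valid when
at least 60% of its positions qualify. The raw (uncorrected) mode is one
flag away, since the site-level analyses use it.

One-way ANOVA with Tukey HSD (`anova_tukey()`) compares per-replicate
genome-wide means across the four treatments (df 3 and 16 in the
reference design).

## F_ST among replicates

Within-treatment divergence uses Nei's fixation index from expected
heterozygosities: `H_S` is the mean of `2 p_i (1 - p_i)` over the five
replicates, `H_T` is `2 p_bar (1 - p_bar)` at the unweighted mean
frequency, and

    E[F_ST] = 1 - mean(H_S) / mean(H_T)

with means over sites having `H_T > 0` (the ratio-of-averages form; the
average-of-ratios variant is available for sensitivity analysis, but the
ratio of averages is the standard small-sample-stable choice and the one
implied by averaging "over all sites"). Because unequal coverage alone
moves this estimator, treatments are compared only after
**coverage-matched resampling** (`coverage_matched_fst()`): at each site
the five replicates of every treatment are ranked by coverage, the i-th
ranked populations are matched across treatments and subsampled without
replacement to the minimum coverage of that rank, and the estimator is
recomputed; the whole procedure repeats 10 times and averages. Sites
where any matched coverage is zero are skipped and counted.

Regional contrasts use five approximately recombinationally independent
regions (the distal halves of 2L, 2R, 3L, 3R, plus the X chromosome;
`assign_region()` carries the coordinates), and `x_autosome_contrast()`
pairs X with the autosomal mean within each treatment for a paired
t-test (df 3).

## Genome-scale diagnostics

* `enrichment_by_bin()` splits the observed `-log10(q)` range into 11
  equal-width bins and standardises the per-bin class ratio (e.g.
  genic/intergenic) by its mean over bins, so enrichment along the
  significance axis reads directly as departure from 1. Bins with an
  empty denominator are flagged and excluded from the standardising
  mean. The bin placement is equal-width over the observed range; edges
  are returned so any alternative binning can be audited.
* `beta_clustering()` measures the fraction of beta-sites among
  alpha-sites in windows centred on random beta-sites (focal site
  excluded) against a permutation null that scatters the beta labels
  uniformly over alpha positions.
* `fst_decay()` tracks variance-weighted mean site F_ST in 50 bp bins
  out to 2 kb from focal sites, the focal site excluded from its own
  first bin; the weight is the total allelic variance
  `p_bar (1 - p_bar)` across populations, the simplest variance proxy
  consistent with down-weighting nearly-fixed sites.
* `inversion_frequency()` estimates an inversion's frequency as total
  marker-allele reads over total reads at its marker SNPs — the
  coverage-weighted mean of marker frequencies, invariant to splitting
  counts across markers.
* `classify_conditional_neutrality()` applies the two printed closeness
  rules (ancestor vs grand ancestor, evolved treatment vs initial
  frequency, both within 0.1) symmetrically for each environment.
* `standardized_correlation()` reports the Pearson correlation of
  treatment-mean frequencies over putatively selected sites minus the
  same over control sites, removing the correlation that initial
  frequency variance alone induces. Selected sites come from a
  two-sided Fisher exact screen on the two ancestors (q < 0.001 after
  BY); control sites are sampled to match the selected sites'
  initial-diversity distribution by decile stratification
  (`match_control_sites()`), because a control set with a different
  `pi_ini` profile would carry a different baseline correlation.
  Allele orientation is fixed once genome-wide (the minor allele of the
  pooled ancestors) so correlations are sign-coherent.

## The forward simulator

`run_simulation()` drives an individual-based Wright–Fisher engine:
diploid individuals carry bitset haplotypes, selection is genic and
multiplicative — in a given environment, fitness multiplies by `(1+s)`
per copy of the locally favoured allele and `(1-s)` per copy of the
disfavoured one — recombination is a Poisson crossover process on the
Haldane map implied by adjacent-locus distances (no interference), and
each generation N offspring draw two fitness-weighted parents. The
single-locus deterministic limit is the textbook recursion
`p' = p(1+s)/(1 + (2p-1)s)` (`deterministic_step()` exposes it).

Regimes: constant (one environment throughout), temporal (strict
alternation), neutral, and two spatial soft-selection variants. In
`"spatial"`, adults are split at random into two demes of N/2 that breed
within-deme under opposite environments and contribute N/2 offspring
each. In `"spatial_viability"`, mating is panmictic and *offspring* are
assigned to the two environments, survive in proportion to their local
viability, and exactly N/2 survivors per environment form the next
generation — this is the actual life cycle of the spatial treatment
(mixed adults lay eggs; larvae develop and are selected inside one
habitat; equal numbers of emerging adults are pooled). The deme-breeding
variant produces distinctly stronger balancing at the selected loci; the
offspring-viability variant produces less among-replicate divergence.
The regime-simulator default is `"spatial"`, the synthetic-experiment
default `"spatial_viability"` (see below).

**Default architecture.** 40 antagonistically selected loci, equally
spaced at recombination fraction 0.05, N = 448 diploids, initial allele
frequencies drawn iid uniform on (0, 1), and initial linkage
disequilibrium induced by thresholding latent Gaussians with a random
full-rank correlation matrix (`random_corr_matrix()`), every pairwise D
clipped into its feasibility box. The default simulated span is 100
generations: the two ancestral populations adapted to their environments
for roughly 30–60 generations before the cross, and the experimental
phase adds 42 more, so a single run under a constant regime stands in
for the full selective history of a constant-environment lineage. With
these defaults the endpoint mean diversity `2p(1-p)` at the selected
loci behaves as classic theory predicts: constant selection purges it
(0.078 at s = 0.02, below 0.002 at s = 0.05), temporal alternation is
nearly neutral (~0.30), and spatial soft selection holds loci
polymorphic (0.30 at s = 0.02 rising to ~0.46 at s = 0.07), while the
no-selection reference decays only by drift (~0.30).

**Numerical choices.** Initial frequencies are realised as exact allele
counts when LD is off, so founder heterozygosity is `2p(1-p)` without a
sampling deficit and the neutral decay matches
`0.5 (1 - 1/(2N))^t` exactly in expectation. Crossover sampling uses
cumulative Haldane distances, so the marginal switch probability across
each gap equals the requested recombination fraction. The engine's inner
sampling runs on a xoshiro256++ generator seeded from R's RNG, so
`set.seed()` fully determines a run while keeping per-gamete sampling
cheap. Fitness evaluation uses a popcount-and-lookup fast path whenever
all selected loci share one coefficient per environment.

## The synthetic experiment generator

`generate_experiment()` produces a full 23-population dataset with known
ground truth: grand-ancestor frequencies (uniform on 0.05–0.95 by
default), ancestor divergence under the two constant environments
(N = 1000, 50 generations each by default; the real ancestors' spans
differed somewhat, and the config exposes them separately), F1 founding
of twenty populations (each founder carries one haplotype sampled from
each ancestor, which creates admixture LD between ancestrally
differentiated sites), 42 generations under the four regimes, then
pooled sequencing: 140 chromosomes drawn hypergeometrically from 2N,
read counts binomial at Poisson coverage (mean 17.5 by default).

Site classes: environmentally antagonistic (`eas`), conditionally
neutral in either direction (`cn_a`, `cn_b`), uniformly selected and
neutral, with configurable fractions and selection coefficients.

Two simulation modes trade realism for scale. `"linked"` simulates every
arm as one haplotype block through the engine, so physical linkage,
hitchhiking and founding admixture LD are real; it supports up to 4096
sites per arm. `"independent"` evolves each site as a separate binomial
Wright–Fisher process with a deterministic selection response — it
scales to hundreds of thousands of sites and is exact for null
calibration, but carries no linkage at all, hence no linked-selection
effects on neutral sites.

What the generator does **not** emulate: sequencing error beyond
binomial read sampling (base-quality filtering is upstream of the sync
abstraction), inversions, unequal recombination along arms,
mutation (the 42-generation experiment runs on standing variation), and
X-specific inheritance (all arms are autosomal in the generator;
region-level X contrasts therefore exercise the interface, not X
biology). Tests passing on these data show the pipeline's statistics
behave correctly under the design's sampling structure; they cannot
certify behaviour under artefacts the generator omits.

## Study scales used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
keeping every qualitative contrast identifiable: the simulator's
endpoint table uses 2,000 replicate runs per regime-by-s combination
(Monte-Carlo SE about 0.001–0.003 on each endpoint); the neutral-drift
check uses 5,000 replicates; scan calibration uses an all-neutral
100,000-site independent-mode experiment at coverage 20; and the
planted-signal runs use 20,000 linked sites on five 25 Mb arms with 1%
antagonistic sites at s = 0.1 — the 25 Mb map length matters, because on
a very short genome every "neutral" site is tightly linked to a selected
target and the regimes' genome-wide diversity contrasts are suppressed
by construction. On those runs the pipeline reproduces the expected
orderings: at strongly differentiated sites mean diversity ranks
Spatial > Temp > constants; at weakly differentiated sites Temp is
lowest and Spatial highest; and within-treatment F_ST is highest for
Temp and lowest for Spatial.

## Known limitations

* CMH on raw read counts ignores the pool-sampling layer; the
  pseudo-treatment null is the empirical guard. A count down-scaling
  option would be a natural extension.
* The coverage-matched F_ST procedure matches coverage *profiles* by
  rank, not per-population identities; it assumes five replicates per
  treatment throughout.
* The Fisher screen computes one exact test per site in a loop; at
  millions of sites a vectorised approximation would be preferable.
* `run_simulation()` caps the random-LD initialiser at 512 loci (the
  copula needs a dense Cholesky); the engine itself has no such limit.
* The generator's independent mode deliberately has no linkage; use
  linked mode for any question about hitchhiking or effective
  population size.
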