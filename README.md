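# evoregime

Analysis of pooled resequencing (Pool-seq) data from evolve-and-resequence
experiments that contrast **constant**, **temporally fluctuating** and
**spatially heterogeneous** selection regimes, together with a forward
Wright–Fisher simulator of environmentally antagonistic selection.

The package is built around a two-ancestor experimental design: two
populations adapted to opposite environments (salt- and cadmium-enriched
media) are crossed, the cross founds replicate populations (5 per
treatment, N = 448) that evolve 42 generations under one of four regimes
(constant salt, constant cadmium, temporal alternation, spatial soft
selection), and every population is pool-sequenced (140 chromosomes,
read counts in popoolation2 `sync` format). The questions it answers are
how the regimes differentiate allele frequencies and how they reshape
within- and among-population diversity at ecologically selected versus
neutral sites.

## What's inside

* **sync I/O** — `read_sync()` / `write_sync()` for per-site
  `A:T:C:G:N:del` read-count tables, plus a population manifest.
* **Site screens** — biallelic reduction, per-site diversity
  `pi = 1 - sum(f^2)` over the five allele categories, the coverage /
  initial-diversity screens defining the scan (`screen_alpha()`) and
  diversity (`screen_chi()`) site sets, and stratification by ancestral
  differentiation `d = |p_AC - p_AS|`.
* **Differentiation scan** — the five-pairing Cochran–Mantel–Haenszel
  test with Benjamini–Yekutieli q-values,
  `q(i) = min_{j>=i} min(1, p(j) m c(m) / j)`, beta-site calling at
  FDR 1e-5, a pseudo-treatment permutation null, and 5 kb window
  summaries.
* **Diversity and F_ST** — pool-size-corrected windowed Tajima's pi,
  diversity by `d` stratum with replicate standard errors, Nei's
  `F_ST = 1 - mean(H_S)/mean(H_T)` with coverage-matched resampling
  across treatments, genomic regions and the X-vs-autosome paired
  contrast, one-way ANOVA + Tukey HSD.
* **Genome diagnostics** — enrichment by significance bin, clustering of
  significant sites vs a permutation null, F_ST decay around focal
  sites, inversion-marker frequencies, conditional-neutrality
  classification, standardized allele-frequency correlations between
  treatments.
* **Forward simulator** — individual-based Wright–Fisher engine (Rcpp,
  bitset haplotypes) with genic multiplicative antagonistic selection,
  Poisson/Haldane recombination and all four regimes (two spatial
  variants).
* **Synthetic experiments** — `generate_experiment()` builds complete
  23-population datasets (ancestors, cross, evolution, pooled
  sequencing) with a ground-truth ledger, either with real linkage
  (whole-arm haplotype simulation) or site-independent at large scale.
* **Pipeline** — `run_pipeline()` chains the stages with deterministic
  per-stage seeds and writes TSV/YAML outputs.

## Worked example

Generate a small linked experiment with 5% environmentally antagonistic
sites, screen it, and scan for differentiation between the constant
treatments:

```r
library(evoregime)

cfg <- experiment_config(n_sites = 300, mode = "linked",
                         frac_eas = 0.05, seed = 7)
gen <- generate_experiment(cfg)
gen$sync
#> sync table: 300 sites x 23 populations

bi    <- reduce_biallelic(gen$sync)
alpha <- screen_alpha(bi)
res   <- scan_pair(subset_biallelic(bi, alpha), "Salt", "Cad",
                   ancestor1 = "AS", ancestor2 = "AC")
beta  <- call_beta(res)            # combined rule, FDR 1e-5
c(alpha = sum(alpha), beta = sum(beta))
#> alpha  beta
#>   272    97
truth <- gen$truth$sites[bi$sites$sync_row][which(alpha)]
sum(truth$class[beta] == "eas")
#> [1] 15
```

All 15 planted antagonistic sites are recovered; the remaining beta
calls sit on the same arms and are differentiated through linkage and
founding admixture — the expected behaviour for this design, where
hitchhiking makes many more sites significant than there are true
targets.

The simulator reproduces the classic diversity contrast between
regimes (40 antagonistic loci, s = 0.05, N = 448):

```r
run_simulation(sim_config(regime = "spatial", s = 0.05, n_reps = 200, seed = 1))
#> sim_result: regime spatial, s = 0.05, 200 reps, 100 generations
#>   mean selected-locus pi: 0.4441 (se 0.0017)
```

Constant selection at the same s collapses selected-locus diversity to
below 0.002, temporal alternation leaves it near the neutral value
(~0.30), and spatial soft selection holds loci polymorphic near 0.45.

## Documentation

The methods vignette (`vignettes/evoregime-methods.Rmd`) describes the
statistical procedures, the simulator's model and defaults, the
synthetic-data generator's scope and limitations, and the numerical
choices in detail.
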