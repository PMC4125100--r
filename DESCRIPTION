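Package: evoregime
Title: Pool-Seq Analysis of Experimental Evolution under Alternative Selection Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled resequencing (Pool-seq) data from
    evolve-and-resequence experiments contrasting constant, temporally
    fluctuating and spatially heterogeneous selection regimes. Reads
    popoolation2-style sync allele-count tables, screens sites by coverage
    and initial diversity, runs replicated Cochran-Mantel-Haenszel
    differentiation scans with Benjamini-Yekutieli control, computes
    windowed nucleotide diversity and Nei F_ST with coverage-matched
    resampling, and provides genome-scale diagnostics (clustering of
    significant sites, F_ST decay, enrichment by significance bin,
    inversion-marker frequencies, standardized allele-frequency
    correlations). Includes a forward Wright-Fisher simulator of
    environmentally antagonistic selection with linked loci and a
    synthetic-experiment generator emulating a two-ancestor cross design
    with pooled sequencing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
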