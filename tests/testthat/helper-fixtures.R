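# small in-code fixtures shared across test files

# sync table from a list of per-population count matrices
# counts_list: list over populations of (n_sites x 6) matrices (A,T,C,G,N,D)
make_sync <- function(counts_list, chrom = NULL, pos = NULL, ref = "A",
                      treatment = NULL, pool_size = 140) {
  n <- nrow(counts_list[[1]])
  npop <- length(counts_list)
  arr <- array(0L, c(n, 6, npop))
  for (j in seq_len(npop)) arr[, , j] <- as.integer(counts_list[[j]])
  pops <- names(counts_list)
  if (is.null(pops)) pops <- paste0("pop", seq_len(npop))
  if (is.null(treatment)) treatment <- pops
  man <- population_manifest(pops, treatment,
                             replicate = NA_integer_, pool_size = pool_size)
  sync_table(chrom %||% rep("2L", n), pos %||% seq_len(n),
             rep_len(ref, n), arr, man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# biallelic object for the 23-population design directly from minor counts
# minor, cov: site x population matrices with design population columns
make_design_bi <- function(minor, cov, pool_size = 140, include_ga = TRUE) {
  man <- default_manifest(pool_size = pool_size, include_ga = include_ga)
  stopifnot(ncol(minor) == nrow(man))
  colnames(minor) <- colnames(cov) <- man$population
  n <- nrow(minor)
  arr <- array(0L, c(n, 6, nrow(man)))
  for (j in seq_len(nrow(man))) {
    arr[, 1, j] <- as.integer(cov[, j] - minor[, j])  # major = A
    arr[, 3, j] <- as.integer(minor[, j])             # minor = C
  }
  sync <- sync_table(rep("2L", n), seq_len(n), rep("A", n), arr, man)
  reduce_biallelic(sync)
}
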