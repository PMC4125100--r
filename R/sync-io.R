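# Reading and writing popoolation2-style "sync" allele-count tables and the
# population manifest that binds sync columns to experimental populations.

SYNC_BASES <- c("A", "T", "C", "G", "N", "D")

#' Build a population manifest
#'
#' A manifest binds each population column of a sync table to its treatment
#' label, replicate index and pool size (in chromosomes). Ancestral
#' populations (`GA`, `AS`, `AC`) carry no replicate index.
#'
#' @param population character vector of unique population ids, in sync
#'   column order.
#' @param treatment treatment label per population; conventionally one of
#'   `GA`, `AS`, `AC`, `Salt`, `Cad`, `Temp`, `Spatial`.
#' @param replicate integer replicate index (1-5) per population, `NA` for
#'   ancestors.
#' @param pool_size pool size in chromosomes per population (140 for a pool
#'   of 70 diploid females).
#' @return A `data.table` of class `population_manifest` with one row per
#'   population.
#' @export
#' @examples
#' population_manifest(c("AS", "AC"), c("AS", "AC"))
population_manifest <- function(population, treatment,
                                replicate = NA_integer_, pool_size = 140) {
  m <- data.table(
    population = as.character(population),
    treatment = as.character(treatment),
    replicate = as.integer(replicate),
    pool_size = as.numeric(pool_size)
  )
  validate_manifest(m)
  setattr(m, "class", c("population_manifest", class(m)))
  m
}

validate_manifest <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("population", "treatment", "replicate", "pool_size") %in% names(m)))
  if (anyDuplicated(m$population)) stop("duplicated population ids in manifest")
  if (any(m$pool_size <= 0)) stop("pool sizes must be positive")
  reps <- m[!is.na(replicate), .N, by = .(treatment, replicate)]
  if (nrow(reps) && any(reps$N > 1))
    stop("a treatment has duplicated replicate indices")
  invisible(m)
}

#' The 23-population two-ancestor experimental design
#'
#' Grand ancestor (`GA`), two derived ancestors (`AS`, `AC`) and four
#' treatments (`Salt`, `Cad`, `Temp`, `Spatial`) with five replicates each.
#'
#' @param pool_size pool size in chromosomes (default 140).
#' @param include_ga include the grand-ancestor population (default `TRUE`).
#' @return a [population_manifest()].
#' @export
default_manifest <- function(pool_size = 140, include_ga = TRUE) {
  anc <- if (include_ga) c("GA", "AS", "AC") else c("AS", "AC")
  trt <- c("Salt", "Cad", "Temp", "Spatial")
  population_manifest(
    population = c(anc, paste0(rep(trt, each = 5), 1:5)),
    treatment = c(anc, rep(trt, each = 5)),
    replicate = c(rep(NA_integer_, length(anc)), rep(1:5, times = 4)),
    pool_size = pool_size
  )
}

#' Read a population manifest from TSV
#'
#' Expects columns `population`, `treatment`, `replicate`, `pool_size`.
#'
#' @param path file path.
#' @return a [population_manifest()].
#' @export
read_manifest <- function(path) {
  m <- fread(path, sep = "\t", colClasses = list(
    character = c("population", "treatment"), integer = "replicate",
    numeric = "pool_size"))
  population_manifest(m$population, m$treatment, m$replicate, m$pool_size)
}

#' Write a population manifest to TSV
#' @param manifest a [population_manifest()].
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  fwrite(as.data.table(manifest), path, sep = "\t")
  invisible(path)
}

#' Construct a sync table object
#'
#' A sync table stores, for each genomic site and population, the read counts
#' of the six sync categories A, T, C, G, N and deletion. Coordinates are
#' 1-based.
#'
#' @param chrom chromosome-arm names.
#' @param pos 1-based positions (integer, >= 1).
#' @param ref reference base per site (A/C/G/T/N).
#' @param counts integer array of dimension `(n_sites, 6, n_pops)`; the
#'   second dimension is in fixed order A, T, C, G, N, deletion.
#' @param manifest a [population_manifest()]; its row order defines the
#'   population order of `counts`.
#' @return an object of class `sync`.
#' @export
sync_table <- function(chrom, pos, ref, counts, manifest) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n)
  if (length(dim(counts)) != 3 || dim(counts)[2] != 6)
    stop("counts must be an (n_sites, 6, n_pops) array")
  if (dim(counts)[1] != n) stop("counts row count does not match site count")
  if (dim(counts)[3] != nrow(manifest))
    stop("counts population count does not match the manifest")
  if (any(pos < 1)) stop("positions must be >= 1")
  if (any(counts < 0)) stop("negative read counts")
  dimnames(counts) <- list(NULL, SYNC_BASES, manifest$population)
  structure(
    list(sites = data.table(chrom = as.character(chrom), pos = as.integer(pos),
                            ref = as.character(ref)),
         counts = counts, manifest = manifest),
    class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync table: %d sites x %d populations\n",
              nrow(x$sites), dim(x$counts)[3]))
  print(head(x$sites, 3))
  invisible(x)
}

#' Per-population read coverage of a sync table
#'
#' @param sync a [sync_table()].
#' @return numeric matrix `(n_sites, n_pops)`: sum of the six count
#'   categories.
#' @export
sync_coverage <- function(sync) {
  colSums(aperm(sync$counts, c(2, 1, 3)))
}

#' Read a sync file
#'
#' Parses tab-separated lines `chrom pos ref n1 ... nk` where each `ni` is a
#' colon-separated 6-tuple `A:T:C:G:N:del` of read counts for the i-th
#' population of the manifest.
#'
#' @param path path to the sync file.
#' @param manifest a [population_manifest()] whose rows match the population
#'   columns, in order.
#' @return a [sync_table()].
#' @export
#' @examples
#' man <- read_manifest(system.file("extdata", "toy_manifest.tsv",
#'                                  package = "evoregime"))
#' s <- read_sync(system.file("extdata", "toy.sync", package = "evoregime"),
#'                man)
#' sync_coverage(s)
read_sync <- function(path, manifest) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  npop <- nrow(manifest)
  if (!length(lines)) {
    return(sync_table(character(), integer(), character(),
                      array(0L, c(0, 6, npop)), manifest))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != npop + 3L)
  if (length(bad))
    stop(sprintf("sync parse error at line %d: expected %d fields, found %d",
                 bad[1], npop + 3L, nf[bad[1]]))
  fm <- matrix(unlist(fields), ncol = npop + 3L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(fm[, 2]))
  if (anyNA(pos) || any(pos < 1)) {
    bad <- which(is.na(pos) | pos < 1)[1]
    stop(sprintf("sync parse error at line %d: invalid position '%s'",
                 bad, fm[bad, 2]))
  }
  counts <- array(0L, c(length(lines), 6L, npop))
  for (j in seq_len(npop)) {
    parts <- strsplit(fm[, j + 3L], ":", fixed = TRUE)
    np <- lengths(parts)
    if (any(np != 6L)) {
      bad <- which(np != 6L)[1]
      stop(sprintf("sync parse error at line %d: count field '%s' is not a 6-tuple",
                   bad, fm[bad, j + 3L]))
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      bad <- ceiling(which(is.na(v))[1] / 6)
      stop(sprintf("sync parse error at line %d: non-integer count in '%s'",
                   bad, fm[bad, j + 3L]))
    }
    counts[, , j] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  sync_table(fm[, 1], pos, fm[, 3], counts, manifest)
}

#' Write a sync file
#'
#' Inverse of [read_sync()]: emits deterministic tab/colon-separated lines so
#' that write-then-read round-trips byte-for-byte.
#'
#' @param sync a [sync_table()].
#' @param path output path.
#' @export
write_sync <- function(sync, path) {
  n <- nrow(sync$sites)
  npop <- dim(sync$counts)[3]
  if (n == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  popcols <- vapply(seq_len(npop), function(j) {
    m <- sync$counts[, , j, drop = FALSE]
    dim(m) <- c(n, 6L)
    do.call(paste, c(lapply(seq_len(6), function(b) m[, b]), sep = ":"))
  }, character(n))
  if (n == 1) popcols <- matrix(popcols, nrow = 1)
  lines <- do.call(paste, c(list(sync$sites$chrom, sync$sites$pos,
                                 sync$sites$ref),
                            lapply(seq_len(npop), function(j) popcols[, j]),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# population ids for a treatment, in replicate order
treatment_pops <- function(manifest, treatment_label) {
  m <- as.data.table(manifest)
  out <- m[treatment == treatment_label][order(replicate)]$population
  if (!length(out)) stop(sprintf("no populations with treatment '%s'", treatment_label))
  out
}
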