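# Internal helpers shared across modules.

# Evaluate `code` with a private RNG stream; the caller's .Random.seed is
# untouched, so simulation functions are reproducible and side-effect free.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Chromosome ordering used for all genome-order outputs: numeric names first
# in numeric order, then the remainder (Z, W, ...) alphabetically.
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(sub("^(chr|GGA)", "", u, ignore.case = TRUE)))
  ord <- order(is.na(num), num, u)
  u[ord]
}

chrom_factor <- function(chroms) {
  factor(as.character(chroms), levels = chrom_order(chroms))
}

# 1-based inclusive intervals -> GRanges (already 1-based closed in R).
intervals_to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = as.character(chrom),
                         ranges = IRanges::IRanges(start = start, end = end))
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
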