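# Brute-force oracles, independent of the package's interval machinery.

# Transitive union of >=1 bp-overlapping intervals by explicit connected
# components over the all-pairs overlap graph.
oracle_merge <- function(df) {
  n <- nrow(df)
  if (n == 0) return(df[0, c("chrom", "start", "end")])
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    df$chrom[i] == df$chrom[j] && df$start[i] <= df$end[j] && df$end[i] >= df$start[j]))
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cid
      frontier <- which(is.na(comp) & apply(adj[, frontier, drop = FALSE], 1, any))
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix)
    data.frame(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
               end = max(df$end[ix]), n = length(ix))))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Does interval i of `a` overlap any interval of `b` by >= min_bp?
oracle_hits <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
        pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) + 1 >= min_bp)
  }, logical(1))
}

# Exhaustive per-line fixation check on a state matrix.
oracle_classify <- function(mat, line_of, lenient = FALSE) {
  lines <- sort(unique(line_of))
  t(vapply(seq_len(ncol(mat)), function(j) {
    carrier <- mat[, j] != "none"
    fixed_in <- lines[vapply(lines, function(L) all(carrier[line_of == L]), logical(1))]
    is_fixed <- length(fixed_in) > 0
    spec <- length(fixed_in) == 1 &&
      (lenient || !any(carrier[line_of != fixed_in]))
    c(is_fixed = is_fixed, is_line_specific = spec)
  }, logical(2)))
}

random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1e5,
                             max_len = 8e3) {
  start <- sample(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small probe map + cohort used by several files
tiny_map <- function(len = 2e5, spacing = 4000, jitter = 0, seed = 1, chroms = "1") {
  build_probe_map(genome_spec(chroms, rep(len, length(chroms))),
                  spacing_bp = spacing, jitter_fraction = jitter, seed = seed)
}

# Pairwise Jaccard distance on carrier profiles, written out longhand.
oracle_jaccard <- function(presence) {
  n <- nrow(presence)
  d <- matrix(0, n, n, dimnames = list(rownames(presence), rownames(presence)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    un <- sum(presence[i, ] | presence[j, ])
    d[i, j] <- if (un == 0) 0 else 1 - sum(presence[i, ] & presence[j, ]) / un
  }
  d
}
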