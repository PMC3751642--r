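#' Sample-to-line catalog
#'
#' @param samples data frame with `sample_id` and `line_id`, or a named
#'   character vector mapping sample to line.
#' @return A `line_catalog`: list with `map` (named vector sample -> line)
#'   and `n_samples` (named per-line counts).
#' @export
line_catalog <- function(samples) {
  map <- as_line_map(samples)
  if (any(map == "" | is.na(map))) stop_bad("every sample must map to a line")
  n <- table(map)
  structure(list(map = map, n_samples = stats::setNames(as.integer(n), names(n))),
            class = "line_catalog")
}

as_line_catalog <- function(x) if (inherits(x, "line_catalog")) x else line_catalog(x)

#' Per-sample copy-number state matrix over CNVRs
#'
#' For each sample and region the state is "gain" or "loss" if the sample
#' carries any call of that class overlapping the region, else "none". When
#' a sample carries both classes in one region, the class of the call with
#' the largest overlap wins.
#'
#' @param regions a `cnvr_catalog`.
#' @param calls per-sample `cnv_calls` (from [call_cohort()]).
#' @param line_catalog a [line_catalog()] covering every sample in `calls`;
#'   its samples define the matrix rows.
#' @return Character matrix samples x regions with values
#'   "none"/"gain"/"loss"; rownames are sample ids, colnames cnvr ids.
#' @export
occurrence_matrix <- function(regions, calls, line_catalog) {
  lc <- as_line_catalog(line_catalog)
  samples <- names(lc$map)
  miss <- setdiff(unique(calls$sample_id), samples)
  if (length(miss))
    stop_bad("samples not in the line catalog: %s", paste(miss, collapse = ", "))
  m <- matrix("none", nrow = length(samples), ncol = nrow(regions),
              dimnames = list(samples, regions$cnvr_id))
  if (nrow(calls) && nrow(regions)) {
    gr_c <- intervals_to_granges(calls$chrom, calls$start, calls$end)
    gr_r <- intervals_to_granges(regions$chrom, regions$start, regions$end)
    hit <- GenomicRanges::findOverlaps(gr_c, gr_r)
    if (length(hit)) {
      q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
      ov <- IRanges::width(IRanges::pintersect(gr_c[q], gr_r[s]))
      df <- data.frame(sample = calls$sample_id[q], region = s,
                       class = calls$class[q], ov = ov)
      # largest overlap wins within (sample, region)
      df <- df[order(df$sample, df$region, -df$ov), ]
      df <- df[!duplicated(df[c("sample", "region")]), ]
      m[cbind(df$sample, regions$cnvr_id[df$region])] <- df$class
    }
  }
  m
}

#' Classify CNVRs as line-fixed and line-specific
#'
#' A region is *fixed* in line L when every sampled animal of L carries it
#' (region-level carrier status: any overlapping call of either class). A
#' region is *line-specific* when it is fixed in exactly one line and, in
#' the default strict mode, no animal outside that line carries it; the
#' lenient mode drops the outside-carrier condition.
#'
#' @param mat state matrix from [occurrence_matrix()].
#' @param line_catalog a [line_catalog()].
#' @param lenient if TRUE, sporadic carriers outside the focal line do not
#'   disqualify line-specificity.
#' @return A `region_classification` data frame: `cnvr_id`, `is_fixed`,
#'   `fixed_lines` (comma-separated), `is_line_specific`, `specific_line`,
#'   `n_carriers`.
#' @export
classify_regions <- function(mat, line_catalog, lenient = FALSE) {
  lc <- as_line_catalog(line_catalog)
  if (any(lc$n_samples < 1)) stop_bad("a line has zero samples")
  samples <- rownames(mat)
  miss <- setdiff(samples, names(lc$map))
  if (length(miss)) stop_bad("unmapped samples: %s", paste(miss, collapse = ", "))
  line_of <- lc$map[samples]
  lines <- names(lc$n_samples)
  carrier <- mat != "none"
  per_line_carriers <- rowsum(carrier + 0L, group = line_of, reorder = TRUE)
  n_line <- lc$n_samples[rownames(per_line_carriers)]
  fixed <- per_line_carriers == n_line   # lines x regions
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    fl <- rownames(fixed)[fixed[, j]]
    is_fixed <- length(fl) > 0
    outside_ok <- if (length(fl) == 1) {
      if (lenient) TRUE
      else sum(per_line_carriers[, j]) == per_line_carriers[fl, j]
    } else FALSE
    data.frame(cnvr_id = colnames(mat)[j], is_fixed = is_fixed,
               fixed_lines = paste(fl, collapse = ","),
               is_line_specific = length(fl) == 1 && outside_ok,
               specific_line = if (length(fl) == 1 && outside_ok) fl else NA_character_,
               n_carriers = sum(carrier[, j]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_classification", "data.frame")
  out
}

#' Cluster samples by CNV genotype
#'
#' Hierarchical clustering of the per-sample CNVR state matrix. The default
#' Jaccard distance compares carrier status (any non-"none" state); the
#' Hamming distance compares the full three-level states. With strong
#' line-fixed CNV signal, cutting the tree at the number of lines recovers
#' the lines.
#'
#' @param mat state matrix from [occurrence_matrix()] (>= 2 samples).
#' @param distance "jaccard" or "hamming".
#' @param linkage "average" or "complete".
#' @param k optional number of clusters for a flat cut.
#' @return A `cnv_clustering` list: `hclust`, `dist`, and `assignments`
#'   (named cluster ids, when `k` given).
#' @export
cluster_samples <- function(mat, distance = c("jaccard", "hamming"),
                            linkage = c("average", "complete"), k = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(mat) < 2) stop_bad("need at least 2 samples to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]  # deterministic tie-break
  d <- switch(distance,
    jaccard = dist((mat != "none") + 0L, method = "binary"),
    hamming = {
      n <- nrow(mat)
      dm <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        dm[i, j] <- dm[j, i] <- mean(mat[i, ] != mat[j, ])
      }
      stats::as.dist(dm)
    })
  d[is.na(d)] <- 0   # two all-"none" samples are identical
  h <- hclust(d, method = linkage)
  out <- list(hclust = h, dist = d,
              assignments = if (!is.null(k)) cutree(h, k = k))
  class(out) <- "cnv_clustering"
  out
}

#' @export
print.cnv_clustering <- function(x, ...) {
  cat(sprintf("CNV clustering of %d samples (%s linkage)\n",
              length(x$hclust$order), x$hclust$method))
  if (!is.null(x$assignments))
    print(table(cluster = x$assignments))
  invisible(x)
}

#' Plot the sample dendrogram
#'
#' @param x a `cnv_clustering`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.cnv_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "sample", sub = "", ...)
}

#' Export the sample dendrogram as Newick
#'
#' @param clustering a `cnv_clustering` from [cluster_samples()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "cnv_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
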