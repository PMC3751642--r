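#' Merge unique CNVs into non-overlapping CNV regions
#'
#' CNVRs are the transitive union of CNVs overlapping by at least 1 bp,
#' irrespective of class (the Redon-style aggregation used for population
#' CNV maps). A region's extent runs from the minimum member start to the
#' maximum member end; its type is "gain", "loss" or "both" according to its
#' members' classes; occurrence totals are summed over members. Region ids
#' are assigned in genome order.
#'
#' @param cnvs a `unique_cnvs` data frame from [collate_calls()] or
#'   [read_cnv_table()] (minimally `chrom`, `start`, `end`; `class`,
#'   `occurrence_total` and per-line columns are propagated when present).
#' @return A `cnvr_catalog` data frame: `cnvr_id`, `chrom`, `start`, `end`,
#'   `type`, `n_members`, `occurrence_total`, per-line occurrence columns,
#'   and `member_cnvs` (comma-separated cnv ids).
#' @export
merge_to_cnvrs <- function(cnvs) {
  stopifnot(is.data.frame(cnvs), all(c("chrom", "start", "end") %in% names(cnvs)))
  if (any(cnvs$start > cnvs$end)) stop_bad("malformed interval: start > end")
  lines <- attr(cnvs, "lines")
  if (nrow(cnvs) == 0) {
    out <- data.frame(cnvr_id = character(), chrom = character(), start = numeric(),
                      end = numeric(), type = character(), n_members = integer(),
                      occurrence_total = integer(), member_cnvs = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cnvr_catalog", "data.frame")
    return(out)
  }
  if (is.null(cnvs$cnv_id)) cnvs$cnv_id <- sprintf("CNV%04d", seq_len(nrow(cnvs)))
  gr <- intervals_to_granges(cnvs$chrom, cnvs$start, cnvs$end)
  red <- IRanges::reduce(gr)   # >= 1 bp overlap: transitive union
  hit <- GenomicRanges::findOverlaps(gr, red)
  memb <- split(S4Vectors::queryHits(hit), S4Vectors::subjectHits(hit))
  ord <- order(chrom_factor(as.character(GenomicRanges::seqnames(red))),
               GenomicRanges::start(red))
  rows <- lapply(seq_along(ord), function(i) {
    ri <- ord[i]
    ix <- memb[[as.character(ri)]]
    cls <- unique(cnvs$class[ix])
    type <- if (is.null(cnvs$class) || all(is.na(cls))) NA_character_
            else if (all(cls == "gain", na.rm = TRUE)) "gain"
            else if (all(cls == "loss", na.rm = TRUE)) "loss" else "both"
    base <- data.frame(cnvr_id = sprintf("CNVR%04d", i),
                       chrom = as.character(GenomicRanges::seqnames(red))[ri],
                       start = min(cnvs$start[ix]), end = max(cnvs$end[ix]),
                       type = type, n_members = length(ix),
                       occurrence_total = if (is.null(cnvs$occurrence_total)) length(ix)
                                          else sum(cnvs$occurrence_total[ix]),
                       stringsAsFactors = FALSE)
    if (!is.null(lines))
      for (ln in lines) base[[ln]] <- sum(cnvs[[ln]][ix])
    base$member_cnvs <- paste(cnvs$cnv_id[ix], collapse = ",")
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lines") <- lines
  class(out) <- c("cnvr_catalog", "data.frame")
  out
}

#' Interval size in kb, using printed-coordinate convention
#'
#' Sizes are computed as `(end - start) / 1000` on 1-based inclusive
#' coordinates, the convention used when CNVR sizes are quoted alongside
#' printed genomic positions, and reported to 0.1 kb.
#'
#' @param start start coordinate(s) (1-based inclusive), or a data frame
#'   with `start` and `end` columns.
#' @param end end coordinate(s) when `start` is numeric.
#' @return Numeric size(s) in kb, rounded to 0.1 kb.
#' @examples
#' region_size_kb(144185960, 144403060)  # 217.1
#' @export
region_size_kb <- function(start, end = NULL) {
  if (is.data.frame(start)) { end <- start$end; start <- start$start }
  if (any(end < start)) stop_bad("reversed coordinates: end < start")
  round((end - start) / 1000, 1)
}

#' Summary statistics of a CNV/CNVR catalog
#'
#' @param cnvs a `unique_cnvs` data frame.
#' @param regions the matching `cnvr_catalog` from [merge_to_cnvrs()].
#' @param genome_length_bp total genome length used for percent coverage
#'   (default: the sum of chromosome lengths of `probe_map`'s genome when
#'   supplied).
#' @param line_catalog optional [line_catalog()]; enables mean calls per
#'   animal per line.
#' @param probe_map optional probe map whose genome supplies
#'   `genome_length_bp`.
#' @return A `catalog_stats` list: `n_cnv`, `n_cnvr`, `mean_cnv_size_kb`,
#'   `n_recurrent_cnv` and `mean_recurrent_cnv_size_kb` (occurrence >= 2),
#'   `total_cnvr_coverage_bp`, `pct_genome`, `pct_loss`, `largest_cnv_kb`,
#'   `per_line_mean_calls`.
#' @export
catalog_stats <- function(cnvs, regions, genome_length_bp = NULL,
                          line_catalog = NULL, probe_map = NULL) {
  if (is.null(genome_length_bp) && !is.null(probe_map)) {
    g <- attr(probe_map, "genome")
    if (!is.null(g)) genome_length_bp <- sum(g$length)
  }
  if (nrow(cnvs) == 0) {
    warning("empty CNV catalog: all statistics are zero", call. = FALSE)
    return(structure(list(n_cnv = 0L, n_cnvr = 0L, mean_cnv_size_kb = 0,
                          mean_recurrent_cnv_size_kb = 0, n_recurrent_cnv = 0L,
                          total_cnvr_coverage_bp = 0, pct_genome = 0,
                          pct_loss = 0, largest_cnv_kb = 0,
                          per_line_mean_calls = NULL),
                     class = "catalog_stats"))
  }
  if (is.null(genome_length_bp) || genome_length_bp <= 0)
    stop_bad("genome_length_bp must be a positive number")
  sizes <- (cnvs$end - cnvs$start) / 1000
  occ <- if (is.null(cnvs$occurrence_total)) rep(1L, nrow(cnvs)) else cnvs$occurrence_total
  rec <- occ >= 2
  coverage <- sum(regions$end - regions$start)
  per_line <- NULL
  if (!is.null(line_catalog)) {
    line_catalog <- as_line_catalog(line_catalog)
    per_line <- vapply(names(line_catalog$n_samples), function(ln) {
      if (is.null(cnvs[[ln]])) return(NA_real_)
      sum(cnvs[[ln]]) / line_catalog$n_samples[[ln]]
    }, numeric(1))
  }
  structure(list(
    n_cnv = nrow(cnvs), n_cnvr = nrow(regions),
    mean_cnv_size_kb = round(mean(sizes), 1),
    mean_recurrent_cnv_size_kb = if (any(rec)) round(mean(sizes[rec]), 1) else 0,
    n_recurrent_cnv = sum(rec),
    total_cnvr_coverage_bp = coverage,
    pct_genome = 100 * coverage / genome_length_bp,
    pct_loss = if (is.null(cnvs$class)) NA_real_
               else 100 * mean(cnvs$class == "loss", na.rm = TRUE),
    largest_cnv_kb = round(max(sizes), 1),
    per_line_mean_calls = per_line), class = "catalog_stats")
}

#' @export
print.catalog_stats <- function(x, ...) {
  cat(sprintf("CNV catalog: %d CNVs (%d recurrent) in %d CNVRs\n",
              x$n_cnv, x$n_recurrent_cnv, x$n_cnvr))
  cat(sprintf("  mean CNV size %.1f kb (recurrent %.1f kb), largest %.1f kb\n",
              x$mean_cnv_size_kb, x$mean_recurrent_cnv_size_kb, x$largest_cnv_kb))
  cat(sprintf("  CNVR coverage %.1f Mb = %.2f%% of genome; %.1f%% of CNVs are losses\n",
              x$total_cnvr_coverage_bp / 1e6, x$pct_genome, x$pct_loss))
  if (!is.null(x$per_line_mean_calls)) {
    cat("  mean CNV carriage per animal by line:\n")
    print(round(x$per_line_mean_calls, 1))
  }
  invisible(x)
}

#' Annotate CNVRs with overlapping gene intervals
#'
#' A gene is assigned to a region when it overlaps it by at least 1 bp
#' (completely or partially). The unique gene count deduplicates genes
#' spanning several regions.
#'
#' @param regions a `cnvr_catalog`.
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return List with `per_region` (named list of gene-id vectors, one per
#'   cnvr_id), `unique_genes` and `n_unique`.
#' @export
annotate_genes <- function(regions, genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop_bad("malformed gene interval")
  per_region <- stats::setNames(vector("list", nrow(regions)), regions$cnvr_id)
  if (nrow(regions) && nrow(genes)) {
    gr_r <- intervals_to_granges(regions$chrom, regions$start, regions$end)
    gr_g <- intervals_to_granges(genes$chrom, genes$start, genes$end)
    hit <- GenomicRanges::findOverlaps(gr_r, gr_g)
    for (i in seq_len(nrow(regions))) per_region[[i]] <- character()
    if (length(hit)) {
      sp <- split(genes$gene_id[S4Vectors::subjectHits(hit)], S4Vectors::queryHits(hit))
      for (nm in names(sp)) per_region[[as.integer(nm)]] <- unique(sp[[nm]])
    }
  }
  ug <- unique(unlist(per_region, use.names = FALSE))
  list(per_region = per_region, unique_genes = ug, n_unique = length(ug))
}
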