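#' Normalize chromosome names across naming schemes
#'
#' Harmonizes "chr2", "GGA2" and "2" (case-insensitive) to a common form;
#' an alias table applies first for anything irregular.
#'
#' @param x character chromosome names.
#' @param aliases optional named character vector, `names(aliases)` being
#'   the irregular spelling and the value its canonical name.
#' @return Character vector of harmonized names.
#' @export
harmonize_chrom <- function(x, aliases = NULL) {
  x <- as.character(x)
  if (!is.null(aliases)) {
    hit <- match(x, names(aliases))
    x[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  toupper(sub("^(chr|GGA)", "", x, ignore.case = TRUE))
}

#' Fraction of external CNV intervals hitting the CNVR catalog
#'
#' Counts how many intervals of an external CNV set (for instance
#' inter-specific CNVs detected between bird species) overlap any CNVR by at
#' least `min_overlap_bp`. Intervals on chromosomes that cannot be resolved
#' against the catalog's genome (for example a chromosome absent from the
#' probe design) are excluded from the denominator and reported.
#'
#' @param external data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), optionally carrying a `label` attribute or column.
#' @param regions a `cnvr_catalog`.
#' @param min_overlap_bp minimum overlap to count a hit (default 1).
#' @param aliases chromosome alias table, see [harmonize_chrom()].
#' @param label optional set label for printing.
#' @param genome_chroms chromosomes covered by the probe design. When given,
#'   external intervals on other chromosomes are excluded from the
#'   denominator; by default every interval counts.
#' @return An `overlap_result` list: `label`, `n_overlapping`, `n_total`
#'   (resolvable intervals), `fraction`, `n_excluded`, `excluded_chroms`,
#'   and `hits` (logical per resolvable interval).
#' @export
overlap_fraction <- function(external, regions, min_overlap_bp = 1,
                             aliases = NULL, label = NULL,
                             genome_chroms = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(external)))
  if (nrow(external) == 0) stop_bad("external CNV set is empty")
  if (is.null(label)) label <- attr(external, "label") %||% "external"
  ext_chr <- harmonize_chrom(external$chrom, aliases)
  reg_chr <- harmonize_chrom(regions$chrom, aliases)
  resolvable <- if (is.null(genome_chroms)) rep(TRUE, nrow(external))
                else ext_chr %in% unique(harmonize_chrom(genome_chroms, aliases))
  excluded <- unique(as.character(external$chrom)[!resolvable])
  ext <- external[resolvable, , drop = FALSE]
  n_total <- nrow(ext)
  if (n_total == 0)
    stop_bad("no external interval maps to a catalog chromosome")
  hits <- rep(FALSE, n_total)
  if (nrow(regions)) {
    gr_e <- intervals_to_granges(ext_chr[resolvable], ext$start, ext$end)
    gr_r <- intervals_to_granges(reg_chr, regions$start, regions$end)
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(gr_e, gr_r, minoverlap = min_overlap_bp))
    hits[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  structure(list(label = label, n_overlapping = sum(hits), n_total = n_total,
                 fraction = sum(hits) / n_total, n_excluded = length(excluded),
                 excluded_chroms = excluded, hits = hits),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d intervals overlap a CNVR (%.1f%%)\n",
              x$label, x$n_overlapping, x$n_total, 100 * x$fraction))
  if (x$n_excluded)
    cat(sprintf("  excluded (unresolvable chromosome): %s\n",
                paste(x$excluded_chroms, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
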