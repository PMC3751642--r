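# All catalog/profile files are tab-delimited text with a header row and
# 1-based inclusive coordinates; BED exports alone use 0-based half-open
# coordinates per the BED standard.

#' Write a cohort's log2 profiles as tab-delimited text
#'
#' Columns: probe_id, chrom, start, end (1-based inclusive), then one log2
#' column per sample. Values are written to 6 decimals, so a write/read
#' round trip is lossless at that precision. Sample metadata (line, sex) and
#' the truth table, when present, are written alongside as
#' `<stem>.samples.tsv` / `<stem>.truth.tsv`.
#'
#' @param cohort an `acgh_cohort`.
#' @param path output profile file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(cohort, path) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  pm <- cohort$probe_map
  df <- data.frame(pm[c("probe_id", "chrom", "start", "end")],
                   apply(cohort$log2, 2, function(v) sprintf("%.6f", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("probe_id", "chrom", "start", "end", colnames(cohort$log2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stem <- sub("\\.tsv$", "", path)
  write.table(cohort$samples, paste0(stem, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth) && nrow(cohort$truth))
    write_truth(cohort$truth, paste0(stem, ".truth.tsv"))
  invisible(path)
}

#' Read a tab-delimited profile file
#'
#' Validates the probe grid: probe ids must be unique and probes sorted by
#' position within each chromosome; every log2 cell must be numeric. Errors
#' name the offending row.
#'
#' @param path profile file from [write_profiles()].
#' @param samples optional path to the sample metadata file (defaults to
#'   `<stem>.samples.tsv` when present).
#' @return An `acgh_cohort` (without covariate or truth unless found
#'   alongside).
#' @export
read_profiles <- function(path, samples = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop_bad("profile file must start with columns: %s", paste(need, collapse = ", "))
  dup <- which(duplicated(df$probe_id))
  if (length(dup)) stop_bad("duplicated probe id '%s' at row %d", df$probe_id[dup[1]], dup[1])
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end))
    stop_bad("non-numeric coordinate at row %d", which(is.na(start) | is.na(end))[1])
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    if (is.unsorted(start[idx], strictly = TRUE))
      stop_bad("probes unsorted on chromosome %s near row %d", ch,
               idx[which(diff(start[idx]) <= 0)[1] + 1L])
  }
  sample_cols <- setdiff(names(df), need)
  m <- matrix(NA_real_, nrow(df), length(sample_cols),
              dimnames = list(df$probe_id, sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(df[[sample_cols[j]]]))
    bad <- which(is.na(v) & !(df[[sample_cols[j]]] %in% c("NA", "")))
    if (length(bad))
      stop_bad("non-numeric value '%s' in column %s at row %d",
               df[[sample_cols[j]]][bad[1]], sample_cols[j], bad[1])
    m[, j] <- v
  }
  pm <- structure(data.frame(probe_id = df$probe_id, chrom = df$chrom,
                             start = start, end = end, stringsAsFactors = FALSE),
                  class = c("probe_map", "data.frame"))
  stem <- sub("\\.tsv$", "", path)
  if (is.null(samples) && file.exists(paste0(stem, ".samples.tsv")))
    samples <- paste0(stem, ".samples.tsv")
  smp <- if (!is.null(samples)) read.delim(samples, stringsAsFactors = FALSE)
         else data.frame(sample_id = sample_cols, line_id = NA_character_,
                         stringsAsFactors = FALSE)
  truth_path <- paste0(stem, ".truth.tsv")
  truth <- if (file.exists(truth_path)) read_truth(truth_path)
  structure(list(probe_map = pm, log2 = m,
                 samples = smp[match(sample_cols, smp$sample_id), , drop = FALSE],
                 covariate = NULL, truth = truth),
            class = "acgh_cohort")
}

#' Write / read a truth CNV table (BED-like TSV with copy number)
#'
#' @param truth data frame `sample_id`, `chrom`, `start`, `end`,
#'   `copy_number` (1-based inclusive coordinates).
#' @param path file path.
#' @return The path (write) or the truth data frame (read).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-sample CNV calls as BED
#'
#' BED uses 0-based half-open coordinates: `start - 1`, `end`. The name
#' field is `sample_id:class`, the score the mean log2 ratio, strand ".".
#'
#' @param calls a `cnv_calls` or `unique_cnvs` data frame.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  name <- if (!is.null(calls$sample_id)) paste0(calls$sample_id, ":", calls$class)
          else if (!is.null(calls$cnv_id)) paste0(calls$cnv_id, ":", calls$class)
          else if (!is.null(calls$cnvr_id)) calls$cnvr_id
          else "region"
  score <- if (!is.null(calls$mean_log2)) sprintf("%.4f", calls$mean_log2)
           else if (!is.null(calls$occurrence_total)) calls$occurrence_total else 0
  bed <- data.frame(chrom = calls$chrom, start = calls$start - 1, end = calls$end,
                    name = name, score = score, strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a unique-CNV catalog as TSV
#'
#' Internal dialect: `cnv_id`, `cnvr_id` (when regions are supplied),
#' `chrom`, `start`, `end`, `class`, `occurrence_total`, one per-line
#' occurrence column, `carrier_samples`.
#'
#' @param cnvs a `unique_cnvs` data frame.
#' @param path output file.
#' @param regions optional `cnvr_catalog`, used to attach each CNV's region.
#' @return `path`, invisibly.
#' @export
write_cnv_catalog <- function(cnvs, path, regions = NULL) {
  out <- as.data.frame(cnvs)
  if (!is.null(regions) && nrow(out)) {
    member <- strsplit(regions$member_cnvs, ",")
    map <- stats::setNames(rep(regions$cnvr_id, lengths(member)), unlist(member))
    out <- cbind(out[1], cnvr_id = unname(map[out$cnv_id]), out[-1])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV table
#'
#' Two dialects are supported. `"internal"` is the format written by
#' [write_cnv_catalog()]. `"additional_file_1"` mirrors published
#' population-CNV supplementary tables: first column the CNV number, second
#' the CNVR number, then chromosome, start and end of the CNV, the overall
#' occurrence across animals, followed by per-line occurrence columns
#' (matched case-insensitively against the line catalog) and tolerated
#' extra columns.
#'
#' @param path TSV file.
#' @param dialect "internal" or "additional_file_1".
#' @param line_catalog optional [line_catalog()]; its line ids select and
#'   validate the per-line occurrence columns.
#' @return A `unique_cnvs` data frame.
#' @export
read_cnv_table <- function(path, dialect = c("internal", "additional_file_1"),
                           line_catalog = NULL) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "additional_file_1") {
    if (ncol(df) < 6)
      stop_bad("additional_file_1 dialect needs >= 6 columns (cnv, cnvr, chrom, start, end, occurrence)")
    names(df)[1:6] <- c("cnv_id", "cnvr_id", "chrom", "start", "end",
                        "occurrence_total")
    if (is.null(df$class)) df$class <- NA_character_
  }
  need <- c("chrom", "start", "end", "occurrence_total")
  if (!all(need %in% names(df)))
    stop_bad("CNV table must contain columns: %s", paste(need, collapse = ", "))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$occurrence_total <- as.integer(df$occurrence_total)
  bad <- which(df$occurrence_total < 1)
  if (length(bad))
    stop_bad("CNV at row %d has occurrence %d (must be >= 1)", bad[1],
             df$occurrence_total[bad[1]])
  lines <- NULL
  if (!is.null(line_catalog)) {
    lc <- as_line_catalog(line_catalog)
    want <- names(lc$n_samples)
    got <- match(tolower(want), tolower(names(df)))
    if (anyNA(got))
      stop_bad("line column(s) missing from table: %s",
               paste(want[is.na(got)], collapse = ", "))
    names(df)[got] <- want
    lines <- want
  }
  if (is.null(df$cnv_id)) df$cnv_id <- sprintf("CNV%04d", seq_len(nrow(df)))
  attr(df, "lines") <- lines
  class(df) <- c("unique_cnvs", "data.frame")
  df
}

#' Write a CNVR catalog as TSV
#'
#' @param regions a `cnvr_catalog`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cnvr_catalog <- function(regions, path) {
  write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run the whole pipeline on a synthetic scenario
#'
#' Simulation, normalization, self-self threshold calibration, per-sample
#' calling, collation, CNVR merging, line classification, clustering and
#' catalog statistics, with every stage written to an artifact directory as
#' TSV/BED plus a run log. Deterministic given `config$seed`.
#'
#' @param config a list or the path of a YAML file with (all optional):
#'   `seed`, `out_dir`, `genome` (list of `name`/`length` vectors, or the
#'   scale of [example_genome()]), `spacing_bp`, `jitter_fraction`,
#'   `noise_sd`, `shared_cnv_rate`, `private_cnv_rate`, `dye_bias_amplitude`,
#'   `span`, `sex_center`, `n_self_self`, `grid`, `target_false_calls`,
#'   `min_probes`, `max_gap_probes`, `lenient_specific`, `cluster_k`.
#' @return Invisibly, a list with the computed objects (`cohort`,
#'   `calibration`, `calls`, `cnvs`, `regions`, `classification`,
#'   `clustering`, `stats`) and the artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(name, default) config[[name]] %||% default
  seed <- cfg("seed", 1L)
  out_dir <- cfg("out_dir", tempfile("acghcnv_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_bad("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  genome <- step("genome", {
    g <- cfg("genome", NULL)
    if (is.null(g)) example_genome()
    else if (is.numeric(g)) example_genome(scale = g)
    else genome_spec(g$name, g$length)
  })
  pm <- step("probe_map", build_probe_map(genome, spacing_bp = cfg("spacing_bp", 4000),
             jitter_fraction = cfg("jitter_fraction", 0.2), seed = seed))
  lines <- step("lines", {
    ls <- cfg("lines", NULL)
    if (is.null(ls)) default_lines(noise_sd = cfg("noise_sd", 0.1),
                                   shared_cnv_rate = cfg("shared_cnv_rate", 0.5),
                                   private_cnv_rate = cfg("private_cnv_rate", 0.1))
    else lapply(ls, function(l) do.call(line_spec, l))
  })
  cohort <- step("simulate", simulate_cohort(pm, lines, seed = seed + 1L,
                 dye_bias_amplitude = cfg("dye_bias_amplitude", 0.1)))
  write_profiles(cohort, file.path(out_dir, "profiles.tsv"))
  norm <- step("normalize", normalize_cohort(cohort, span = cfg("span", 0.3),
               per_chromosome_center = cfg("sex_center", FALSE)))
  write_profiles(norm, file.path(out_dir, "profiles_normalized.tsv"))
  selfself <- step("self_self", {
    ss <- simulate_self_self(pm, noise_sd = cfg("noise_sd", 0.1),
                             n_arrays = cfg("n_self_self", 5), seed = seed + 2L,
                             dye_bias_amplitude = cfg("dye_bias_amplitude", 0.1))
    normalize_cohort(ss, span = cfg("span", 0.3))
  })
  calib <- step("calibrate", calibrate_threshold(selfself,
                grid = cfg("grid", seq(2, 6, by = 0.5)),
                min_probes = cfg("min_probes", 2L),
                max_gap_probes = cfg("max_gap_probes", 1L),
                target_false_calls_per_array = cfg("target_false_calls", 1)))
  calls <- step("call", call_cohort(norm, calib))
  write_bed(calls, file.path(out_dir, "calls.bed"))
  lc <- line_catalog(cohort$samples)
  cnvs <- step("collate", collate_calls(calls, lc))
  regions <- step("merge", merge_to_cnvrs(cnvs))
  write_cnv_catalog(cnvs, file.path(out_dir, "cnvs.tsv"), regions)
  write_cnvr_catalog(regions, file.path(out_dir, "cnvrs.tsv"))
  write_bed(regions, file.path(out_dir, "cnvrs.bed"))
  mat <- step("occurrence", occurrence_matrix(regions, calls, lc))
  classification <- step("classify", classify_regions(mat, lc,
                          lenient = cfg("lenient_specific", FALSE)))
  write.table(classification, file.path(out_dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clustering <- if (nrow(mat) >= 2 && ncol(mat) >= 1)
    step("cluster", cluster_samples(mat, k = cfg("cluster_k", length(lines))))
  if (!is.null(clustering)) write_newick(clustering, file.path(out_dir, "dendrogram.nwk"))
  stats <- step("stats", catalog_stats(cnvs, regions,
                genome_length_bp = cfg("genome_length_bp", sum(genome$length)),
                line_catalog = lc))
  stats_df <- data.frame(
    stat = c("n_cnv", "n_cnvr", "mean_cnv_size_kb", "mean_recurrent_cnv_size_kb",
             "n_recurrent_cnv", "total_cnvr_coverage_bp", "pct_genome",
             "pct_loss", "largest_cnv_kb"),
    value = c(stats$n_cnv, stats$n_cnvr, stats$mean_cnv_size_kb,
              stats$mean_recurrent_cnv_size_kb, stats$n_recurrent_cnv,
              stats$total_cnvr_coverage_bp, round(stats$pct_genome, 4),
              round(stats$pct_loss, 4), stats$largest_cnv_kb))
  write.table(stats_df, file.path(out_dir, "stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_lines <- c(sprintf("acghcnv %s", as.character(utils::packageVersion("acghcnv"))),
                 sprintf("seed\t%d", as.integer(seed)),
                 sprintf("threshold_t\t%.3f", calib$t),
                 sprintf("mean_sd_e\t%.5f", calib$sd_e),
                 sprintf("min_probes\t%d", calib$min_probes),
                 sprintf("max_gap_probes\t%d", calib$max_gap_probes),
                 sprintf("target_false_calls\t%.3f", calib$target_false_calls_per_array),
                 sprintf("n_probes\t%d", nrow(pm)),
                 sprintf("n_samples\t%d", ncol(cohort$log2)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(out_dir = out_dir, cohort = cohort, normalized = norm,
                 calibration = calib, calls = calls, cnvs = cnvs,
                 regions = regions, occurrence = mat,
                 classification = classification, clustering = clustering,
                 stats = stats))
}
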