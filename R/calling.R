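#' Robust per-array noise estimate
#'
#' Estimates the per-probe noise SD of a log2 profile from the median
#' absolute successive difference, `median(|x[i+1] - x[i]|) / (0.6745 *
#' sqrt(2))`. Because a CNV shifts a run of consecutive probes together, its
#' probes contribute only two large differences at its boundaries, so the
#' estimate is robust to a minority of CNV-bearing probes (unlike the sample
#' SD).
#'
#' @param values numeric log2 series (>= 10 probes) or an `acgh_profile`.
#' @return `sd_e`, the noise SD in log2 units (0 for a constant profile).
#' @export
estimate_noise <- function(values) {
  if (inherits(values, "acgh_profile")) values <- values$values
  if (length(values) < 10) stop_bad("need at least 10 probes to estimate noise")
  median(abs(diff(values))) / (0.6745 * sqrt(2))
}

#' Calling parameters calibrated on self-self arrays
#'
#' @param t threshold multiple of the per-array noise SD.
#' @param min_probes minimum probes per call (default 2).
#' @param max_gap_probes sub-threshold probes bridged between same-sign runs.
#' @param target_false_calls_per_array calibration target.
#' @param sd_e reference noise level (informational; [call_segments()]
#'   re-estimates noise per profile).
#' @param mean_false_calls mean self-self calls at `t` (filled by
#'   [calibrate_threshold()]).
#' @param warning TRUE when no grid value met the target.
#' @param grid_evaluation per-grid-point mean self-self call counts.
#' @return A `noise_calibration` object.
#' @export
noise_calibration <- function(t, min_probes = 2L, max_gap_probes = 1L,
                              target_false_calls_per_array = 1,
                              sd_e = NA_real_, mean_false_calls = NA_real_,
                              warning = FALSE, grid_evaluation = NULL) {
  stopifnot(t > 0, min_probes >= 1, max_gap_probes >= 0)
  if (!is.na(sd_e) && sd_e < 0) stop_bad("sd_e must be >= 0")
  structure(list(t = t, min_probes = as.integer(min_probes),
                 max_gap_probes = as.integer(max_gap_probes),
                 target_false_calls_per_array = target_false_calls_per_array,
                 sd_e = sd_e, mean_false_calls = mean_false_calls,
                 warning = warning, grid_evaluation = grid_evaluation),
            class = "noise_calibration")
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf("Noise calibration: t = %.2f x sd_e (sd_e ~ %.4f), min_probes = %d, max_gap = %d\n",
              x$t, x$sd_e, x$min_probes, x$max_gap_probes))
  cat(sprintf("  mean self-self calls/array %.3f (target %.3f)%s\n",
              x$mean_false_calls, x$target_false_calls_per_array,
              if (isTRUE(x$warning)) " [target not met: largest grid value used]" else ""))
  invisible(x)
}

#' Calibrate the calling threshold on self-self hybridizations
#'
#' Self-self arrays contain no true CNVs, so every call on them is a false
#' positive. The threshold multiple `t` is chosen empirically as the
#' smallest value on an ascending grid for which the mean number of calls
#' per self-self array does not exceed the target; if no grid value
#' qualifies, the largest is returned with a warning flag.
#'
#' @param self_self an `acgh_cohort` of self-self arrays (>= 2), e.g. from
#'   [simulate_self_self()], or a probes x arrays matrix.
#' @param grid ascending threshold multiples to evaluate.
#' @param min_probes,max_gap_probes segmentation parameters, see
#'   [call_segments()].
#' @param target_false_calls_per_array acceptable mean false calls.
#' @param probe_map needed when `self_self` is a plain matrix.
#' @return A [noise_calibration()] with the grid evaluation attached.
#' @export
calibrate_threshold <- function(self_self, grid = seq(2, 6, by = 0.5),
                                min_probes = 2L, max_gap_probes = 1L,
                                target_false_calls_per_array = 1,
                                probe_map = NULL) {
  if (inherits(self_self, "acgh_cohort")) {
    probe_map <- self_self$probe_map
    m <- self_self$log2
  } else m <- as.matrix(self_self)
  if (is.null(probe_map)) stop_bad("a probe map is required")
  if (ncol(m) < 2) stop_bad("need at least 2 self-self arrays")
  if (length(grid) == 0) stop_bad("threshold grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) stop_bad("threshold grid must be ascending")
  counts <- vapply(grid, function(t) {
    mean(vapply(seq_len(ncol(m)), function(j) {
      nrow(segment_profile(m[, j], probe_map, t = t, min_probes = min_probes,
                           max_gap_probes = max_gap_probes))
    }, numeric(1)))
  }, numeric(1))
  ok <- which(counts <= target_false_calls_per_array)
  if (length(ok)) { pick <- ok[1]; warn <- FALSE }
  else { pick <- length(grid); warn <- TRUE }
  noise_calibration(t = grid[pick], min_probes = min_probes,
                    max_gap_probes = max_gap_probes,
                    target_false_calls_per_array = target_false_calls_per_array,
                    sd_e = mean(apply(m, 2, estimate_noise)),
                    mean_false_calls = counts[pick], warning = warn,
                    grid_evaluation = data.frame(t = grid, mean_calls = counts))
}

# Core run-based segmentation of one numeric profile. Returns a data.frame
# of calls (chrom, start, end, class, n_probes, mean_log2).
segment_profile <- function(values, probe_map, t, min_probes, max_gap_probes) {
  sd_e <- estimate_noise(values)
  thr <- t * sd_e
  if (sd_e == 0 && any(values != 0))
    warning("zero noise estimate with non-zero probes: every non-zero run is called",
            call. = FALSE)
  state <- integer(length(values))
  state[values > thr] <- 1L
  state[values < -thr] <- -1L
  out <- list()
  for (ch in unique(probe_map$chrom)) {
    idx <- which(probe_map$chrom == ch)
    runs <- find_runs(state[idx], max_gap_probes)
    if (!nrow(runs)) next
    first <- idx[runs$from]; last <- idx[runs$to]
    n_probes <- runs$to - runs$from + 1L
    keep <- n_probes >= min_probes
    if (!any(keep)) next
    mean_log2 <- vapply(which(keep), function(k)
      mean(values[idx[runs$from[k]:runs$to[k]]]), numeric(1))
    out[[ch]] <- data.frame(chrom = ch,
                            start = probe_map$start[first[keep]],
                            end = probe_map$end[last[keep]],
                            class = ifelse(runs$sign[keep] > 0, "gain", "loss"),
                            n_probes = n_probes[keep],
                            mean_log2 = mean_log2,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      class = character(), n_probes = integer(),
                      mean_log2 = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(chrom_factor(res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Maximal same-sign runs of a -1/0/+1 state vector; same-sign runs separated
# by <= max_gap sub-threshold (0) probes are merged. Opposite signs never
# merge. Returns data.frame(from, to, sign) in index order.
find_runs <- function(state, max_gap) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- which(r$values != 0L)
  if (!length(nz)) return(data.frame(from = integer(), to = integer(), sign = integer()))
  from <- starts[nz]; to <- ends[nz]; sgn <- r$values[nz]
  merged_from <- from[1]; merged_to <- to[1]; merged_sgn <- sgn[1]
  res <- list()
  for (k in seq_along(nz)[-1]) {
    gap <- from[k] - merged_to[length(merged_to)] - 1L
    last <- length(merged_to)
    if (sgn[k] == merged_sgn[last] && gap <= max_gap) {
      merged_to[last] <- to[k]
    } else {
      merged_from <- c(merged_from, from[k])
      merged_to <- c(merged_to, to[k])
      merged_sgn <- c(merged_sgn, sgn[k])
    }
  }
  data.frame(from = merged_from, to = merged_to, sign = merged_sgn)
}

#' Call CNV segments in one profile
#'
#' Threshold-run segmentation in the style of CNVfinder: maximal runs of
#' probes whose normalized log2 value exceeds `+t * sd_e` (gain) or falls
#' below `-t * sd_e` (loss), where `sd_e` is re-estimated from this profile
#' by [estimate_noise()]. Same-sign runs separated by at most
#' `max_gap_probes` sub-threshold probes are merged (single probe dropouts
#' are common); merged runs shorter than `min_probes` probes are discarded.
#' A call spans from the first probe's start to the last probe's end.
#'
#' @param profile an `acgh_profile` (see [get_profile()]), or numeric values
#'   with `probe_map` supplied.
#' @param calibration a [noise_calibration()].
#' @param probe_map probe map when `profile` is a numeric vector.
#' @param sample_id sample label for the calls (taken from the profile when
#'   one is supplied).
#' @return A `cnv_calls` data frame: `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `class` ("gain"/"loss"), `n_probes`, `mean_log2`,
#'   sorted by position.
#' @export
call_segments <- function(profile, calibration, probe_map = NULL,
                          sample_id = NULL) {
  stopifnot(inherits(calibration, "noise_calibration"))
  if (inherits(profile, "acgh_profile")) {
    probe_map <- profile$probe_map
    if (is.null(sample_id)) sample_id <- profile$sample_id
    profile <- profile$values
  }
  if (is.null(probe_map)) stop_bad("a probe map is required")
  if (is.null(sample_id)) sample_id <- "sample"
  res <- segment_profile(profile, probe_map, t = calibration$t,
                         min_probes = calibration$min_probes,
                         max_gap_probes = calibration$max_gap_probes)
  res <- cbind(sample_id = rep(sample_id, nrow(res)), res,
               stringsAsFactors = FALSE)
  class(res) <- c("cnv_calls", "data.frame")
  res
}

#' Call CNV segments for every sample of a cohort
#'
#' @param cohort a normalized `acgh_cohort`.
#' @param calibration a [noise_calibration()].
#' @return A `cnv_calls` data frame over all samples.
#' @export
call_cohort <- function(cohort, calibration) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  out <- lapply(seq_len(ncol(cohort$log2)), function(j)
    call_segments(cohort$log2[, j], calibration, cohort$probe_map,
                  cohort$samples$sample_id[j]))
  res <- do.call(rbind, out)
  class(res) <- c("cnv_calls", "data.frame")
  res
}

#' Deduplicate calls into unique CNVs with occurrence counts
#'
#' Two calls are the same CNV when they agree exactly on chromosome, start,
#' end and class (a gain and a loss over the same interval are distinct
#' CNVs). Each unique CNV carries its overall occurrence across samples and
#' its per-line occurrence, mirroring a population CNV catalog.
#'
#' @param calls a `cnv_calls` data frame over all samples.
#' @param line_map named character vector mapping sample_id to line_id, a
#'   `line_catalog`, or a data frame with `sample_id` and `line_id`.
#' @return A `unique_cnvs` data frame: `cnv_id`, `chrom`, `start`, `end`,
#'   `class`, `occurrence_total`, one occurrence column per line, and
#'   `carrier_samples` (comma-separated), sorted by position.
#' @export
collate_calls <- function(calls, line_map) {
  line_map <- as_line_map(line_map)
  miss <- setdiff(unique(calls$sample_id), names(line_map))
  if (length(miss))
    stop_bad("samples absent from the line map: %s", paste(miss, collapse = ", "))
  lines <- unique(unname(line_map))
  if (nrow(calls) == 0) {
    out <- data.frame(cnv_id = character(), chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      occurrence_total = integer(), stringsAsFactors = FALSE)
    for (ln in lines) out[[ln]] <- integer()
    out$carrier_samples <- character()
    class(out) <- c("unique_cnvs", "data.frame")
    return(out)
  }
  key <- paste(calls$chrom, calls$start, calls$end, calls$class, sep = "\r")
  grp <- split(seq_len(nrow(calls)), key)
  first <- vapply(grp, `[`, integer(1), 1L)
  per_line <- t(vapply(grp, function(ix)
    as.integer(table(factor(line_map[calls$sample_id[ix]], levels = lines))),
    integer(length(lines))))
  out <- data.frame(chrom = calls$chrom[first], start = calls$start[first],
                    end = calls$end[first], class = calls$class[first],
                    occurrence_total = lengths(grp), stringsAsFactors = FALSE)
  out[lines] <- as.data.frame(per_line)
  out$carrier_samples <- vapply(grp, function(ix)
    paste(sort(calls$sample_id[ix]), collapse = ","), character(1))
  out <- out[order(chrom_factor(out$chrom), out$start, out$end, out$class), , drop = FALSE]
  out <- cbind(cnv_id = sprintf("CNV%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lines") <- lines
  class(out) <- c("unique_cnvs", "data.frame")
  out
}

# Accepts named vector, data.frame(sample_id, line_id) or line_catalog.
as_line_map <- function(line_map) {
  if (inherits(line_map, "line_catalog")) return(line_map$map)
  if (is.data.frame(line_map)) {
    stopifnot(all(c("sample_id", "line_id") %in% names(line_map)))
    return(stats::setNames(as.character(line_map$line_id),
                           as.character(line_map$sample_id)))
  }
  if (is.null(names(line_map))) stop_bad("line map must be named by sample id")
  stats::setNames(as.character(line_map), names(line_map))
}
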