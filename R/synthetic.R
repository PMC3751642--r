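#' Genome specification
#'
#' A minimal description of the genome the array tiles: chromosome names and
#' lengths. It stands in for an assembly such as galGal3 (chromosomes 1-28,
#' 32, Z and W) in simulations.
#'
#' @param name character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in base pairs (> 0).
#' @return A `genome_spec` data frame with columns `name` and `length`.
#' @examples
#' genome_spec(c("1", "Z"), c(2e6, 1e6))
#' @export
genome_spec <- function(name, length) {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) == 0L) stop_bad("genome must contain at least one chromosome")
  if (anyDuplicated(name)) stop_bad("chromosome names must be unique")
  if (length(name) != base::length(length)) stop_bad("name and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0)) stop_bad("chromosome lengths must be positive")
  structure(data.frame(name = name, length = length, stringsAsFactors = FALSE),
            class = c("genome_spec", "data.frame"))
}

#' Example chicken-like genome for simulations
#'
#' A scaled-down stand-in genome with macro/micro-chromosome size decay plus
#' Z and (optionally) W. Intended for whole-pipeline simulations at desk
#' scale; real assemblies can be supplied through [genome_spec()].
#'
#' @param n_autosomes number of autosomes.
#' @param scale multiplier on all chromosome lengths.
#' @param with_w include a W chromosome.
#' @return A `genome_spec`.
#' @export
example_genome <- function(n_autosomes = 6, scale = 1, with_w = FALSE) {
  stopifnot(n_autosomes >= 1, scale > 0)
  auto_mb <- round(20 * 0.7^(seq_len(n_autosomes) - 1), 2)  # 20, 14, 9.8, ... Mb
  nm <- as.character(seq_len(n_autosomes))
  len <- auto_mb * 1e6
  nm <- c(nm, "Z"); len <- c(len, 8e6)
  if (with_w) { nm <- c(nm, "W"); len <- c(len, 2e6) }
  genome_spec(nm, round(len * scale))
}

#' Build an ordered probe map tiling a genome
#'
#' Probes tile each chromosome from position 1 at a fixed target spacing
#' (median inter-probe distance), optionally with uniform positional jitter,
#' emulating an oligonucleotide CGH array such as a 244K design with ~4 kb
#' median probe spacing. Probe starts are jittered at most
#' `jitter_fraction * spacing_bp` (clamped so probes never overlap).
#'
#' @param genome a [genome_spec()].
#' @param spacing_bp target inter-probe spacing in bp (default 4000).
#' @param jitter_fraction uniform jitter as a fraction of spacing, in [0, 0.5).
#' @param probe_length_bp length of each probe (60-mer by default).
#' @param seed integer seed; the map is deterministic given the seed.
#' @return A `probe_map` data frame with columns `probe_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), carrying `spacing_bp` as an
#'   attribute and the genome as attribute `genome`.
#' @examples
#' pm <- build_probe_map(genome_spec("1", 40000), spacing_bp = 4000)
#' head(pm$start)  # 1, 4001, 8001, ...
#' @export
build_probe_map <- function(genome, spacing_bp = 4000, jitter_fraction = 0,
                            probe_length_bp = 60, seed = 1) {
  if (!inherits(genome, "genome_spec")) genome <- genome_spec(genome$name, genome$length)
  if (nrow(genome) == 0L) stop_bad("genome must contain at least one chromosome")
  stopifnot(spacing_bp > 0, probe_length_bp >= 1)
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop_bad("jitter_fraction must lie in [0, 0.5)")
  # clamp keeps consecutive probes separated by at least probe_length_bp
  max_shift <- min(jitter_fraction * spacing_bp, (spacing_bp - probe_length_bp) / 2)
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genome)), function(i) {
      chrom <- genome$name[i]
      len <- genome$length[i]
      base <- seq(1, max(1, len - probe_length_bp + 1), by = spacing_bp)
      start <- base
      if (max_shift > 0) {
        shift <- round(runif(length(base), -max_shift, max_shift))
        start <- pmin(pmax(base + shift, 1), len - probe_length_bp + 1)
      }
      data.frame(probe_id = sprintf("%s_%06d", chrom, seq_along(start)),
                 chrom = chrom, start = start,
                 end = start + probe_length_bp - 1,
                 stringsAsFactors = FALSE)
    })
    pm <- do.call(rbind, pieces)
    rownames(pm) <- NULL
    structure(pm, spacing_bp = spacing_bp, genome = genome,
              class = c("probe_map", "data.frame"))
  })
}

#' Expected log2 ratio for a copy-number state
#'
#' Dosage model used by the simulator: a segment at `copy_number` copies in
#' the test sample against a diploid reference measures
#' `log2(copy_number / reference_copies)`; a homozygous deletion (0 copies)
#' is floored because real arrays saturate rather than report -Inf.
#'
#' @param copy_number integer copy number(s) >= 0.
#' @param reference_copies copies in the reference (default 2).
#' @param floor value returned for copy number 0 (default -4 log2 units).
#' @return Numeric vector of expected log2 ratios.
#' @examples
#' expected_log2(c(0, 1, 2, 3, 4))
#' @export
expected_log2 <- function(copy_number, reference_copies = 2, floor = -4) {
  stopifnot(reference_copies >= 1)
  if (any(!is.finite(copy_number)) || any(copy_number < 0))
    stop_bad("copy_number must be a non-negative number")
  out <- log2(copy_number / reference_copies)
  out[copy_number == 0] <- floor
  out
}

#' Describe one line of a simulated cohort
#'
#' A line (breed or experimental population) is a set of samples sharing
#' line-fixed CNVs (carried by every sample), line-shared segregating CNVs
#' (carried with probability `shared_cnv_rate` per sample), and private CNVs
#' unique to single samples.
#'
#' @param line_id line name.
#' @param n_samples number of animals sampled from the line (>= 1).
#' @param fixed_cnvs optional data frame of CNV templates (`chrom`, `start`,
#'   `end`, `copy_number`) carried by every sample of the line.
#' @param shared_cnv_rate per-sample carriage probability of each of the
#'   line's segregating CNV templates, in [0, 1].
#' @param private_cnv_rate per-sample, per-candidate probability of a private
#'   CNV, in [0, 1].
#' @param noise_sd per-probe Gaussian noise, log2 units.
#' @return A `line_spec` list.
#' @export
line_spec <- function(line_id, n_samples, fixed_cnvs = NULL,
                      shared_cnv_rate = 0, private_cnv_rate = 0,
                      noise_sd = 0.1) {
  stopifnot(n_samples >= 1, noise_sd >= 0)
  if (shared_cnv_rate < 0 || shared_cnv_rate > 1 ||
      private_cnv_rate < 0 || private_cnv_rate > 1)
    stop_bad("CNV carriage rates must lie in [0, 1]")
  if (!is.null(fixed_cnvs)) {
    fixed_cnvs <- as.data.frame(fixed_cnvs)
    need <- c("chrom", "start", "end", "copy_number")
    if (!all(need %in% names(fixed_cnvs)))
      stop_bad("fixed_cnvs needs columns: %s", paste(need, collapse = ", "))
    if (any(fixed_cnvs$start >= fixed_cnvs$end))
      stop_bad("fixed_cnvs must have start < end")
    if (any(fixed_cnvs$copy_number == 2))
      stop_bad("a CNV template cannot have the reference copy number 2")
  }
  structure(list(line_id = as.character(line_id), n_samples = as.integer(n_samples),
                 fixed_cnvs = fixed_cnvs, shared_cnv_rate = shared_cnv_rate,
                 private_cnv_rate = private_cnv_rate, noise_sd = noise_sd),
            class = "line_spec")
}

#' Study-design line specification mirroring a 15-line, 64-animal cohort
#'
#' Default cohort structure for simulations: 15 lines (Red Jungle Fowl,
#' experimental layer lines, commercial broilers and layers, Silkie) with the
#' per-line sample counts of a typical diversity panel totalling 64 animals.
#' CNV content (fixed / shared / private rates) is set per line so that some
#' lines carry line-specific fixed CNVs.
#'
#' @param noise_sd per-probe noise for every line.
#' @param shared_cnv_rate,private_cnv_rate carriage rates applied to all lines.
#' @return A list of [line_spec()] objects.
#' @export
default_lines <- function(noise_sd = 0.1, shared_cnv_rate = 0.5,
                          private_cnv_rate = 0.1) {
  counts <- c(aviandiv_101 = 4, LineBrL = 5, Line6_1 = 5, Line6_3 = 5,
              LineN = 5, Line15I_5 = 5, Line7_2 = 5, ComBroilA = 2,
              ComBroilB = 3, ComBroilC = 4, BroilM = 8, ComBrownL1 = 4,
              ComBrownL2 = 4, ComWhiteL = 2, Silkie = 3)
  lapply(names(counts), function(nm)
    line_spec(nm, counts[[nm]], shared_cnv_rate = shared_cnv_rate,
              private_cnv_rate = private_cnv_rate, noise_sd = noise_sd))
}

# probes overlapping a 1-based inclusive interval on one chromosome
probes_in_interval <- function(probe_map, chrom, start, end) {
  which(probe_map$chrom == chrom & probe_map$start <= end & probe_map$end >= start)
}

# Random CNV template on the probe map: position chosen uniformly, size in
# probes log-uniform within size_probes, copy number from the loss-biased
# palette (~75% losses, matching aCGH CNV surveys in birds).
random_cnv_template <- function(probe_map, size_probes, copy_weights) {
  n_probes <- sample(seq(size_probes[1], size_probes[2]), 1L)
  i <- sample(nrow(probe_map), 1L)
  chrom <- probe_map$chrom[i]
  idx <- which(probe_map$chrom == chrom)
  pos <- match(i, idx)
  j <- idx[min(pos + n_probes - 1L, length(idx))]
  cn <- as.integer(sample(names(copy_weights), 1L, prob = copy_weights))
  data.frame(chrom = chrom,
             start = max(1, probe_map$start[i] - 500),
             end = probe_map$end[j] + 500,
             copy_number = cn, stringsAsFactors = FALSE)
}

#' Simulate a multi-line aCGH cohort with known implanted CNVs
#'
#' Generates one log2(test/reference) profile per sample over a probe map.
#' Probes inside a sample's true CNV are shifted by [expected_log2()] of its
#' copy number; everything else is centred at 0 with i.i.d. Gaussian noise at
#' the line's `noise_sd` (optionally AR(1)-correlated "waves"). A smooth
#' covariate-dependent dye-bias trend can be added per array to exercise
#' normalization. The ground-truth CNV table is returned alongside.
#'
#' @param probe_map a [build_probe_map()] result.
#' @param lines list of [line_spec()] objects.
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_shared_templates segregating CNV templates drawn per line.
#' @param n_private_templates private CNV candidates per sample.
#' @param size_probes integer range (min, max) of random CNV sizes in probes.
#' @param copy_weights sampling weights for random CNV copy numbers, named by
#'   copy number. The default puts 75% of its mass on losses.
#' @param dye_bias_amplitude log2 amplitude of the per-array smooth intensity
#'   trend (0 disables it).
#' @param wave_ar1 AR(1) coefficient of the noise (0 = independent probes).
#' @param sex_mismatched_reference if TRUE, W probes of female samples are
#'   shifted to the saturation level (+4) as against a male reference; by
#'   default the reference is matched-sex and W probes are pure noise.
#' @return An `acgh_cohort`: list with `probe_map`, `log2` (probes x samples
#'   matrix), `samples` (sample_id, line_id, sex), `covariate` (per-probe
#'   intensity proxy) and `truth` (sample_id, chrom, start, end,
#'   copy_number).
#' @export
simulate_cohort <- function(probe_map, lines, seed = 1,
                            n_shared_templates = 8, n_private_templates = 8,
                            size_probes = c(3, 20),
                            copy_weights = c("0" = 0.15, "1" = 0.60,
                                             "3" = 0.20, "4" = 0.05),
                            dye_bias_amplitude = 0, wave_ar1 = 0,
                            sex_mismatched_reference = FALSE) {
  stopifnot(inherits(probe_map, "data.frame"), length(lines) >= 1)
  if (inherits(lines, "line_spec")) lines <- list(lines)
  genome <- attr(probe_map, "genome")
  check_template <- function(tpl, line_id) {
    if (is.null(tpl) || nrow(tpl) == 0L) return(invisible())
    bad <- !(tpl$chrom %in% probe_map$chrom)
    if (any(bad))
      stop_bad("line %s: CNV template on chromosome '%s' absent from probe map",
               line_id, tpl$chrom[which(bad)[1]])
    if (!is.null(genome)) {
      len <- genome$length[match(tpl$chrom, genome$name)]
      if (any(tpl$end > len))
        stop_bad("line %s: CNV template exceeds chromosome length", line_id)
    }
  }
  for (ln in lines) check_template(ln$fixed_cnvs, ln$line_id)

  n_probes <- nrow(probe_map)
  with_seed(seed, {
    covariate <- rnorm(n_probes, mean = 10, sd = 1)  # probe intensity proxy
    zcov <- as.numeric(scale(covariate))
    shared <- lapply(lines, function(ln) {
      if (ln$shared_cnv_rate > 0 && n_shared_templates > 0)
        do.call(rbind, replicate(n_shared_templates, simplify = FALSE,
                                 random_cnv_template(probe_map, size_probes, copy_weights)))
    })
    sample_rows <- list(); truth_rows <- list(); value_cols <- list()
    for (li in seq_along(lines)) {
      ln <- lines[[li]]
      for (si in seq_len(ln$n_samples)) {
        sid <- sprintf("%s_%02d", ln$line_id, si)
        sex <- if (si %% 2L == 1L) "F" else "M"
        tpl <- ln$fixed_cnvs
        if (!is.null(shared[[li]])) {
          take <- runif(nrow(shared[[li]])) < ln$shared_cnv_rate
          tpl <- rbind(tpl, shared[[li]][take, , drop = FALSE])
        }
        n_priv <- rbinom(1L, n_private_templates, ln$private_cnv_rate)
        if (n_priv > 0)
          tpl <- rbind(tpl, do.call(rbind, replicate(n_priv, simplify = FALSE,
                       random_cnv_template(probe_map, size_probes, copy_weights))))
        if (!is.null(tpl) && nrow(tpl) > 1L) {
          # resolve random-template collisions; conflicting user templates error
          tpl <- resolve_truth_overlaps(tpl, n_fixed = NROW(ln$fixed_cnvs),
                                        line_id = ln$line_id)
        }
        v <- rnorm(n_probes, 0, ln$noise_sd)
        if (wave_ar1 > 0 && ln$noise_sd > 0) {
          innov_sd <- ln$noise_sd * sqrt(1 - wave_ar1^2)
          v <- as.numeric(stats::filter(rnorm(n_probes, 0, innov_sd),
                                        wave_ar1, method = "recursive"))
        }
        if (!is.null(tpl) && nrow(tpl) > 0L) {
          for (k in seq_len(nrow(tpl))) {
            idx <- probes_in_interval(probe_map, tpl$chrom[k], tpl$start[k], tpl$end[k])
            v[idx] <- v[idx] + expected_log2(tpl$copy_number[k])
          }
          truth_rows[[length(truth_rows) + 1L]] <-
            data.frame(sample_id = sid, tpl, stringsAsFactors = FALSE)
        }
        if (sex_mismatched_reference && sex == "F") {
          widx <- which(probe_map$chrom %in% c("W", "chrW", "GGAW"))
          v[widx] <- v[widx] + 4
        }
        if (dye_bias_amplitude > 0) {
          c1 <- runif(1, -1, 1); c2 <- runif(1, -1, 1)
          v <- v + dye_bias_amplitude * (c1 * zcov + c2 * (zcov^2 - 1))
        }
        sample_rows[[length(sample_rows) + 1L]] <-
          data.frame(sample_id = sid, line_id = ln$line_id, sex = sex,
                     stringsAsFactors = FALSE)
        value_cols[[sid]] <- v
      }
    }
    samples <- do.call(rbind, sample_rows)
    log2m <- do.call(cbind, value_cols)
    rownames(log2m) <- probe_map$probe_id
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
             else data.frame(sample_id = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             copy_number = integer(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    structure(list(probe_map = probe_map, log2 = log2m, samples = samples,
                   covariate = covariate, truth = truth, seed = seed),
              class = "acgh_cohort")
  })
}

# Drop random templates that collide with an earlier template of the same
# sample at a different copy number; conflicting *fixed* templates error.
resolve_truth_overlaps <- function(tpl, n_fixed, line_id) {
  keep <- rep(TRUE, nrow(tpl))
  for (k in seq_len(nrow(tpl))[-1]) {
    prev <- which(keep[seq_len(k - 1L)])
    clash <- prev[tpl$chrom[prev] == tpl$chrom[k] &
                  tpl$start[prev] <= tpl$end[k] & tpl$end[prev] >= tpl$start[k]]
    clash <- clash[tpl$copy_number[clash] != tpl$copy_number[k]]
    if (length(clash)) {
      if (k <= n_fixed)
        stop_bad("line %s: overlapping fixed CNV templates with conflicting copy numbers",
                 line_id)
      keep[k] <- FALSE
    }
  }
  tpl[keep, , drop = FALSE]
}

#' Simulate self-self replicate hybridizations
#'
#' A self-self array hybridizes the reference DNA against itself, so the
#' profile is pure technical noise around 0 with no CNVs. These arrays
#' calibrate the calling threshold (see [calibrate_threshold()]).
#'
#' @inheritParams simulate_cohort
#' @param noise_sd per-probe noise, log2 units (>= 0).
#' @param n_arrays number of replicate arrays (>= 1).
#' @return An `acgh_cohort` whose `truth` table is empty.
#' @export
simulate_self_self <- function(probe_map, noise_sd = 0.1, n_arrays = 3,
                               seed = 1, dye_bias_amplitude = 0) {
  if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
  stopifnot(n_arrays >= 1)
  ln <- line_spec("selfself", n_arrays, noise_sd = noise_sd)
  simulate_cohort(probe_map, list(ln), seed = seed,
                  n_shared_templates = 0, n_private_templates = 0,
                  dye_bias_amplitude = dye_bias_amplitude)
}

#' @export
print.acgh_cohort <- function(x, ...) {
  cat(sprintf("aCGH cohort: %d samples x %d probes, %d lines, %d truth CNVs\n",
              ncol(x$log2), nrow(x$log2), length(unique(x$samples$line_id)),
              nrow(x$truth)))
  invisible(x)
}

#' Extract one sample's profile from a cohort
#'
#' @param cohort an `acgh_cohort`.
#' @param sample sample id or column index.
#' @return List with `sample_id`, `line_id`, `values`, `covariate`,
#'   `probe_map` (an `acgh_profile`).
#' @export
get_profile <- function(cohort, sample) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  j <- if (is.character(sample)) match(sample, cohort$samples$sample_id) else sample
  if (is.na(j) || j < 1 || j > ncol(cohort$log2)) stop_bad("unknown sample '%s'", sample)
  structure(list(sample_id = cohort$samples$sample_id[j],
                 line_id = cohort$samples$line_id[j],
                 values = cohort$log2[, j], covariate = cohort$covariate,
                 probe_map = cohort$probe_map),
            class = "acgh_profile")
}
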