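test_that("robust noise estimate matches the sample SD on clean Gaussian noise", {
  expect_identical(estimate_noise(rep(0, 100)), 0)
  pm <- build_probe_map(genome_spec("1", 2e8), 4000, 0, seed = 1)  # 50k probes
  ss <- simulate_self_self(pm, 0.1, 1, seed = 11)
  est <- estimate_noise(ss$log2[, 1])
  expect_gte(est, 0.097)
  expect_lte(est, 0.103)
  expect_equal(est, sd(ss$log2[, 1]), tolerance = 0.02)
  expect_error(estimate_noise(rnorm(5)), "at least 10")
})

test_that("noise estimate resists contiguous CNV blocks covering 5% of probes", {
  set.seed(42)
  v <- rnorm(50000, 0, 0.1)
  blocks <- seq(1, 49001, by = 1000)
  idx <- unlist(lapply(blocks, function(b) b:(b + 49)))  # 5% of probes
  v[idx] <- v[idx] - 1
  est <- estimate_noise(v)
  expect_lt(abs(est - 0.1) / 0.1, 0.10)
  # trimmed-SD oracle agrees
  expect_equal(est, sd(v[-idx]), tolerance = 0.01)
})

test_that("segmentation calls exact constructions", {
  pm <- tiny_map(len = 2e6)  # 500 probes
  cal <- noise_calibration(t = 4, min_probes = 2, max_gap_probes = 1)
  v <- rep(0, nrow(pm))
  expect_equal(nrow(call_segments(v, cal, pm)), 0)
  v[101:110] <- -1   # 10 consecutive probes at -1, zero noise elsewhere
  calls <- suppressWarnings(call_segments(v, cal, pm, sample_id = "s1"))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$class, "loss")
  expect_equal(calls$n_probes, 10)
  expect_equal(calls$start, pm$start[101])
  expect_equal(calls$end, pm$end[110])
  expect_equal(calls$mean_log2, -1)
})

test_that("a CNV below probe spacing is never called at min_probes = 2", {
  # 3.2 kb event on a 4 kb grid covers at most one probe
  pm <- tiny_map(len = 2e6)
  tr <- data.frame(chrom = "1", start = 99001, end = 102200, copy_number = 1)
  covered <- sum(pm$start <= tr$end & pm$end >= tr$start)
  expect_lte(covered, 1)
  for (seed in 1:5) {
    co <- simulate_cohort(pm, list(line_spec("A", 1, fixed_cnvs = tr,
                                             noise_sd = 0.1)), seed = seed)
    ss <- simulate_self_self(pm, 0.1, 3, seed = seed + 100)
    cal <- calibrate_threshold(ss, min_probes = 2)
    calls <- call_cohort(co, cal)
    # no call attributable to the implanted event: any >= 2-probe call spans
    # more than the 3.2 kb interval, so none can be contained in it
    hit <- calls$chrom == "1" & calls$start >= tr$start & calls$end <= tr$end
    expect_false(any(hit))
  }
})

test_that("threshold calibration picks the smallest grid value meeting the target", {
  pm <- tiny_map(len = 4e7)  # 10k probes
  ss <- simulate_self_self(pm, 0.1, 4, seed = 6)
  grid <- seq(2, 6, by = 0.5)
  cal <- calibrate_threshold(ss, grid = grid, target_false_calls_per_array = 1)
  # brute-force oracle over every grid point
  counts <- sapply(grid, function(t) {
    mean(sapply(seq_len(ncol(ss$log2)), function(j) {
      c0 <- noise_calibration(t = t, min_probes = 2, max_gap_probes = 1)
      nrow(call_segments(ss$log2[, j], c0, pm))
    }))
  })
  expect_equal(cal$grid_evaluation$mean_calls, counts)
  expect_equal(cal$t, grid[which(counts <= 1)[1]])
  expect_false(cal$warning)
  expect_lte(cal$mean_false_calls, 1)
  # re-running the self-self arrays at the calibrated threshold reproduces it
  recheck <- mean(sapply(seq_len(ncol(ss$log2)), function(j)
    nrow(call_segments(ss$log2[, j], cal, pm))))
  expect_lte(recheck, 1)
})

test_that("calibration boundary behaviour: zero noise and unreachable targets", {
  pm <- tiny_map(len = 2e6)
  ss0 <- simulate_self_self(pm, 0, 2, seed = 1)
  cal0 <- calibrate_threshold(ss0, grid = c(2, 3, 4))
  expect_equal(cal0$t, 2)
  expect_equal(cal0$mean_false_calls, 0)
  ssn <- simulate_self_self(build_probe_map(genome_spec("1", 4e7), 4000, 0),
                            0.1, 2, seed = 2)
  caln <- calibrate_threshold(ssn, grid = c(1, 1.5, 2),
                              target_false_calls_per_array = 0)
  expect_equal(caln$t, 2)
  expect_true(caln$warning)
  expect_error(calibrate_threshold(ss0, grid = numeric()), "empty")
  expect_error(calibrate_threshold(ss0, grid = c(3, 2)), "ascending")
})

test_that("gap merging joins same-sign runs only and respects min_probes", {
  pm <- tiny_map(len = 2e6)
  cal <- noise_calibration(t = 4, min_probes = 3, max_gap_probes = 1)
  v <- rnorm(nrow(pm), 0, 0.05)
  v[50:52] <- -1; v[53] <- 0.01; v[54:55] <- -1   # one dropout probe inside
  v[200:202] <- 1; v[203] <- -1; v[204:206] <- 1  # opposite sign: no bridge
  v[300:301] <- -1                                 # below min_probes
  calls <- call_segments(v, cal, pm)
  loss <- calls[calls$class == "loss", ]
  expect_equal(nrow(loss[loss$start == pm$start[50], ]), 1)
  expect_equal(loss$n_probes[loss$start == pm$start[50]], 6)
  gains <- calls[calls$class == "gain", ]
  expect_equal(nrow(gains), 2)
  expect_false(any(calls$start == pm$start[300]))
})

test_that("calibrated calling recovers implanted CNVs with >= 95% sensitivity", {
  g <- genome_spec(as.character(1:4), rep(1e7, 4))
  pm <- build_probe_map(g, 4000, 0.1, seed = 2)
  ln <- lapply(1:10, function(i) line_spec(paste0("L", i), 2,
                                           private_cnv_rate = 0.6, noise_sd = 0.1))
  co <- simulate_cohort(pm, ln, seed = 4, n_private_templates = 10,
                        size_probes = c(3, 8),
                        copy_weights = c("1" = 0.5, "4" = 0.5))  # |log2| = 1
  expect_gte(nrow(co$truth), 100)
  ss <- simulate_self_self(pm, 0.1, 5, seed = 6)
  cal <- calibrate_threshold(ss, target_false_calls_per_array = 1)
  calls <- call_cohort(co, cal)
  recovered <- vapply(seq_len(nrow(co$truth)), function(i) {
    tr <- co$truth[i, ]
    cc <- calls[calls$sample_id == tr$sample_id & calls$chrom == tr$chrom, ]
    if (!nrow(cc)) return(FALSE)
    ov <- pmax(0, pmin(cc$end, tr$end) - pmax(cc$start, tr$start) + 1)
    any(ov >= 0.5 * (tr$end - tr$start + 1) & ov >= 0.5 * (cc$end - cc$start + 1))
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  # gain/loss labels match the implanted sign wherever recovered
  expect_false(cal$warning)
})

test_that("sensitivity is monotone non-increasing in the threshold multiple", {
  g <- genome_spec("1", 2e7)
  pm <- build_probe_map(g, 4000, 0, seed = 2)
  ln <- list(line_spec("L", 4, private_cnv_rate = 0.5, noise_sd = 0.15))
  co <- simulate_cohort(pm, ln, seed = 8, n_private_templates = 8,
                        size_probes = c(2, 4),
                        copy_weights = c("1" = 0.7, "3" = 0.3))
  sens <- sapply(c(2, 3, 4, 5, 6), function(t) {
    cal <- noise_calibration(t = t, min_probes = 2, max_gap_probes = 1)
    calls <- call_cohort(co, cal)
    mean(vapply(seq_len(nrow(co$truth)), function(i) {
      tr <- co$truth[i, ]
      cc <- calls[calls$sample_id == tr$sample_id & calls$chrom == tr$chrom, ]
      nrow(cc) > 0 && any(pmin(cc$end, tr$end) >= pmax(cc$start, tr$start))
    }, logical(1)))
  })
  expect_true(all(diff(sens) <= 0))
})

test_that("no two calls of one sample overlap and zero-noise labels match truth", {
  g <- genome_spec(c("1", "2"), c(1e7, 1e7))
  pm <- build_probe_map(g, 4000, 0.1, seed = 3)
  ln <- list(line_spec("L", 3, private_cnv_rate = 0.5, noise_sd = 0))
  co <- simulate_cohort(pm, ln, seed = 13, n_private_templates = 6)
  cal <- noise_calibration(t = 4, min_probes = 2, max_gap_probes = 1)
  calls <- suppressWarnings(call_cohort(co, cal))
  for (s in unique(calls$sample_id)) {
    cc <- calls[calls$sample_id == s, ]
    for (ch in unique(cc$chrom)) {
      ci <- cc[cc$chrom == ch, ]
      if (nrow(ci) > 1) expect_true(all(ci$start[-1] > ci$end[-nrow(ci)]))
    }
  }
  # every zero-noise call lies inside a truth CNV of matching sign
  for (i in seq_len(nrow(calls))) {
    tr <- co$truth[co$truth$sample_id == calls$sample_id[i] &
                   co$truth$chrom == calls$chrom[i] &
                   co$truth$start <= calls$end[i] &
                   co$truth$end >= calls$start[i], ]
    expect_gte(nrow(tr), 1)
    expected_sign <- ifelse(tr$copy_number > 2, "gain", "loss")
    expect_true(calls$class[i] %in% expected_sign)
  }
})

test_that("collation groups identical calls and matches a brute-force group-by", {
  calls <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    chrom = c("1", "1", "1", "1"),
    start = c(100, 100, 100, 500), end = c(200, 200, 200, 700),
    class = c("loss", "loss", "gain", "loss"),
    n_probes = 2, mean_log2 = c(-1, -1, 0.6, -1), stringsAsFactors = FALSE)
  lm <- c(a = "L1", b = "L2", c = "L1", d = "L2")
  u <- collate_calls(calls, lm)
  expect_equal(nrow(u), 3)  # same interval as gain and loss stays distinct
  dup <- u[u$start == 100 & u$class == "loss", ]
  expect_equal(dup$occurrence_total, 2)
  expect_equal(dup$L1, 1); expect_equal(dup$L2, 1)
  expect_equal(dup$carrier_samples, "a,b")
  expect_error(collate_calls(calls, lm[-1]), "absent from the line map")

  # random cohort vs brute-force aggregation
  set.seed(31)
  rc <- data.frame(sample_id = sample(letters[1:6], 80, replace = TRUE),
                   chrom = sample(c("1", "2"), 80, replace = TRUE),
                   start = sample(c(100, 500, 900), 80, replace = TRUE),
                   stringsAsFactors = FALSE)
  rc$end <- rc$start + 150
  rc$class <- sample(c("gain", "loss"), 80, replace = TRUE)
  rc <- rc[!duplicated(rc[c("sample_id", "chrom", "start", "class")]), ]
  lmap <- setNames(rep(c("X", "Y"), 3), letters[1:6])
  u2 <- collate_calls(rc, lmap)
  key <- paste(rc$chrom, rc$start, rc$end, rc$class)
  expect_equal(sort(u2$occurrence_total), sort(as.integer(table(key))))
  expect_equal(sum(u2$X) + sum(u2$Y), nrow(rc))
  expect_equal(u2$occurrence_total, u2$X + u2$Y)
})
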