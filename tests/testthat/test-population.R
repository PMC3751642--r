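mk_regions <- function(start, end, chrom = "1") {
  df <- data.frame(cnvr_id = sprintf("CNVR%04d", seq_along(start)),
                   chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(df) <- c("cnvr_catalog", "data.frame")
  df
}

mk_calls <- function(sample_id, chrom, start, end, class) {
  data.frame(sample_id = sample_id, chrom = as.character(chrom), start = start,
             end = end, class = class, stringsAsFactors = FALSE)
}

test_that("occurrence matrix reports carrier state per sample and region", {
  lc <- line_catalog(c(s1 = "A", s2 = "A", s3 = "B"))
  rg <- mk_regions(c(1000, 5000), c(2000, 6000))
  calls <- mk_calls(c("s1", "s3"), "1", c(1100, 5100), c(1900, 5900),
                    c("loss", "gain"))
  m <- occurrence_matrix(rg, calls, lc)
  expect_equal(m["s1", "CNVR0001"], "loss")
  expect_equal(m["s3", "CNVR0002"], "gain")
  expect_equal(m["s2", "CNVR0001"], "none")
  expect_equal(dim(m), c(3, 2))
  expect_error(occurrence_matrix(rg, mk_calls("zz", "1", 1, 10, "loss"), lc),
               "not in the line catalog")
})

test_that("conflicting classes in one region resolve to the largest overlap", {
  lc <- line_catalog(c(s1 = "A", s2 = "A"))
  rg <- mk_regions(1000, 9000)
  calls <- mk_calls(c("s1", "s1"), "1", c(1000, 6000), c(3000, 8950),
                    c("loss", "gain"))
  m <- occurrence_matrix(rg, calls, lc)
  expect_equal(m["s1", "CNVR0001"], "gain")  # 2951 bp beats 2001 bp
})

test_that("occurrence matrix equals a brute-force interval lookup", {
  set.seed(61)
  lc <- line_catalog(setNames(rep(c("A", "B"), 4), paste0("s", 1:8)))
  rg <- mk_regions(seq(1000, 46000, by = 5000), seq(3000, 48000, by = 5000))
  n <- 60
  calls <- mk_calls(sample(paste0("s", 1:8), n, TRUE), "1",
                    start <- sample(5e4, n, TRUE), start + sample(3000, n, TRUE),
                    sample(c("gain", "loss"), n, TRUE))
  # drop within-sample overlapping calls to match caller output structure
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) if (keep[i]) {
    o <- which(keep & seq_len(n) != i & calls$sample_id == calls$sample_id[i] &
               calls$start <= calls$end[i] & calls$end >= calls$start[i])
    keep[o[o > i]] <- FALSE
  }
  calls <- calls[keep, ]
  m <- occurrence_matrix(rg, calls, lc)
  for (s in rownames(m)) for (j in seq_len(nrow(rg))) {
    cc <- calls[calls$sample_id == s &
                calls$start <= rg$end[j] & calls$end >= rg$start[j], ]
    want <- if (!nrow(cc)) "none" else {
      ov <- pmin(cc$end, rg$end[j]) - pmax(cc$start, rg$start[j]) + 1
      cc$class[which.max(ov)]
    }
    expect_equal(m[s, rg$cnvr_id[j]], want)
  }
})

test_that("fixation and line-specificity follow their definitions", {
  lc <- line_catalog(setNames(c("Silkie", "Silkie", "Silkie", "L2", "L2"),
                              paste0("s", 1:5)))
  m <- matrix("none", 5, 3, dimnames = list(paste0("s", 1:5),
                                            paste0("R", 1:3)))
  m[1:3, 1] <- "loss"                 # fixed in Silkie only, absent elsewhere
  m[1:5, 2] <- "gain"                 # fixed in both lines
  m[c(1:3, 4), 3] <- "loss"           # fixed in Silkie, sporadic carrier in L2
  cl <- classify_regions(m, lc)
  expect_true(cl$is_fixed[1]); expect_true(cl$is_line_specific[1])
  expect_equal(cl$specific_line[1], "Silkie")
  expect_true(cl$is_fixed[2]); expect_false(cl$is_line_specific[2])
  expect_equal(cl$fixed_lines[2], "L2,Silkie")
  expect_false(cl$is_line_specific[3])   # strict mode
  cl_len <- classify_regions(m, lc, lenient = TRUE)
  expect_true(cl_len$is_line_specific[3])
})

test_that("classification matches the exhaustive oracle and ignores sample order", {
  set.seed(62)
  for (rep in 1:10) {
    n_s <- 9
    line_of <- setNames(sample(c("A", "B", "C"), n_s, TRUE), paste0("s", 1:n_s))
    while (length(unique(line_of)) < 3)
      line_of <- setNames(sample(c("A", "B", "C"), n_s, TRUE), paste0("s", 1:n_s))
    lc <- line_catalog(line_of)
    m <- matrix(sample(c("none", "gain", "loss"), n_s * 12, TRUE,
                       prob = c(0.55, 0.15, 0.3)), n_s, 12,
                dimnames = list(names(line_of), sprintf("R%02d", 1:12)))
    cl <- classify_regions(m, lc)
    want <- oracle_classify(m, line_of)
    expect_equal(cl$is_fixed, unname(want[, "is_fixed"]))
    expect_equal(cl$is_line_specific, unname(want[, "is_line_specific"]))
    # permuting samples leaves the classification unchanged
    perm <- sample(n_s)
    cl2 <- classify_regions(m[perm, , drop = FALSE], lc)
    expect_equal(cl2, cl)
    # count identities
    expect_lte(sum(cl$is_line_specific), sum(cl$is_fixed))
    expect_lte(sum(cl$is_fixed), nrow(cl))
  }
})

test_that("implanted line-fixed CNVs classify as fixed at zero noise", {
  pm <- tiny_map(len = 1e6)
  fx <- function(s) data.frame(chrom = "1", start = s, end = s + 60000,
                               copy_number = 1)
  ln <- list(line_spec("A", 3, fixed_cnvs = fx(100001), noise_sd = 0),
             line_spec("B", 2, fixed_cnvs = fx(500001), noise_sd = 0))
  co <- simulate_cohort(pm, ln, seed = 5)
  cal <- noise_calibration(t = 4, min_probes = 2, max_gap_probes = 1)
  calls <- suppressWarnings(call_cohort(co, cal))
  lc <- line_catalog(co$samples)
  cn <- collate_calls(calls, lc)
  rg <- merge_to_cnvrs(cn)
  cl <- classify_regions(occurrence_matrix(rg, calls, lc), lc)
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$is_fixed))
  expect_setequal(cl$specific_line, c("A", "B"))
})

test_that("identical samples merge at distance zero; Jaccard matches the oracle", {
  m <- matrix(c("loss", "loss", "none",
                "loss", "loss", "none",
                "gain", "none", "gain"), 3, 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), paste0("R", 1:3)))
  cl <- cluster_samples(m, k = 2)
  dm <- as.matrix(cl$dist)
  expect_equal(dm["x", "y"], 0)
  expect_equal(cl$assignments[["x"]], cl$assignments[["y"]])
  expect_false(cl$assignments[["x"]] == cl$assignments[["z"]])
  want <- oracle_jaccard((m != "none") + 0L)
  expect_equal(dm, want)
  # all-identical samples: a star at height 0
  m0 <- m[c(1, 1, 1), ]; rownames(m0) <- c("a", "b", "c")
  cl0 <- cluster_samples(m0)
  expect_true(all(cl0$hclust$height == 0))
})

test_that("clustering recovers synthetic line structure exactly under strong signal", {
  skip_if_not_installed("mclust")
  pm <- build_probe_map(genome_spec("1", 2e7), 4000, 0)
  mk <- function(i) data.frame(chrom = "1",
                               start = ((i - 1) * 4 + 0:3) * 1e6 + 1,
                               end = ((i - 1) * 4 + 0:3) * 1e6 + 1e5,
                               copy_number = 1)
  ln <- lapply(1:5, function(i) line_spec(paste0("L", i), 3, fixed_cnvs = mk(i),
                                          noise_sd = 0.1))
  co <- simulate_cohort(pm, ln, seed = 7)
  ss <- simulate_self_self(pm, 0.1, 3, seed = 8)
  cal <- calibrate_threshold(ss)
  calls <- call_cohort(co, cal)
  lc <- line_catalog(co$samples)
  rg <- merge_to_cnvrs(collate_calls(calls, lc))
  m <- occurrence_matrix(rg, calls, lc)
  cl <- cluster_samples(m, k = 5)
  truth_line <- lc$map[names(cl$assignments)]
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth_line), 1.0)
})

test_that("dendrograms export as Newick trees", {
  m <- matrix(sample(c("none", "loss"), 20, TRUE), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("R", 1:5)))
  cl <- cluster_samples(m)
  f <- tempfile(fileext = ".nwk")
  write_newick(cl, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, paste0("s", 1:4))
})
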