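test_that("total intensity and log ratios follow their definitions", {
  expect_equal(total_intensity(matrix(3), matrix(4)), matrix(7))
  expect_equal(total_intensity(matrix(0, 2, 2), matrix(0, 2, 2)),
               matrix(0, 2, 2))
  set.seed(71)
  a <- matrix(rexp(20), 4, 5)
  b <- matrix(rexp(20), 4, 5)
  expect_equal(total_intensity(a, b), a + b)
  expect_error(total_intensity(a, b[, 1:3]), "shape")

  lr <- log_ratio(c(2, 1, 4), c(2, 2, 2))
  expect_equal(lr$r, c(0, log10(0.5), log10(2)))
  expect_warning(lr0 <- log_ratio(c(1, 1), c(1, 0)), "non-positive")
  expect_identical(lr0$keep, c(TRUE, FALSE))
})

test_that("quantile normalization equals the sort/mean/unsort oracle", {
  set.seed(72)
  x <- matrix(rnorm(15), 5, 3)
  qn <- quantile_normalize(x)
  target <- rowMeans(apply(x, 2, sort))
  oracle <- apply(x, 2, function(col) target[rank(col)])
  expect_equal(qn, oracle, tolerance = 1e-12)
  # identical columns are a fixed point
  y <- matrix(rep(rnorm(6), 3), 6, 3)
  expect_equal(quantile_normalize(y), y, tolerance = 1e-12)
  # defining property: identical sorted columns afterwards
  z <- quantile_normalize(matrix(rnorm(40), 10, 4))
  s <- apply(z, 2, sort)
  expect_lt(max(abs(s - s[, 1])), 1e-12)
})

test_that("a noiseless step splits exactly at the oracle breakpoint", {
  r <- c(rep(0, 100), rep(-0.3, 100))
  pos <- seq_len(200) * 1000
  segs <- segment_cnv(r, pos, alpha = 0.01, n_perm = 500, seed = 73,
                      smooth_window = 1)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$end_idx[1], 100L)
  expect_equal(segs$mean_log_ratio, c(0, -0.3))
  # brute-force maximal-split oracle agrees on the breakpoint
  stats <- vapply(1:199, function(i) {
    abs(mean(r[1:i]) - mean(r[(i + 1):200])) / sqrt(1 / i + 1 / (200 - i))
  }, numeric(1))
  expect_identical(which.max(stats), 100L)
})

test_that("pure noise stays a single segment and is seed-deterministic", {
  set.seed(74)
  ok <- 0
  for (s in 1:5) {
    r <- rnorm(200, 0, 0.05)
    segs <- segment_cnv(r, seq_len(200) * 1000, alpha = 0.01, n_perm = 500,
                        seed = s)
    if (nrow(segs) == 1) ok <- ok + 1
  }
  expect_gte(ok, 4)
  r <- rnorm(300, 0, 0.05)
  r[101:200] <- r[101:200] - 0.3
  a <- segment_cnv(r, seq_len(300) * 1000, n_perm = 300, seed = 75)
  b <- segment_cnv(r, seq_len(300) * 1000, n_perm = 300, seed = 75)
  expect_identical(a, b)
  # partition invariant: every probe in exactly one segment
  expect_identical(sum(a$n_probes), 300L)
  expect_identical(a$start_idx[1], 1L)
  expect_identical(a$end_idx[nrow(a)], 300L)
  if (nrow(a) > 1)
    expect_identical(a$start_idx[-1], a$end_idx[-nrow(a)] + 1L)
  # piecewise fit beats the single-mean fit
  fitted <- rep(a$mean_log_ratio, a$n_probes)
  expect_lte(sum((r - fitted)^2), sum((r - mean(r))^2))
})

test_that("segment merging joins near-equal neighbours to a fixed point", {
  segs <- data.frame(chrom = "chr1", start = c(1, 101, 201),
                     end = c(100, 200, 300), n_probes = c(10, 10, 20),
                     mean_log_ratio = c(-0.28, -0.25, 0.1),
                     start_idx = c(1, 11, 21), end_idx = c(10, 20, 40))
  m <- merge_segments(segs)
  expect_identical(nrow(m), 2L)
  expect_equal(m$mean_log_ratio[1], -0.265)
  expect_identical(m$n_probes[1], 20)
  sep <- data.frame(chrom = "chr1", start = c(1, 101), end = c(100, 200),
                    n_probes = c(10, 10), mean_log_ratio = c(0, -0.3),
                    start_idx = c(1, 11), end_idx = c(10, 20))
  expect_identical(nrow(merge_segments(sep)), 2L)
  expect_identical(nrow(merge_segments(sep[1, ])), 1L)
})

test_that("deletion calls respect threshold, size and sign", {
  segs <- data.frame(chrom = "chr1",
                     start = c(1, 1001, 5001), end = c(1000, 5000, 9000),
                     n_probes = c(50, 100, 50),
                     mean_log_ratio = c(0.0, -0.3, 0.18),
                     start_idx = c(1, 51, 151), end_idx = c(50, 150, 200))
  dels <- call_deletions(segs)
  expect_length(dels, 1)
  expect_equal(dels[[1]]$start, 1001)
  expect_equal(dels[[1]]$end, 5000)
  expect_length(call_deletions(segs[c(1, 3), ]), 0)  # neutral + gain only
  small <- segs[2, ]; small$n_probes <- 3
  expect_length(call_deletions(small), 0)
})

test_that("a planted half-intensity deletion is recovered end to end", {
  man <- make_probe_manifest(2000, c(chr1 = 2000), seed = 76, spacing = 1000)
  ds <- simulate_cohort(man, cohort_design(n_cases = 2, n_controls = 10,
                                           n_signal_probes = 0, seed = 77))
  iv <- genomic_interval("chr1", man$pos[500], man$pos[699], "truth")
  ds <- plant_deletion(ds, "case_01", iv, 0.5)
  cnv <- cnv_pipeline(ds, "case_01", alpha = 0.01, n_perm = 500, seed = 78)
  expect_length(cnv$deletions, 1)
  called <- cnv$deletions[[1]]
  expect_gte(reciprocal_overlap(called, iv), 0.95)
})

test_that("critical-region mapping reproduces the published 22q13 region", {
  pos <- phelan_deletion_intervals("large_del")
  neg <- phelan_deletion_intervals("small_del")
  expect_length(pos, 11)
  expect_length(neg, 5)
  cr <- critical_region(pos, neg)
  expect_length(cr, 1)
  expect_identical(cr[[1]]$chrom, "chr22")
  expect_identical(cr[[1]]$start, 49238268)
  expect_identical(cr[[1]]$end, 50248907)

  # order-invariance and idempotence under duplication
  cr2 <- critical_region(rev(pos), c(neg[3:5], neg, neg[1:2]))
  expect_identical(cr2[[1]]$start, cr[[1]]$start)
  expect_identical(cr2[[1]]$end, cr[[1]]$end)

  # no negatives: plain intersection of the positives
  cr3 <- critical_region(pos)
  expect_identical(cr3[[1]]$start, 49238268)
  expect_identical(cr3[[1]]$end, 51214353)

  # negatives covering the intersection empty the region
  cover <- list(genomic_interval("chr22", 49e6, 52e6))
  expect_length(critical_region(pos, cover), 0)

  disjoint <- list(genomic_interval("chr22", 1, 10),
                   genomic_interval("chr22", 100, 200))
  expect_warning(empty <- critical_region(disjoint), "disjoint")
  expect_length(empty, 0)
})

test_that("interval lengths reproduce the published megabase values", {
  df <- phelan_deletions()
  # every printed length equals the recomputed (end-start)/1e6, half-up
  for (i in seq_len(nrow(df))) {
    iv <- genomic_interval(df$chrom[i], df$start[i], df$end[i])
    dec <- nchar(sub("^[0-9]+\\.?", "", as.character(df$length_mb[i])))
    expect_equal(interval_length_mb(iv, max(dec, 2)), df$length_mb[i])
  }
  expect_equal(interval_length_mb(genomic_interval("chr1", 5, 5)), 0)
})
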