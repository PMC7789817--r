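# Copy-number analysis from methylation-array intensities: summed channel
# intensities are quantile normalized, expressed as log10 ratios over the
# control median, median-filter smoothed, and segmented by recursive
# permutation-tested change-point splits.

#' Total probe intensity
#'
#' Elementwise sum of the methylated and unmethylated channels; copy-number
#' changes scale this total while leaving the beta ratio untouched.
#'
#' @param meth,unmeth aligned intensity matrices.
#' @return their sum.
#' @export
total_intensity <- function(meth, unmeth) {
  if (!identical(dim(meth), dim(unmeth)))
    stopf("intensity matrices must have identical shape")
  meth + unmeth
}

#' Quantile normalization
#'
#' Forces every column (sample) to share the same empirical distribution:
#' each column's sorted values are replaced by the cross-column mean of the
#' sorted values, ties receiving the average of the tied target values.
#'
#' @param x probes x samples matrix (at least 2 columns).
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Log10 intensity ratio over the control median
#'
#' @param sample_values one sample's normalized total intensities.
#' @param control_median per-probe median across the control samples;
#'   probes with non-positive medians are dropped with a warning.
#' @return list with `r` (log10 ratios) and `keep` (logical index of the
#'   retained probes).
#' @export
log_ratio <- function(sample_values, control_median) {
  if (length(sample_values) != length(control_median))
    stopf("sample and control median must align")
  keep <- control_median > 0
  if (!all(keep))
    warnf("dropping %d probes with non-positive control median",
          sum(!keep))
  list(r = log10(sample_values[keep] / control_median[keep]), keep = keep)
}

# Maximal standardized mean-difference split statistic for a segment.
# Returns the best split index i (left part = 1..i) and the statistic
# max_i |mean_L - mean_R| / (s * sqrt(1/n_L + 1/n_R)); s is the segment SD,
# which is permutation-invariant, so permutations compare the numerator
# term directly.
max_split_stat <- function(x) {
  n <- length(x)
  cs <- cumsum(unname(x))
  i <- seq_len(n - 1)
  mean_l <- cs[i] / i
  mean_r <- (cs[n] - cs[i]) / (n - i)
  se <- sqrt(1 / i + 1 / (n - i))
  stat <- abs(mean_l - mean_r) / se
  k <- which.max(stat)
  c(split = k, stat = unname(stat[k]))
}

#' Segment a log-ratio track
#'
#' Recursive change-point segmentation of one sample's (single-chromosome)
#' log10 intensity ratios: single-probe outliers are first smoothed
#' (values deviating more than 3 MAD from their running median of window
#' `smooth_window` are replaced by that median, which trims spikes without
#' correlating neighbouring probes), then each candidate segment is split
#' at the position maximising the standardized mean-difference statistic
#' when that statistic exceeds its permutation null (p < `alpha` over
#' `n_perm` random shuffles of the segment's values); recursion continues
#' on both sides until no significant split remains.
#'
#' @param r log10 ratio vector.
#' @param positions sorted bp positions aligned with `r`.
#' @param alpha change-point significance level (default 0.01).
#' @param n_perm permutations per tested split (default 10000).
#' @param seed RNG seed for the permutations.
#' @param smooth_window running-median window for outlier trimming (odd;
#'   default 5; 1 disables smoothing).
#' @param chrom chromosome name recorded in the output.
#' @return `CnvSegment` data.frame: chrom, start, end, n_probes,
#'   mean_log_ratio (of the unsmoothed values), start_idx, end_idx. The
#'   segments partition the probes.
#' @export
segment_cnv <- function(r, positions, alpha = 0.01, n_perm = 10000,
                        seed = 1L, smooth_window = 5, chrom = "chr1") {
  if (is.unsorted(positions)) stopf("positions must be sorted")
  if (n_perm < 100) stopf("n_perm must be at least 100")
  n <- length(r)
  sm <- r
  if (smooth_window > 1 && n > smooth_window) {
    med <- stats::runmed(r, k = smooth_window, endrule = "median")
    dev <- r - med
    cut <- 3 * stats::mad(dev)
    if (cut > 0) {
      out <- abs(dev) > cut
      sm[out] <- med[out]
    }
  }
  breaks <- integer(0)
  with_seed(seed, {
    recurse <- function(lo, hi) {
      len <- hi - lo + 1
      if (len < 2) return()
      x <- sm[lo:hi]
      ms <- max_split_stat(x)
      if (!is.finite(ms["stat"]) || ms["stat"] == 0) return()
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        ps <- max_split_stat(sample(x))
        if (ps["stat"] >= ms["stat"]) exceed <- exceed + 1L
      }
      p <- (exceed + 1) / (n_perm + 1)
      if (p < alpha) {
        k <- lo + ms["split"] - 1
        breaks <<- c(breaks, k)
        recurse(lo, k)
        recurse(k + 1, hi)
      }
    }
    recurse(1, n)
  })
  bounds <- as.integer(sort(unique(c(0, breaks, n))))
  segs <- data.frame(
    chrom = chrom,
    start = positions[utils::head(bounds, -1) + 1L],
    end = positions[bounds[-1]],
    n_probes = diff(bounds),
    mean_log_ratio = vapply(seq_len(length(bounds) - 1), function(i)
      mean(r[(bounds[i] + 1):bounds[i + 1]]), numeric(1)),
    start_idx = utils::head(bounds, -1) + 1L,
    end_idx = bounds[-1],
    stringsAsFactors = FALSE
  )
  class(segs) <- c("CnvSegment", "data.frame")
  segs
}

#' Merge near-equal neighbouring segments
#'
#' Adjacent segments whose mean log ratios differ by less than `max_diff`
#' are joined (iterated to a fixed point); a merged segment's mean is the
#' probe-count-weighted average.
#'
#' @param segments a `CnvSegment` data.frame (ordered).
#' @param max_diff merge threshold on the mean difference (default 0.05,
#'   strict `<`).
#' @return merged `CnvSegment` data.frame.
#' @export
merge_segments <- function(segments, max_diff = 0.05) {
  segs <- segments
  repeat {
    if (nrow(segs) < 2) break
    d <- abs(diff(segs$mean_log_ratio))
    i <- which(d < max_diff)[1]
    if (is.na(i)) break
    w1 <- segs$n_probes[i]
    w2 <- segs$n_probes[i + 1]
    segs$mean_log_ratio[i] <- (w1 * segs$mean_log_ratio[i] +
                                 w2 * segs$mean_log_ratio[i + 1]) / (w1 + w2)
    segs$end[i] <- segs$end[i + 1]
    segs$end_idx[i] <- segs$end_idx[i + 1]
    segs$n_probes[i] <- w1 + w2
    segs <- segs[-(i + 1), , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

#' Call deletions from merged segments
#'
#' Segments with mean log10 ratio at or below `del_threshold` (default
#' -0.1, about a third of the theoretical single-copy signal of
#' log10(0.5) = -0.30, tolerating array compression) and at least
#' `min_probes` probes are emitted as deletion intervals spanning their
#' first to last member probe.
#'
#' @param segments merged `CnvSegment` data.frame.
#' @param del_threshold log10 ratio cutoff (default -0.1).
#' @param min_probes minimum probes per call (default 5).
#' @param label interval label prefix.
#' @return list of [genomic_interval()]s (possibly empty).
#' @export
call_deletions <- function(segments, del_threshold = -0.1, min_probes = 5,
                           label = "del") {
  hit <- which(segments$mean_log_ratio <= del_threshold &
                 segments$n_probes >= min_probes)
  lapply(seq_along(hit), function(j) {
    i <- hit[j]
    genomic_interval(segments$chrom[i], segments$start[i], segments$end[i],
                     label = sprintf("%s_%d", label, j))
  })
}

#' Whole-pipeline CNV calling for one sample
#'
#' Runs the intensity-based CNV chain on a `MethylationDataset`: summed
#' intensities, quantile normalization across the chosen samples, log10
#' ratio over the control median, per-chromosome segmentation, merging and
#' deletion calling.
#'
#' @param ds a `MethylationDataset` with intensity matrices.
#' @param sample_id the sample to segment.
#' @param control_ids samples defining the per-probe median (defaults to
#'   all `cohort == "control"` samples).
#' @inheritParams segment_cnv
#' @inheritParams call_deletions
#' @return list with `segments` (all chromosomes, merged) and `deletions`
#'   (list of `GenomicInterval`).
#' @export
cnv_pipeline <- function(ds, sample_id, control_ids = NULL, alpha = 0.01,
                         n_perm = 10000, seed = 1L, smooth_window = 5,
                         del_threshold = -0.1, min_probes = 5) {
  stopifnot(inherits(ds, "MethylationDataset"))
  if (is.null(control_ids))
    control_ids <- ds$samples$sample_id[ds$samples$cohort == "control"]
  tot <- total_intensity(ds$meth, ds$unmeth)
  cols <- unique(c(sample_id, control_ids))
  qn <- quantile_normalize(tot[, cols, drop = FALSE])
  med <- apply(qn[, control_ids, drop = FALSE], 1, stats::median)
  lr <- log_ratio(qn[, sample_id], med)
  man <- ds$manifest[lr$keep, , drop = FALSE]
  r <- lr$r
  segs <- NULL
  for (ch in unique(man$chrom)) {
    ix <- which(man$chrom == ch)
    s <- segment_cnv(r[ix], man$pos[ix], alpha = alpha, n_perm = n_perm,
                     seed = seed, smooth_window = smooth_window, chrom = ch)
    segs <- rbind(segs, merge_segments(s))
  }
  class(segs) <- c("CnvSegment", "data.frame")
  list(segments = segs,
       deletions = call_deletions(segs, del_threshold, min_probes,
                                  label = sample_id))
}
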