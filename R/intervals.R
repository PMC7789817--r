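# Genomic interval arithmetic for critical-region mapping. Intervals are
# 1-based inclusive in memory; BED output converts to 0-based half-open.

#' Create a genomic interval
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bp coordinates, `start <= end`.
#' @param label optional name.
#' @return list of class `GenomicInterval`.
#' @export
genomic_interval <- function(chrom, start, end, label = NULL) {
  if (length(chrom) != 1 || start > end || start < 1)
    stopf("invalid interval: %s:%s-%s", chrom, start, end)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), label = label),
            class = "GenomicInterval")
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("%s:%s-%s%s\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

intervals_to_granges <- function(ivs) {
  if (inherits(ivs, "GenomicInterval")) ivs <- list(ivs)
  GenomicRanges::GRanges(
    seqnames = vapply(ivs, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(ivs, `[[`, numeric(1), "start"),
      end = vapply(ivs, `[[`, numeric(1), "end")))
}

granges_to_intervals <- function(gr, label = NULL) {
  lapply(seq_along(gr), function(i)
    genomic_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                     GenomicRanges::start(gr)[i],
                     GenomicRanges::end(gr)[i], label = label))
}

#' Map the epi-signature critical region
#'
#' Intersects all signature-positive deletion intervals and subtracts the
#' signature-negative deletions: the result is the genomic region shared by
#' every subject carrying the signature and by none without it. Negatives
#' are subtracted as open intervals (their interiors), so a breakpoint
#' coordinate shared between a positive and a negative deletion remains in
#' the critical region; single-base slivers arising at such boundaries are
#' dropped.
#'
#' @param positives non-empty list of `GenomicInterval`s with the
#'   signature.
#' @param negatives list (possibly empty) of intervals without it.
#' @return list of `GenomicInterval`s (possibly empty; disjoint positives
#'   give an empty result with a warning). Order-invariant in both inputs
#'   and idempotent under duplicated intervals.
#' @export
critical_region <- function(positives, negatives = list()) {
  if (inherits(positives, "GenomicInterval")) positives <- list(positives)
  if (inherits(negatives, "GenomicInterval")) negatives <- list(negatives)
  if (!length(positives)) stopf("at least one positive interval required")
  chroms <- unique(vapply(positives, `[[`, character(1), "chrom"))
  if (length(chroms) > 1)
    stopf("all positive intervals must share one chromosome")
  s <- max(vapply(positives, `[[`, numeric(1), "start"))
  e <- min(vapply(positives, `[[`, numeric(1), "end"))
  if (s > e) {
    warnf("positive intervals are disjoint; critical region is empty")
    return(list())
  }
  inter <- genomic_interval(chroms, s, e)
  gr <- intervals_to_granges(list(inter))
  if (length(negatives)) {
    ng <- intervals_to_granges(negatives)
    # subtract interiors: shrink each negative by 1 bp per side
    keep <- GenomicRanges::width(ng) > 2
    ng <- GenomicRanges::resize(ng[keep],
                                width = GenomicRanges::width(ng[keep]) - 2,
                                fix = "center")
    if (length(ng)) gr <- GenomicRanges::setdiff(gr, ng)
  }
  gr <- gr[GenomicRanges::width(gr) > 1]
  granges_to_intervals(gr, label = "critical_region")
}

#' Interval length in megabases
#'
#' `(end - start) / 1e6`, rounded half-up to `decimals` digits — the
#' convention used when tabulating array-derived deletion sizes.
#'
#' @param interval a `GenomicInterval`.
#' @param decimals digits to round to (default 2).
#' @return length in Mb.
#' @export
interval_length_mb <- function(interval, decimals = 2) {
  stopifnot(inherits(interval, "GenomicInterval"))
  round_half_up((interval$end - interval$start) / 1e6, decimals)
}

#' Published 22q13 deletion coordinates (methylation-array derived)
#'
#' Loads the packaged table of 22q13.3 deletion intervals measured from
#' EPIC-array intensity data in a Phelan-McDermid syndrome cohort: 11
#' signature-positive large deletions and 5 signature-negative small
#' deletions on hg19, with the published rounded lengths.
#'
#' @return data.frame: sample_id, cohort ("large_del" carries the
#'   epi-signature, "small_del" does not), chrom, start, end, length_mb.
#' @export
phelan_deletions <- function() {
  path <- system.file("extdata", "phelan_deletions_epic.csv",
                      package = "episcan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname phelan_deletions
#' @param cohort optional filter ("large_del" or "small_del").
#' @export
phelan_deletion_intervals <- function(cohort = NULL) {
  df <- phelan_deletions()
  if (!is.null(cohort)) df <- df[df$cohort == cohort, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    genomic_interval(df$chrom[i], df$start[i], df$end[i],
                     label = df$sample_id[i]))
}

#' Reciprocal overlap of two intervals
#'
#' The overlap width divided by each interval's width, returned as the
#' minimum of the two fractions; 0 when the intervals do not overlap.
#'
#' @param a,b `GenomicInterval`s on the same chromosome.
#' @return reciprocal overlap fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}
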