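# Differentially methylated region (DMR) calling: kernel smoothing of
# per-probe statistics followed by gap-constrained chaining and a
# Stouffer-combined region-level FDR.

#' Kernel-smooth per-probe statistics
#'
#' Gaussian-kernel smoothing of per-probe t-statistics along one
#' chromosome: with bandwidth `sigma = lambda / C`, weights
#' `w_ij = exp(-(pos_i - pos_j)^2 / (2 sigma^2))` give the smoothed
#' statistic `z_i = sum_j w_ij t_j / sqrt(sum_j w_ij^2)`, which is standard
#' normal under the null of exchangeable null t-statistics, so borrowing
#' strength from dense neighbours raises power while isolated probes keep
#' `z_i = t_i`. Weights are truncated beyond `8 sigma` where they are
#' numerically zero.
#'
#' @param t per-probe statistics (one chromosome).
#' @param positions bp positions, sorted increasing.
#' @param lambda kernel bandwidth in bp (default 1000).
#' @param C bandwidth scaling divisor (default 2, so sigma = 500 bp).
#' @return list with `z` (smoothed statistics) and `p` (two-sided normal
#'   p-values).
#' @export
smooth_stats <- function(t, positions, lambda = 1000, C = 2) {
  if (length(t) != length(positions)) stopf("t and positions must align")
  if (is.unsorted(positions)) stopf("positions must be sorted")
  sigma <- lambda / C
  cutoff <- 8 * sigma
  n <- length(t)
  z <- numeric(n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (positions[i] - positions[lo] > cutoff) lo <- lo + 1L
    while (hi < n && positions[hi + 1L] - positions[i] <= cutoff)
      hi <- hi + 1L
    w <- exp(-(positions[lo:hi] - positions[i])^2 / (2 * sigma^2))
    z[i] <- sum(w * t[lo:hi]) / sqrt(sum(w^2))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Chain candidate probes and compute region-level raw statistics.
# All vectors are aligned, single chromosome, positions sorted.
chain_candidates <- function(candidate, q, t, delta_beta, positions, chrom,
                             max_gap, min_probes, min_mean_delta) {
  idx <- which(candidate)
  if (!length(idx)) return(NULL)
  gaps <- diff(positions[idx])
  run <- cumsum(c(0, gaps > max_gap))
  out <- lapply(split(idx, run), function(m) {
    if (length(m) < min_probes) return(NULL)
    mean_delta <- mean(delta_beta[m])
    if (abs(mean_delta) <= min_mean_delta) return(NULL)
    qi <- pmax(q[m], 1e-300)
    z_reg <- sum(stats::qnorm(qi / 2, lower.tail = FALSE) * sign(t[m])) /
      sqrt(length(m))
    data.frame(chrom = chrom, start = positions[m[1]],
               end = positions[m[length(m)]], n_probes = length(m),
               mean_delta_beta = mean_delta, stouffer_z = z_reg,
               p_region = 2 * stats::pnorm(-abs(z_reg)),
               direction = if (mean_delta > 0) "hyper" else "hypo",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out
}

#' Call DMRs on one chromosome
#'
#' Candidate probes are those significant after BH adjustment of the
#' smoothed p-values (`q < candidate_alpha`); consecutive candidates no
#' more than `max_gap` bp apart are chained into regions. A region is kept
#' when it holds at least `min_probes` probes, its mean beta difference
#' exceeds `min_mean_delta` in absolute value, and its Stouffer-combined
#' FDR is below `max_fdr`. The region statistic combines the member
#' probes' adjusted q-values as signed normal quantiles,
#' `z = sum_i qnorm(1 - q_i/2) * sign(t_i) / sqrt(n)`, whose two-sided
#' normal p-value is BH-adjusted across regions.
#'
#' @param smoothed_p per-probe smoothed p-values (from [smooth_stats()]).
#' @param t per-probe statistics (for direction).
#' @param delta_beta per-probe beta differences.
#' @param positions sorted bp positions.
#' @param chrom chromosome name for the output.
#' @param max_gap maximum intra-region probe gap in bp (default 1000).
#' @param min_probes minimum probes per region (default 3).
#' @param min_mean_delta minimum absolute mean regional beta difference
#'   (default 0.10).
#' @param max_fdr maximum Stouffer FDR (default 0.01).
#' @param candidate_alpha BH threshold defining candidate probes
#'   (default 0.05).
#' @return `Dmr` data.frame (possibly empty): chrom, start, end, n_probes,
#'   mean_delta_beta, stouffer_z, stouffer_fdr, direction.
#' @export
call_dmrs <- function(smoothed_p, t, delta_beta, positions, chrom = "chr1",
                      max_gap = 1000, min_probes = 3, min_mean_delta = 0.10,
                      max_fdr = 0.01, candidate_alpha = 0.05) {
  if (is.unsorted(positions)) stopf("positions must be sorted")
  q <- adjust_bh(smoothed_p)
  regs <- chain_candidates(q < candidate_alpha, q, t, delta_beta, positions,
                           chrom, max_gap, min_probes, min_mean_delta)
  finalize_dmrs(regs, max_fdr)
}

finalize_dmrs <- function(regs, max_fdr) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      mean_delta_beta = numeric(0), stouffer_z = numeric(0),
                      stouffer_fdr = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(regs) || nrow(regs) == 0) {
    class(empty) <- c("Dmr", "data.frame")
    return(empty)
  }
  regs$stouffer_fdr <- adjust_bh(regs$p_region)
  regs <- regs[regs$stouffer_fdr < max_fdr, , drop = FALSE]
  regs$p_region <- NULL
  rownames(regs) <- NULL
  class(regs) <- c("Dmr", "data.frame")
  regs
}

#' Genome-wide DMR calling from differential results
#'
#' Convenience wrapper over [smooth_stats()] and the chaining rules of
#' [call_dmrs()]: smooths each chromosome separately, BH-adjusts the
#' smoothed p-values genome-wide, chains candidates per chromosome, and
#' BH-adjusts the Stouffer region p-values across all regions.
#'
#' @param results a `DiffResult` data.frame from [run_differential()].
#' @inheritParams call_dmrs
#' @inheritParams smooth_stats
#' @return `Dmr` data.frame.
#' @export
find_dmrs <- function(results, lambda = 1000, C = 2, max_gap = 1000,
                      min_probes = 3, min_mean_delta = 0.10, max_fdr = 0.01,
                      candidate_alpha = 0.05) {
  ord <- order(results$chrom, results$pos)
  res <- results[ord, , drop = FALSE]
  by_chr <- split(seq_len(nrow(res)), res$chrom)
  sm_p <- numeric(nrow(res))
  for (ix in by_chr)
    sm_p[ix] <- smooth_stats(res$t_mod[ix], res$pos[ix], lambda, C)$p
  q <- adjust_bh(sm_p)
  regs <- do.call(rbind, lapply(names(by_chr), function(ch) {
    ix <- by_chr[[ch]]
    chain_candidates(q[ix] < candidate_alpha, q[ix], res$t_mod[ix],
                     res$delta_beta[ix], res$pos[ix], ch, max_gap,
                     min_probes, min_mean_delta)
  }))
  finalize_dmrs(regs, max_fdr)
}
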