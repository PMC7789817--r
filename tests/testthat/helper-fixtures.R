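# Shared fixture builders; everything is generated in code at test time.

# Small mixed-chromosome manifest with sex chromosomes.
tiny_manifest <- function(seed = 3) {
  make_probe_manifest(6000, c(chr1 = 2700, chr2 = 2700, chrX = 400,
                              chrY = 200), seed = seed)
}

# Manifest whose chr1 carries a dense probe block (for DMR fixtures):
# `block_n` probes spaced `block_gap` bp, surrounded by isolated probes
# `bg_gap` bp apart.
block_manifest <- function(block_n = 5, block_gap = 200, n_background = 1200,
                           bg_gap = 10000) {
  block_pos <- 1e6 + (seq_len(block_n) - 1) * block_gap
  bg_pos <- 2e6 + seq_len(n_background) * bg_gap
  as_probe_manifest(data.frame(
    probe_id = sprintf("cg%07d", seq_len(block_n + n_background)),
    chrom = "chr1", pos = c(block_pos, bg_pos), stringsAsFactors = FALSE))
}

# Cohort with a signature planted exactly at the manifest's leading block.
block_cohort <- function(man, block_n = 5, delta_beta = 0.20, seed = 21) {
  des <- cohort_design(signal_probe_ids = man$probe_id[seq_len(block_n)],
                       delta_beta = delta_beta, hyper_fraction = 1,
                       seed = seed)
  simulate_cohort(man, des)
}

# Brute-force BH step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled values (no ties).
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) +
    0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  mu <- nx * length(y) / 2
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
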