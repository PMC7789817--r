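# Per-probe moderated differential methylation on M-values.
#
# Effect sizes (delta beta) are reported on the beta scale for biological
# interpretation; inference runs on the M scale where variances are more
# nearly constant.

#' Per-probe linear model fits
#'
#' Ordinary least squares of each probe's M-values on a shared design
#' matrix (group indicator plus covariates such as estimated cell
#' proportions). All probes share the same residual degrees of freedom.
#'
#' @param M probes x samples matrix of M-values.
#' @param design samples x coefficients model matrix containing a column
#'   named `group` (1 = case, 0 = control) and typically an intercept.
#' @return list with per-probe `coef` (the group effect), `s2` (residual
#'   variance), scalar `df`, and `stdev_unscaled` (the group coefficient's
#'   unscaled standard error).
#' @export
fit_probe_models <- function(M, design) {
  design <- as.matrix(design)
  if (!"group" %in% colnames(design))
    stopf("design must contain a 'group' column")
  if (nrow(design) != ncol(M))
    stopf("design rows must match samples (columns of M)")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stopf("design is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  df <- nrow(design) - ncol(design)
  if (df < 1) stopf("no residual degrees of freedom")
  fit <- stats::lm.fit(design, t(M))
  coefs <- t(fit$coefficients)
  res <- fit$residuals                      # samples x probes
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qrd))
  dimnames(xtxi) <- list(colnames(design), colnames(design))
  list(coef = unname(coefs[, "group"]), s2 = unname(s2), df = df,
       stdev_unscaled = sqrt(xtxi["group", "group"]),
       probe_id = rownames(M))
}

# Newton inversion of the trigamma function (y > 0 -> x with
# trigamma(x) = y), as used when fitting the variance prior by moments.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-square prior (prior df `d0`, prior variance
#' `s0_sq`) to the per-probe residual variances by method of moments on
#' `log(s2)` (the log of a variance estimate follows a shifted
#' log-F distribution whose first two moments identify the prior). Each
#' probe's variance is shrunk to the posterior
#' `s2_post = (d0*s0_sq + df*s2) / (d0 + df)`, the moderated t is the
#' coefficient over its posterior standard error, and p-values use
#' `df + d0` degrees of freedom. When the observed variances are constant
#' the prior is degenerate (`d0 = Inf`) and the variances are used as-is.
#'
#' @param fit output of [fit_probe_models()] (needs at least 10 probes).
#' @return list with `prior` (`d0`, `s0_sq`), `s2_post`, `t_mod`, `p`, and
#'   `df_total`.
#' @export
moderate_variances <- function(fit) {
  s2 <- fit$s2
  df <- fit$df
  if (length(s2) < 10) stopf("need at least 10 probes to fit the prior")
  s2c <- pmax(s2, 1e-300)
  if (stats::var(log(s2c)) < 1e-15) {
    # degenerate: no variance heterogeneity to shrink
    d0 <- Inf
    s0_sq <- s2c[1]
    s2_post <- s2
  } else {
    e <- log(s2c) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
      s2_post <- rep(s0_sq, length(s2))
    }
  }
  se <- fit$stdev_unscaled * sqrt(s2_post)
  t_mod <- fit$coef / se
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(prior = list(d0 = d0, s0_sq = s0_sq), s2_post = s2_post,
       t_mod = t_mod, p = p, df_total = df_total)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with enforced monotonicity,
#' order-preserving on the input indices.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select epi-signature probes
#'
#' Applies the dual threshold of the discovery analysis: an absolute
#' group-mean beta difference greater than `min_delta` AND an adjusted
#' p-value strictly below `max_q`. The effect-size guard avoids reporting
#' statistically significant probes of negligible magnitude.
#'
#' @param results a `DiffResult` data.frame (see [run_differential()]).
#' @param min_delta minimum absolute beta difference (default 0.10).
#' @param max_q maximum adjusted p (default 0.01, strict `<`).
#' @return the selected probe ids, sorted by decreasing `|delta_beta|`.
#' @export
select_signature_probes <- function(results, min_delta = 0.10,
                                    max_q = 0.01) {
  if (nrow(results) == 0) return(character(0))
  sel <- results[abs(results$delta_beta) > min_delta &
                   results$q < max_q, , drop = FALSE]
  sel$probe_id[order(-abs(sel$delta_beta))]
}

#' Full per-probe differential methylation analysis
#'
#' Runs the probe-wise pipeline on a (typically already filtered) dataset:
#' M-value transform, OLS fits against case/control with optional
#' cell-proportion covariates, empirical-Bayes variance moderation, BH
#' correction, and beta-scale effect sizes.
#'
#' The last cell-proportion column is dropped from the design (baseline
#' cell type) because proportions summing to one are collinear with the
#' intercept.
#'
#' @param ds a `MethylationDataset` whose sample sheet labels cohorts
#'   "case" / "control".
#' @param cell_props optional `CellProportions` (samples x cell types)
#'   aligned with the dataset samples.
#' @param covariates optional extra numeric covariate matrix
#'   (samples x q).
#' @return `DiffResult` data.frame: probe_id, chrom, pos, delta_beta, coef,
#'   s2, df, t_mod, p, q.
#' @export
run_differential <- function(ds, cell_props = NULL, covariates = NULL) {
  stopifnot(inherits(ds, "MethylationDataset"))
  grp <- as.numeric(ds$samples$cohort == "case")
  if (all(grp == 0) || all(grp == 1)) stopf("need both cases and controls")
  design <- cbind(intercept = 1, group = grp)
  if (!is.null(cell_props)) {
    cp <- as.matrix(cell_props)
    cp <- cp[, -ncol(cp), drop = FALSE]  # baseline cell type
    design <- cbind(design, cp)
  }
  if (!is.null(covariates)) design <- cbind(design, as.matrix(covariates))
  M <- beta_to_m(ds$beta)
  fit <- fit_probe_models(M, design)
  mod <- moderate_variances(fit)
  case <- ds$samples$cohort == "case"
  delta <- rowMeans(ds$beta[, case, drop = FALSE]) -
    rowMeans(ds$beta[, !case, drop = FALSE])
  res <- data.frame(
    probe_id = ds$manifest$probe_id, chrom = ds$manifest$chrom,
    pos = ds$manifest$pos, delta_beta = unname(delta), coef = fit$coef,
    s2 = fit$s2, df = fit$df, t_mod = mod$t_mod, p = mod$p,
    q = adjust_bh(mod$p), stringsAsFactors = FALSE
  )
  class(res) <- c("DiffResult", "data.frame")
  res
}
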