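#' Methylation dataset container
#'
#' A lightweight container aligning a probe manifest with per-sample
#' methylated/unmethylated intensity matrices, beta values, optional
#' detection p-values, and a sample sheet. All matrices are probes x samples
#' with probe ids as rownames and sample ids as colnames.
#'
#' @param manifest a `ProbeManifest`.
#' @param meth,unmeth intensity matrices (may be `NULL` when only betas are
#'   available).
#' @param beta matrix of betas in (0, 1); computed from the intensities with
#'   `offset` when absent.
#' @param detection_p optional matrix of detection p-values.
#' @param samples sample sheet `data.frame` with columns `sample_id`, `age`,
#'   `sex`, `batch`, `cohort`.
#' @param offset beta-offset used to relate intensities and betas.
#' @param truth optional ground-truth bookkeeping (synthetic data).
#' @return list of class `MethylationDataset`.
#' @export
methylation_dataset <- function(manifest, meth = NULL, unmeth = NULL,
                                beta = NULL, detection_p = NULL, samples,
                                offset = 0, truth = NULL) {
  stopifnot(inherits(manifest, "ProbeManifest"), is.data.frame(samples))
  if (anyDuplicated(samples$sample_id)) stopf("sample ids must be unique")
  if (is.null(beta)) {
    if (is.null(meth) || is.null(unmeth))
      stopf("either beta or both intensity matrices are required")
    beta <- compute_beta(meth, unmeth, offset)
  }
  for (m in list(meth, unmeth, beta, detection_p)) {
    if (!is.null(m) && (nrow(m) != nrow(manifest) ||
                        ncol(m) != nrow(samples)))
      stopf("matrix dimensions disagree with manifest/sample sheet")
  }
  structure(list(manifest = manifest, meth = meth, unmeth = unmeth,
                 beta = beta, detection_p = detection_p, samples = samples,
                 offset = offset, truth = truth),
            class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset: %d probes x %d samples (%d cases)\n",
              nrow(x$manifest), nrow(x$samples),
              sum(x$samples$cohort == "case")))
  invisible(x)
}

#' Beta values from intensity pairs
#'
#' `beta = meth / (meth + unmeth + offset)`: the methylated signal over the
#' total signal. With `offset = 0` this is the plain intensity ratio; the
#' Illumina convention adds 100 to stabilise low-intensity probes.
#'
#' @param meth,unmeth non-negative intensities (scalars, vectors, matrices).
#' @param offset non-negative stabilising constant (default 0).
#' @return betas in `[0, 1]`; defined as 0 (with a warning) where the
#'   denominator is 0.
#' @export
compute_beta <- function(meth, unmeth, offset = 0) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stopf("intensities must be non-negative")
  den <- meth + unmeth + offset
  bad <- den == 0
  if (any(bad, na.rm = TRUE)) {
    warnf("zero total intensity at %d entries; beta set to 0", sum(bad))
    den[bad] <- 1
  }
  b <- meth / den
  b[bad] <- 0
  b
}

#' Logit (M-value) transform of betas
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[eps, 1 - eps]`, the variance-stabilised scale used for linear
#' modelling.
#'
#' @param beta betas in `[0, 1]`.
#' @param eps clip bound keeping M finite at the boundaries.
#' @return M-values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Inverse of [beta_to_m()]
#' @param m M-values.
#' @return betas in (0, 1).
#' @export
m_to_beta <- function(m) 1 / (1 + 2^(-m))

#' Probe-level filtering
#'
#' Removes, in manifest order, probes that (in priority order) fail
#' detection at `p > detection_threshold` in any sample, sit on a sex
#' chromosome, contain a SNP at the interrogated position, or are
#' cross-reactive. Each removed probe is recorded with exactly one primary
#' reason.
#'
#' @param ds a `MethylationDataset`.
#' @param detection_threshold detection p-value cutoff (default 0.01,
#'   strict `>` fails).
#' @return list with the filtered `dataset` and a `report` data.frame
#'   (probe_id, pass, reason).
#' @export
filter_probes <- function(ds, detection_threshold = 0.01) {
  stopifnot(inherits(ds, "MethylationDataset"))
  man <- ds$manifest
  reason <- rep(NA_character_, nrow(man))
  if (!is.null(ds$detection_p)) {
    fail_det <- rowSums(ds$detection_p > detection_threshold) > 0
    reason[fail_det] <- "detection"
  }
  reason[is.na(reason) & man$is_sex_chrom] <- "sex_chromosome"
  reason[is.na(reason) & man$flag_snp] <- "snp"
  reason[is.na(reason) & man$flag_cross_reactive] <- "cross_reactive"
  keep <- is.na(reason)
  if (!any(keep)) stopf("all probes removed by filtering")
  report <- data.frame(probe_id = man$probe_id, pass = keep,
                       reason = ifelse(keep, "", reason),
                       stringsAsFactors = FALSE)
  out <- ds
  out$manifest <- man[keep, , drop = FALSE]
  rownames(out$manifest) <- NULL
  class(out$manifest) <- class(man)
  for (nm in c("meth", "unmeth", "beta", "detection_p"))
    if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]][keep, , drop = FALSE]
  list(dataset = out, report = report)
}

#' Sample-level quality control
#'
#' Flags samples whose failed-probe fraction (detection p above
#' `detection_threshold`) exceeds `max_fail_rate` (strict `>`; a sample at
#' exactly the threshold is retained). Also records the predicted sex, its
#' concordance with the sample sheet, and the genome-wide bimodality check.
#'
#' @param ds a `MethylationDataset` with detection p-values.
#' @param max_fail_rate maximum tolerated failed-probe fraction
#'   (default 0.05).
#' @param detection_threshold per-probe detection cutoff.
#' @return data.frame of class `QcReport`: sample_id, fail_fraction,
#'   excluded, predicted_sex, sex_discordant, bimodal_pass.
#' @export
sample_qc <- function(ds, max_fail_rate = 0.05, detection_threshold = 0.01) {
  stopifnot(inherits(ds, "MethylationDataset"))
  if (is.null(ds$detection_p)) stopf("detection p-values required")
  fail_frac <- colMeans(ds$detection_p > detection_threshold)
  pred_sex <- tryCatch(predict_sex(ds), error = function(e) {
    rep(NA_character_, nrow(ds$samples))
  })
  bimodal <- apply(ds$beta, 2, check_bimodality)
  rep <- data.frame(
    sample_id = ds$samples$sample_id,
    fail_fraction = unname(fail_frac),
    excluded = unname(fail_frac > max_fail_rate),
    predicted_sex = pred_sex,
    sex_discordant = !is.na(pred_sex) & pred_sex != ds$samples$sex,
    bimodal_pass = unname(bimodal),
    stringsAsFactors = FALSE
  )
  class(rep) <- c("QcReport", "data.frame")
  rep
}

#' Predict sample sex from sex-chromosome intensities
#'
#' Compares the per-sample median log2 total intensity of chrY probes with
#' that of chrX probes: males carry Y material at autosomal-like levels
#' while female Y probes read near background, so the difference separates
#' the sexes cleanly. The decision threshold (default -2) is configurable.
#'
#' @param ds a `MethylationDataset` (unfiltered: sex-chromosome probes must
#'   be present) with intensity matrices.
#' @param threshold Y-minus-X median log2 intensity difference above which a
#'   sample is called male.
#' @return character vector of "male"/"female" per sample.
#' @export
predict_sex <- function(ds, threshold = -2) {
  stopifnot(inherits(ds, "MethylationDataset"))
  if (is.null(ds$meth) || is.null(ds$unmeth))
    stopf("intensity matrices required for sex prediction")
  x_idx <- which(ds$manifest$chrom == "chrX")
  y_idx <- which(ds$manifest$chrom == "chrY")
  if (!length(x_idx) || !length(y_idx))
    stopf("no sex-chromosome probes in dataset")
  tot <- ds$meth + ds$unmeth
  med_x <- apply(log2(tot[x_idx, , drop = FALSE] + 1), 2, stats::median)
  med_y <- apply(log2(tot[y_idx, , drop = FALSE] + 1), 2, stats::median)
  ifelse(med_y - med_x > threshold, "male", "female")
}

#' Genome-wide methylation bimodality check
#'
#' A healthy genome-wide beta distribution is bimodal (most CpGs near 0 or
#' 1). The check passes when the fraction of betas in the mid-range
#' (`mid[1]`, `mid[2]`) is below `max_mid_mass`.
#'
#' @param beta_vector one sample's betas (at least 100 probes).
#' @param mid mid-range interval (default (0.3, 0.7), open).
#' @param max_mid_mass maximum tolerated mid-range mass (default 0.35).
#' @return logical: `TRUE` when the sample passes.
#' @export
check_bimodality <- function(beta_vector, mid = c(0.3, 0.7),
                             max_mid_mass = 0.35) {
  if (length(beta_vector) < 100) stopf("need at least 100 probes")
  mass <- mean(beta_vector > mid[1] & beta_vector < mid[2])
  mass < max_mid_mass
}

#' Principal-component scores of a sample matrix
#'
#' Column-centred SVD of the samples-by-features matrix; deterministic up to
#' sign. Used for batch-structure review and outlier detection.
#'
#' @param x samples x features matrix (e.g. transposed M-values).
#' @param k number of components (truncated to the matrix rank with a
#'   warning when larger).
#' @return list with `scores` (samples x k) and `explained` (variance
#'   fractions).
#' @export
pca_scores <- function(x, k = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > pos) {
    warnf("requested %d components but rank is %d; truncating", k, pos)
    k <- pos
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  list(scores = scores,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Select age/sex/batch-matched controls
#'
#' Greedy nearest-neighbour matching: for each case, `ratio` controls are
#' drawn without replacement from the pool within the case's exact
#' (sex, batch) stratum, nearest in age first (ties broken by pool order).
#' After each matching pass a PCA over the matched controls' M-values flags
#' outliers (score beyond `sd_cut` SDs on PC1 or PC2); flagged controls are
#' dropped from the pool and matching repeats, up to `max_iter` passes or
#' until no outlier remains.
#'
#' @param cases sample sheet of the cases.
#' @param pool sample sheet of candidate controls.
#' @param pool_m optional samples x probes M-value matrix for the pool
#'   (rownames = sample ids); when absent the PCA outlier pass is skipped.
#' @param ratio controls per case (default 4).
#' @param sd_cut,max_iter outlier rule parameters.
#' @return character vector of exactly `ratio * nrow(cases)` control ids.
#' @export
match_controls <- function(cases, pool, pool_m = NULL, ratio = 4,
                           sd_cut = 3, max_iter = 10) {
  stopifnot(is.data.frame(cases), is.data.frame(pool))
  avail_pool <- pool
  for (iter in seq_len(max_iter)) {
    selected <- character(0)
    avail <- rep(TRUE, nrow(avail_pool))
    for (i in seq_len(nrow(cases))) {
      stratum <- which(avail & avail_pool$sex == cases$sex[i] &
                         avail_pool$batch == cases$batch[i])
      if (length(stratum) < ratio)
        stopf("control pool exhausted in stratum (sex=%s, batch=%s)",
              cases$sex[i], cases$batch[i])
      d <- abs(avail_pool$age[stratum] - cases$age[i])
      pick <- stratum[order(d)][seq_len(ratio)]
      avail[pick] <- FALSE
      selected <- c(selected, avail_pool$sample_id[pick])
    }
    if (is.null(pool_m)) return(selected)
    sc <- pca_scores(pool_m[selected, , drop = FALSE], k = 2)$scores
    out <- rep(FALSE, length(selected))
    for (j in seq_len(ncol(sc))) {
      z <- (sc[, j] - mean(sc[, j])) / stats::sd(sc[, j])
      out <- out | abs(z) > sd_cut
    }
    if (!any(out)) return(selected)
    avail_pool <- avail_pool[!avail_pool$sample_id %in% selected[out], ,
                             drop = FALSE]
  }
  warnf("outliers still present after %d matching iterations", max_iter)
  selected
}
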