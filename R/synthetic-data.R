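#' Build a synthetic probe manifest
#'
#' Creates an array-style probe manifest with unique probe identifiers,
#' chromosome assignments, strictly increasing positions within each
#' chromosome, and quality flags (SNP at the interrogated CpG,
#' cross-reactive) assigned by exact count rather than by coin flips, so a
#' fixed fraction of probes is always flagged.
#'
#' @param n_probes total number of probes; must equal `sum(chrom_plan)`.
#' @param chrom_plan named integer vector mapping chromosome name to probe
#'   count, e.g. `c(chr1 = 8000, chr2 = 8000, chrX = 500)`. Chromosomes named
#'   `chrX`/`chrY` are marked as sex chromosomes.
#' @param seed integer RNG seed; the manifest is a pure function of it.
#' @param frac_snp,frac_cross_reactive fraction of autosomal probes carrying
#'   each flag (disjoint sets, assigned by count).
#' @param spacing mean inter-probe spacing in bp (positions are cumulative
#'   sums of uniform gaps in `[1, 2*spacing]`).
#' @return a `data.frame` of class `ProbeManifest` with columns `probe_id`,
#'   `chrom`, `pos`, `flag_snp`, `flag_cross_reactive`, `is_sex_chrom`,
#'   sorted by (chrom, pos).
#' @export
make_probe_manifest <- function(n_probes, chrom_plan, seed = 1L,
                                frac_snp = 0.01, frac_cross_reactive = 0.01,
                                spacing = 1500) {
  if (!is_count(n_probes) || n_probes < 1)
    stopf("n_probes must be a positive count")
  if (is.null(names(chrom_plan)) || any(chrom_plan < 1))
    stopf("chrom_plan must be a named vector of positive counts")
  if (sum(chrom_plan) != n_probes)
    stopf("sum(chrom_plan) (%d) must equal n_probes (%d)",
          sum(chrom_plan), n_probes)
  with_seed(seed, {
    chroms <- rep(names(chrom_plan), times = chrom_plan)
    pos <- unlist(lapply(chrom_plan, function(k) {
      cumsum(sample(seq_len(2 * spacing), k, replace = TRUE))
    }), use.names = FALSE)
    man <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      chrom = chroms, pos = pos,
      flag_snp = FALSE, flag_cross_reactive = FALSE,
      is_sex_chrom = chroms %in% c("chrX", "chrY"),
      stringsAsFactors = FALSE
    )
    auto <- which(!man$is_sex_chrom)
    n_snp <- floor(frac_snp * length(auto))
    n_cr <- floor(frac_cross_reactive * length(auto))
    flagged <- sample(auto, n_snp + n_cr)
    man$flag_snp[flagged[seq_len(n_snp)]] <- TRUE
    if (n_cr > 0) man$flag_cross_reactive[flagged[n_snp + seq_len(n_cr)]] <- TRUE
    man <- man[order(man$chrom, man$pos), , drop = FALSE]
    rownames(man) <- NULL
    class(man) <- c("ProbeManifest", "data.frame")
    man
  })
}

#' Coerce a data.frame to a probe manifest
#'
#' Validates and sorts a user-supplied manifest table (columns `probe_id`,
#' `chrom`, `pos`, and optionally the three flag columns, which default to
#' `FALSE` / chrX-chrY detection).
#'
#' @param df data.frame with at least `probe_id`, `chrom`, `pos`.
#' @return a `ProbeManifest`.
#' @export
as_probe_manifest <- function(df) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$probe_id)) stopf("probe ids must be unique")
  if (any(df$pos < 1)) stopf("positions must be >= 1")
  if (is.null(df$flag_snp)) df$flag_snp <- FALSE
  if (is.null(df$flag_cross_reactive)) df$flag_cross_reactive <- FALSE
  if (is.null(df$is_sex_chrom)) df$is_sex_chrom <- df$chrom %in% c("chrX",
                                                                   "chrY")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ProbeManifest", "data.frame")
  df
}

#' Synthetic leukocyte reference profiles
#'
#' Generates a cell-type reference matrix for deconvolution testing: each of
#' the `n_cell_types` types owns a block of discriminating probes where its
#' mean beta is high (`hi`) while all other types are low (`lo`). This is a
#' synthetic stand-in for published sorted-cell references; real references
#' can be supplied as any matrix of the same shape.
#'
#' @param cell_types character vector of cell-type labels.
#' @param probes_per_type number of discriminating probes owned by each type.
#' @param probe_ids optional probe identifiers to use (length must be
#'   `length(cell_types) * probes_per_type`); defaults to `ref_cg...` ids.
#' @param hi,lo beta levels for the owning / non-owning cell type.
#' @param seed RNG seed for the small jitter applied to the levels.
#' @return matrix (cell types x probes) of class `CellReference`, values in
#'   `[0, 1]`, with cell-type rownames and probe colnames.
#' @export
make_cell_reference <- function(cell_types = c("CD4T", "CD8T", "NK", "Bcell",
                                               "Mono", "Gran"),
                                probes_per_type = 100, probe_ids = NULL,
                                hi = 0.85, lo = 0.15, seed = 1L) {
  k <- length(cell_types)
  p <- k * probes_per_type
  if (is.null(probe_ids)) probe_ids <- sprintf("refcg%06d", seq_len(p))
  if (length(probe_ids) != p) stopf("need %d probe ids, got %d", p,
                                    length(probe_ids))
  with_seed(seed, {
    prof <- matrix(lo, k, p, dimnames = list(cell_types, probe_ids))
    for (i in seq_len(k)) {
      cols <- (i - 1) * probes_per_type + seq_len(probes_per_type)
      prof[i, cols] <- hi
    }
    prof <- prof + matrix(stats::rnorm(k * p, 0, 0.02), k, p)
    prof[] <- pmin(pmax(prof, 0.01), 0.99)
    class(prof) <- c("CellReference", class(prof))
    prof
  })
}

#' Cohort simulation design
#'
#' Bundles the parameters of a synthetic case/control methylation cohort.
#' Defaults mirror the study conditions of the discovery analysis: 11 cases
#' against 44 matched controls, a 1,000-probe signature with 10--20% beta
#' shifts dominated by hypermethylation, blood-cell-composition structure and
#' age/sex/batch covariates.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_signal_probes number of planted signature probes.
#' @param delta_beta planted group-mean difference on the beta scale,
#'   in (0, 1).
#' @param hyper_fraction fraction of signature probes shifted upward
#'   (hypermethylated) in cases.
#' @param cell_reference optional `CellReference` matrix; when supplied, each
#'   sample's betas at the reference probes are a Dirichlet-weighted mixture
#'   of the cell-type profiles.
#' @param case_cell_alpha,control_cell_alpha Dirichlet concentration vectors
#'   for the per-sample cell proportions (length = number of cell types).
#'   Unequal vectors create cell-composition confounding between groups.
#' @param batch_labels,age_range,sex_ratio sample-sheet structure.
#' @param noise_sd beta-scale noise SD at beta = 0.5; noise is applied on the
#'   M scale as Gaussian with SD `noise_sd * 4 / log(2)` and back-transformed,
#'   keeping betas strictly inside (0, 1).
#' @param signal_probe_ids optional explicit probe ids to plant the
#'   signature at (overrides random placement; `n_signal_probes` is set to
#'   their count).
#' @param exclude_probes optional probe ids never used for the signature
#'   (e.g. to keep two cohorts' signatures disjoint).
#' @param seed RNG seed.
#' @return list of class `CohortDesign`.
#' @export
cohort_design <- function(n_cases = 11, n_controls = 44,
                          n_signal_probes = 1000, delta_beta = 0.15,
                          hyper_fraction = 0.8, cell_reference = NULL,
                          case_cell_alpha = NULL, control_cell_alpha = NULL,
                          batch_labels = c("batch1", "batch2"),
                          age_range = c(3, 19), sex_ratio = 0.5,
                          noise_sd = 0.05, signal_probe_ids = NULL,
                          exclude_probes = NULL, seed = 1L) {
  if (!is.null(signal_probe_ids))
    n_signal_probes <- length(signal_probe_ids)
  if (n_signal_probes > 0 && (delta_beta <= 0 || delta_beta >= 1))
    stopf("delta_beta must lie in (0, 1)")
  if (hyper_fraction < 0 || hyper_fraction > 1)
    stopf("hyper_fraction must lie in [0, 1]")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_signal_probes = n_signal_probes, delta_beta = delta_beta,
                 hyper_fraction = hyper_fraction,
                 cell_reference = cell_reference,
                 case_cell_alpha = case_cell_alpha,
                 control_cell_alpha = control_cell_alpha,
                 batch_labels = batch_labels, age_range = age_range,
                 sex_ratio = sex_ratio, noise_sd = noise_sd,
                 signal_probe_ids = signal_probe_ids,
                 exclude_probes = exclude_probes, seed = seed),
            class = "CohortDesign")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

logit2 <- function(b) log2(b / (1 - b))
expit2 <- function(m) 1 / (1 + 2^(-m))

#' Simulate a case/control methylation cohort
#'
#' Generates a [methylation_dataset()] from a manifest and a
#' [cohort_design()]: bimodal baseline betas, an optional cell-type mixture
#' layer at the reference probes, a planted signature (group-mean beta shift
#' of `delta_beta` at `n_signal_probes` autosomal probes, direction split by
#' `hyper_fraction`), logit-normal noise, and intensity pairs exactly
#' consistent with the betas (`beta = meth / (meth + unmeth)`, generator
#' offset 0). Sex-chromosome intensities follow the sample sex: chrY probes
#' sit at autosomal level in males and near background in females; chrX is
#' halved in males.
#'
#' The ground truth (signature probe ids and directions, true cell
#' proportions) is returned in the dataset's `truth` element.
#'
#' @param manifest a `ProbeManifest`.
#' @param design a `CohortDesign`.
#' @return a `MethylationDataset`.
#' @export
simulate_cohort <- function(manifest, design) {
  stopifnot(inherits(manifest, "ProbeManifest"),
            inherits(design, "CohortDesign"))
  P <- nrow(manifest)
  n <- design$n_cases + design$n_controls
  if (design$n_signal_probes > sum(!manifest$is_sex_chrom))
    stopf("n_signal_probes exceeds available autosomal probes")
  with_seed(design$seed, {
    ids <- c(sprintf("case_%02d", seq_len(design$n_cases)),
             sprintf("ctrl_%02d", seq_len(design$n_controls)))
    cohort <- rep(c("case", "control"),
                  c(design$n_cases, design$n_controls))
    n_male <- round(design$sex_ratio * n)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    samples <- data.frame(
      sample_id = ids,
      age = round(stats::runif(n, design$age_range[1], design$age_range[2]), 1),
      sex = sex,
      batch = rep_len(design$batch_labels, n),
      cohort = cohort, stringsAsFactors = FALSE
    )

    # bimodal baseline (most probes near 0 or 1)
    lowhigh <- stats::runif(P) < 0.5
    mu <- ifelse(lowhigh, stats::rbeta(P, 1, 20), stats::rbeta(P, 20, 1))
    mu <- pmin(pmax(mu, 0.02), 0.98)

    # cell-type mixture layer
    ref <- design$cell_reference
    cell_props <- NULL
    ref_idx <- integer(0)
    mean_beta <- matrix(mu, P, n)
    if (!is.null(ref)) {
      k <- nrow(ref)
      ca <- design$case_cell_alpha %||% rep(10, k)
      co <- design$control_cell_alpha %||% rep(10, k)
      cell_props <- rbind(rdirichlet(design$n_cases, ca),
                          rdirichlet(design$n_controls, co))
      rownames(cell_props) <- ids
      colnames(cell_props) <- rownames(ref)
      ref_idx <- match(colnames(ref), manifest$probe_id)
      if (anyNA(ref_idx))
        stopf("cell reference probes missing from manifest")
      mean_beta[ref_idx, ] <- t(ref) %*% t(cell_props)
    }

    # planted signature on autosomal, non-reference probes
    eligible <- setdiff(which(!manifest$is_sex_chrom), ref_idx)
    if (!is.null(design$exclude_probes))
      eligible <- setdiff(eligible,
                          match(design$exclude_probes, manifest$probe_id))
    if (!is.null(design$signal_probe_ids)) {
      sig_idx <- sort(match(design$signal_probe_ids, manifest$probe_id))
      if (anyNA(sig_idx)) stopf("signal_probe_ids missing from manifest")
    } else {
      sig_idx <- sort(sample(eligible, design$n_signal_probes))
    }
    n_hyper <- round(design$hyper_fraction * design$n_signal_probes)
    dir <- rep(-1, design$n_signal_probes)
    if (n_hyper > 0) dir[sample(design$n_signal_probes, n_hyper)] <- 1
    if (design$n_signal_probes > 0) {
      # give signature probes mid-range baselines with headroom
      base <- ifelse(dir > 0,
                     stats::runif(design$n_signal_probes, 0.20, 0.45),
                     stats::runif(design$n_signal_probes, 0.55, 0.80))
      mean_beta[sig_idx, ] <- base
      shifted <- base + dir * design$delta_beta
      if (any(shifted <= 0.01 | shifted >= 0.99))
        stopf("delta_beta pushes signature means outside (0, 1)")
      case_cols <- which(cohort == "case")
      mean_beta[sig_idx, case_cols] <- shifted
    }

    # logit-normal noise
    sd_m <- design$noise_sd * 4 / log(2)
    M <- logit2(mean_beta) + matrix(stats::rnorm(P * n, 0, sd_m), P, n)
    beta <- expit2(M)

    # intensities consistent with betas (offset 0); probe-level base
    # intensities span orders of magnitude, as on real arrays
    probe_level <- stats::rlnorm(P, log(5000), 0.8)
    total <- probe_level * matrix(stats::rlnorm(P * n, 0, 0.1), P, n)
    y_idx <- which(manifest$chrom == "chrY")
    x_idx <- which(manifest$chrom == "chrX")
    male <- samples$sex == "male"
    if (length(y_idx)) {
      total[y_idx, !male] <- total[y_idx, !male] * 0.05
    }
    if (length(x_idx)) {
      total[x_idx, male] <- total[x_idx, male] * 0.5
    }
    meth <- beta * total
    unmeth <- (1 - beta) * total
    dimnames(meth) <- dimnames(unmeth) <- dimnames(beta) <-
      list(manifest$probe_id, ids)
    detection_p <- matrix(stats::runif(P * n, 0, 0.005), P, n,
                          dimnames = list(manifest$probe_id, ids))

    methylation_dataset(
      manifest = manifest, meth = meth, unmeth = unmeth, beta = beta,
      detection_p = detection_p, samples = samples, offset = 0,
      truth = list(signal_probes = manifest$probe_id[sig_idx],
                   signal_direction = stats::setNames(dir,
                                                      manifest$probe_id[sig_idx]),
                   cell_props = cell_props, deletions = list())
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant a heterozygous-style deletion into a dataset
#'
#' Multiplies the methylated and unmethylated intensities of every probe
#' inside `interval` by `intensity_factor` for the listed samples (0.5
#' emulates a one-copy loss; a mosaic loss uses a factor nearer 1). Betas are
#' untouched, as a copy-number change scales both channels equally.
#'
#' @param dataset a `MethylationDataset`.
#' @param sample_ids samples carrying the deletion.
#' @param interval a [genomic_interval()] on a manifest chromosome.
#' @param intensity_factor multiplicative factor in (0, 1].
#' @return the modified dataset, with the planted deletion recorded in
#'   `truth$deletions`.
#' @export
plant_deletion <- function(dataset, sample_ids, interval,
                           intensity_factor = 0.5) {
  stopifnot(inherits(dataset, "MethylationDataset"),
            inherits(interval, "GenomicInterval"))
  if (intensity_factor <= 0 || intensity_factor > 1)
    stopf("intensity_factor must lie in (0, 1]")
  missing <- setdiff(sample_ids, dataset$samples$sample_id)
  if (length(missing))
    stopf("unknown sample id(s): %s", paste(missing, collapse = ", "))
  man <- dataset$manifest
  hit <- which(man$chrom == interval$chrom & man$pos >= interval$start &
                 man$pos <= interval$end)
  if (!length(hit)) {
    warnf("planted interval overlaps no probes; dataset unchanged")
    return(dataset)
  }
  cols <- match(sample_ids, dataset$samples$sample_id)
  dataset$meth[hit, cols] <- dataset$meth[hit, cols] * intensity_factor
  dataset$unmeth[hit, cols] <- dataset$unmeth[hit, cols] * intensity_factor
  dataset$truth$deletions <- c(dataset$truth$deletions,
                               list(list(sample_ids = sample_ids,
                                         interval = interval,
                                         intensity_factor = intensity_factor)))
  dataset
}

#' Plate simulation design
#'
#' @param n_case_lines,n_control_lines numbers of cell lines per group.
#' @param affected_wells character vector of well keys (`"<plate>:<well>"`,
#'   e.g. `"PM-M6:E03"`) whose case-line signal is shifted.
#' @param effect_size downward shift (OD units) applied to affected wells in
#'   case lines; the planted effect is reduced dye reduction (less NADH).
#' @param n_timepoints kinetic points per well (15-min reads over 24 h).
#' @param noise_sd OD noise SD.
#' @param seed RNG seed.
#' @return list of class `PlateDesign`.
#' @export
plate_design <- function(n_case_lines = 11, n_control_lines = 50,
                         affected_wells = character(0), effect_size = 0.3,
                         n_timepoints = 96, noise_sd = 0.05, seed = 1L) {
  if (n_timepoints < 2) stopf("n_timepoints must be at least 2")
  structure(list(n_case_lines = n_case_lines,
                 n_control_lines = n_control_lines,
                 affected_wells = affected_wells, effect_size = effect_size,
                 n_timepoints = n_timepoints, noise_sd = noise_sd,
                 seed = seed),
            class = "PlateDesign")
}

#' Simulate a phenotype-microarray experiment
#'
#' Generates endpoint (A590/A750) readings — and optionally full kinetic
#' series — for every analyzed well of the layout, for case and control cell
#' lines plus a media-only blank triplicate per plate. Each well has a
#' latent dye-reduction amplitude; affected wells in case lines are shifted
#' down by `design$effect_size`. Kinetic curves are scaled logistics in time
#' with additive Gaussian noise.
#'
#' @param layout a [plate_layout()].
#' @param design a [plate_design()].
#' @param kinetics logical; also simulate per-well kinetic series (stored as
#'   a lines x wells x timepoints array).
#' @return list of class `PlateExperiment` with elements `layout`, `lines`
#'   (line_id, cohort), `endpoints` (long data.frame), `blanks`, `kinetics`
#'   and `truth`.
#' @export
simulate_plate_run <- function(layout, design, kinetics = FALSE) {
  stopifnot(inherits(layout, "PlateLayout"), inherits(design, "PlateDesign"))
  unknown <- setdiff(design$affected_wells, layout$wells$key)
  if (length(unknown))
    stopf("affected wells not in layout: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  if (design$n_timepoints != layout$n_timepoints)
    warnf("design n_timepoints (%d) differs from layout expectation (%d)",
          design$n_timepoints, layout$n_timepoints)
  with_seed(design$seed, {
    lines <- data.frame(
      line_id = c(sprintf("case_line_%02d", seq_len(design$n_case_lines)),
                  sprintf("ctrl_line_%02d", seq_len(design$n_control_lines))),
      cohort = rep(c("case", "control"),
                   c(design$n_case_lines, design$n_control_lines)),
      stringsAsFactors = FALSE
    )
    W <- nrow(layout$wells)
    L <- nrow(lines)
    baseline_a750 <- 0.20
    blank_offset <- 0.10
    well_amp <- stats::runif(W, 0.5, 1.2)  # latent per-well dye reduction
    amp <- matrix(well_amp, L, W, byrow = TRUE)
    aff <- layout$wells$key %in% design$affected_wells
    amp[lines$cohort == "case", aff] <-
      pmax(amp[lines$cohort == "case", aff] - design$effect_size, 0.02)
    noise <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0,
                                                  design$noise_sd), nr, nc)
    a750 <- baseline_a750 + abs(noise(L, W)) * 0.2
    a590 <- a750 + blank_offset + amp + noise(L, W)
    endpoints <- data.frame(
      line_id = rep(lines$line_id, times = W),
      cohort = rep(lines$cohort, times = W),
      plate = rep(layout$wells$plate, each = L),
      well = rep(layout$wells$well, each = L),
      key = rep(layout$wells$key, each = L),
      a590 = as.vector(a590), a750 = as.vector(a750),
      stringsAsFactors = FALSE
    )
    blanks <- do.call(rbind, lapply(1:3, function(r) {
      b750 <- baseline_a750 + abs(stats::rnorm(W, 0, design$noise_sd)) * 0.2
      data.frame(rep = r, plate = layout$wells$plate,
                 well = layout$wells$well, key = layout$wells$key,
                 a590 = b750 + blank_offset +
                   stats::rnorm(W, 0, design$noise_sd / sqrt(3)),
                 a750 = b750, stringsAsFactors = FALSE)
    }))
    kin <- NULL
    if (kinetics) {
      tt <- seq_len(design$n_timepoints) * (layout$dt_min / 60)
      logi <- 1 / (1 + exp(-(tt - 8) / 3))
      kin <- array(0, c(L, W, design$n_timepoints),
                   dimnames = list(lines$line_id, layout$wells$key, NULL))
      for (j in seq_len(W)) {
        kin[, j, ] <- outer(amp[, j], logi) +
          matrix(stats::rnorm(L * design$n_timepoints, 0, design$noise_sd),
                 L, design$n_timepoints)
      }
    }
    structure(list(layout = layout, lines = lines, endpoints = endpoints,
                   blanks = blanks, kinetics = kin,
                   truth = list(affected_wells = design$affected_wells,
                                effect_size = design$effect_size)),
              class = "PlateExperiment")
  })
}

#' Isolated-cell-type beta profiles
#'
#' Builds one synthetic "pure cell population" sample per reference cell
#' type: a base sample's betas with the reference probes overwritten by
#' that cell type's profile. Used to check that a classifier trained on
#' whole-blood profiles is not driven by cell composition.
#'
#' @param dataset a `MethylationDataset`.
#' @param reference a `CellReference` whose probes are in the dataset.
#' @param base_sample sample id providing the non-reference betas
#'   (defaults to the first control).
#' @return probes x cell-types beta matrix.
#' @export
pure_cell_profiles <- function(dataset, reference, base_sample = NULL) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (is.null(base_sample))
    base_sample <- dataset$samples$sample_id[
      dataset$samples$cohort == "control"][1]
  b <- dataset$beta[, base_sample]
  idx <- match(colnames(reference), rownames(dataset$beta))
  if (anyNA(idx)) stopf("reference probes missing from dataset")
  out <- vapply(seq_len(nrow(reference)), function(i) {
    v <- b
    v[idx] <- reference[i, ]
    v
  }, numeric(length(b)))
  dimnames(out) <- list(rownames(dataset$beta), rownames(reference))
  out
}

# ---- plain-text writers -----------------------------------------------------

#' Write synthetic-data objects to plain-text files
#'
#' TSV for manifests and probe-by-sample matrices, CSV for sample sheets and
#' long-form plate endpoints, BED (0-based half-open) for genomic intervals.
#'
#' @param x object to write.
#' @param path output file path.
#' @name episcan-writers
NULL

#' @rdname episcan-writers
#' @export
write_manifest_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname episcan-writers
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname episcan-writers
#' @export
write_sample_sheet_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname episcan-writers
#' @param intervals list of `GenomicInterval`s.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "GenomicInterval")) intervals <- list(intervals)
  df <- do.call(rbind, lapply(intervals, function(iv) {
    data.frame(chrom = iv$chrom, start = iv$start - 1L, end = iv$end,
               name = iv$label %||% ".", stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname episcan-writers
#' @export
write_plate_csv <- function(x, path) {
  stopifnot(inherits(x, "PlateExperiment"))
  utils::write.csv(x$endpoints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
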