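# Phenotype-microarray (Biolog PM-M) statistics: plate layout model, blank
# normalization, kinetic parameters, per-well rank tests with BH correction.

#' Phenotype-microarray plate layout
#'
#' Models the analyzed wells of a PM-M experiment: eight 96-well plates
#' (PM-M1 to PM-M4 hold energy sources, PM-M5 to PM-M8 metabolic
#' effectors) plus the custom tryptophan plate, of which 8 distinct well
#' contents per line enter the analysis (glucose, empty well, tryptophan
#' and 5 tryptophan dipeptides) — 776 analyzed wells in total. Kinetic
#' reads arrive every `dt_min` minutes over 24 h (`n_timepoints` points).
#'
#' @param n_timepoints kinetic series length (default 96).
#' @param dt_min read interval in minutes (default 15).
#' @return list of class `PlateLayout` with `wells` (plate, well, key,
#'   category), `n_timepoints`, `dt_min`.
#' @export
plate_layout <- function(n_timepoints = 96, dt_min = 15) {
  pm_wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
  plates <- sprintf("PM-M%d", 1:8)
  wells <- do.call(rbind, lapply(plates, function(p) {
    data.frame(plate = p, well = pm_wells,
               category = if (p %in% sprintf("PM-M%d", 1:4))
                 "energy_source" else "metabolic_effector",
               stringsAsFactors = FALSE)
  }))
  trp <- data.frame(plate = "PM-Trp",
                    well = c("glucose", "empty", "tryptophan", "trp_gly",
                             "trp_lys", "trp_leu", "trp_arg", "trp_ala"),
                    category = "tryptophan", stringsAsFactors = FALSE)
  wells <- rbind(wells, trp)
  wells$key <- paste(wells$plate, wells$well, sep = ":")
  structure(list(wells = wells, n_timepoints = n_timepoints,
                 dt_min = dt_min),
            class = "PlateLayout")
}

#' Relative absorbance
#'
#' `A590 - A750`: the dye's absorbance peak minus the background reading.
#'
#' @param a590,a750 endpoint readings (vectorised).
#' @return relative absorbance.
#' @export
relative_absorbance <- function(a590, a750) a590 - a750

#' Normalize well readings to the blank-plate triplicate
#'
#' Subtracts the mean of the blank (media-only) readings per well, floors
#' the difference at `floor` to keep the logarithm finite, and transforms
#' to `log_base`.
#'
#' @param values named numeric vector of per-well relative absorbances.
#' @param blank_values matrix or data.frame of blank relative absorbances,
#'   wells x replicates (a triplicate is expected; other counts are used
#'   with a warning), rownames matching `names(values)`.
#' @param floor lower bound applied before the log (default 1e-3).
#' @param log_base logarithm base (default 10).
#' @return named vector of normalized log-scale values.
#' @export
normalize_to_blank <- function(values, blank_values, floor = 1e-3,
                               log_base = 10) {
  blank_values <- as.matrix(blank_values)
  if (ncol(blank_values) != 3)
    warnf("expected a blank triplicate, got %d replicate(s); using their mean",
          ncol(blank_values))
  bm <- rowMeans(blank_values)
  if (!is.null(names(values)) && !is.null(rownames(blank_values)))
    bm <- bm[names(values)]
  log(pmax(values - bm, floor), base = log_base)
}

#' Kinetic parameters of a well's OD series
#'
#' @param series optical densities at equal spacing.
#' @param dt_min read interval in minutes (default 15).
#' @return named vector: `slope` (least-squares slope, OD/hour),
#'   `endpoint` (final OD), `auc` (trapezoidal integral, OD*hour).
#' @export
kinetic_params <- function(series, dt_min = 15) {
  n <- length(series)
  if (n < 2) stopf("need at least 2 kinetic points")
  tt <- (seq_len(n) - 1) * dt_min / 60
  slope <- stats::cov(tt, series) / stats::var(tt)
  auc <- sum((series[-1] + series[-n]) / 2) * dt_min / 60
  c(slope = slope, endpoint = series[n], auc = auc)
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration p-value for small samples (`n_x + n_y <= 12`, no
#' ties); otherwise the normal approximation with tie and continuity
#' correction. Identical constant groups give p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` (the Mann-Whitney U for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (max(c(x, y)) == min(c(x, y)))
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = (length(x) + length(y) <= 12) && !ties,
    correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-well case/control comparison across a plate experiment
#'
#' For every analyzed well of the layout: endpoint relative absorbances
#' are blank-normalized and log-transformed, case and control lines are
#' compared by the two-sided Mann-Whitney test, and p-values are
#' BH-adjusted across all analyzed wells. The summary counts significant
#' wells (q < `alpha`) overall, by direction, and within the
#' PM-M6 to PM-M8 metabolic-effector block (288 wells).
#'
#' @param experiment a `PlateExperiment` (see [simulate_plate_run()]), or
#'   any list with `layout`, `endpoints` (line_id, cohort, plate, well,
#'   key, a590, a750) and `blanks` (rep, key, a590, a750).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param floor,log_base normalization parameters.
#' @return list with `results` (`WellResult` data.frame: plate, well, key,
#'   category, n_case, n_control, mean_case, mean_control, direction, U,
#'   p, q) and `summary` (well counts and significant fractions).
#' @export
compare_wells <- function(experiment, alpha = 0.05, floor = 1e-3,
                          log_base = 10) {
  layout <- experiment$layout
  ep <- experiment$endpoints
  bl <- experiment$blanks
  ep$rel <- relative_absorbance(ep$a590, ep$a750)
  bl$rel <- relative_absorbance(bl$a590, bl$a750)
  blank_mean <- tapply(bl$rel, bl$key, mean)
  n_reps <- unique(table(bl$key))
  if (!identical(as.integer(n_reps), 3L))
    warnf("blank plates are not a triplicate; using the available mean")
  rows <- vector("list", nrow(layout$wells))
  missing_wells <- character(0)
  for (i in seq_len(nrow(layout$wells))) {
    key <- layout$wells$key[i]
    sub <- ep[ep$key == key, , drop = FALSE]
    if (!nrow(sub)) {
      missing_wells <- c(missing_wells, key)
      next
    }
    val <- log(pmax(sub$rel - blank_mean[[key]], floor), base = log_base)
    xc <- val[sub$cohort == "case"]
    yc <- val[sub$cohort == "control"]
    if (length(xc) < 2 || length(yc) < 2)
      stopf("need at least 2 lines per group (well %s)", key)
    mw <- mann_whitney(xc, yc)
    rows[[i]] <- data.frame(
      plate = layout$wells$plate[i], well = layout$wells$well[i],
      key = key, category = layout$wells$category[i],
      n_case = length(xc), n_control = length(yc),
      mean_case = mean(xc), mean_control = mean(yc),
      direction = if (mean(xc) <= mean(yc)) "lower" else "higher",
      U = mw$U, p = mw$p, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  res$q <- adjust_bh(res$p)
  rownames(res) <- NULL
  class(res) <- c("WellResult", "data.frame")
  sig <- res$q < alpha
  block <- res$plate %in% sprintf("PM-M%d", 6:8)
  summary <- list(
    n_wells = nrow(res),
    n_missing = length(missing_wells),
    n_significant = sum(sig),
    frac_significant = mean(sig),
    n_significant_lower = sum(sig & res$direction == "lower"),
    n_significant_higher = sum(sig & res$direction == "higher"),
    n_effector_block = sum(block),
    n_effector_block_significant = sum(sig & block)
  )
  list(results = res, summary = summary)
}
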