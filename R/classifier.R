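# MVP (methylation variant pathogenicity) classifier: feature selection,
# one-vs-rest linear SVMs with cross-validated cost selection, and Platt
# sigmoid calibration of decision values into per-class scores in [0, 1].

#' Select classifier feature probes
#'
#' Probes within the shared-platform mask whose absolute group-mean beta
#' difference between cases and controls is at least `min_diff`.
#'
#' @param betas probes x samples matrix.
#' @param case_ids,control_ids column ids of the two groups.
#' @param min_diff minimum absolute mean beta difference (default 0.10,
#'   `>=`).
#' @param shared_mask optional probe-id vector restricting the candidates
#'   (e.g. probes shared by two array platforms).
#' @return character vector of selected probe ids.
#' @export
select_features <- function(betas, case_ids, control_ids, min_diff = 0.10,
                            shared_mask = NULL) {
  probes <- rownames(betas)
  if (!is.null(shared_mask)) probes <- intersect(probes, shared_mask)
  b <- betas[probes, , drop = FALSE]
  d <- rowMeans(b[, case_ids, drop = FALSE]) -
    rowMeans(b[, control_ids, drop = FALSE])
  sel <- probes[abs(d) >= min_diff]
  if (!length(sel))
    stopf("no probes pass min_diff = %g; consider lowering the threshold",
          min_diff)
  sel
}

# Platt sigmoid fit (Newton with backtracking, after Lin/Weng/Keerthi):
# finds (A, B) minimising the smoothed-target cross-entropy of
# p = 1 / (1 + exp(A*f + B)) against y (logical: target class).
platt_fit <- function(f, y, max_iter = 100, min_step = 1e-10,
                      sigma = 1e-12) {
  prior1 <- sum(y)
  prior0 <- length(y) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  tt <- ifelse(y, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  nll <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0, tt * fApB + log1p(exp(-fApB)),
               (tt - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- nll(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    d2 <- p * (1 - p)
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    d1 <- tt - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= min_step) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- nll(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < min_step) break
  }
  c(A = A, B = B)
}

platt_score <- function(f, ab) 1 / (1 + exp(ab["A"] * f + ab["B"]))

# Linear binary SVM for one class vs the rest; returns an oriented
# (w, b) with positive decision values for the target class.
fit_ovr_svm <- function(X, is_class, cost) {
  y <- factor(ifelse(is_class, "target", "rest"),
              levels = c("target", "rest"))
  m <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  f <- drop(X %*% w + b)
  if (mean(f[is_class]) < mean(f[!is_class])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

#' Train the MVP classification model
#'
#' One-vs-rest linear SVMs over selected feature probes. The SVM cost `C`
#' is chosen by k-fold cross-validation over `c_grid` (ties broken towards
#' the smaller, i.e. more regularised, cost). Per-class Platt sigmoids are
#' fit on the cross-validated (out-of-fold) decision values at the chosen
#' cost, so the calibrated scores are not optimistic resubstitution
#' values. Deterministic for a fixed seed.
#'
#' @param X samples x features matrix (feature probes as colnames).
#' @param y class labels (e.g. "case"/"control"; two or more classes).
#' @param c_grid candidate SVM costs.
#' @param folds cross-validation folds (reduced with a warning when a class
#'   is smaller).
#' @param seed RNG seed for fold assignment.
#' @param control_class label whose training means are stored for missing-
#'   probe imputation at scoring time (defaults to "control" when present).
#' @return list of class `MvpModel`: `feature_probes`, `classes`, `weights`
#'   (features x classes), `bias`, `platt` (A, B per class), `cost`,
#'   `cv_accuracy`, `cv_scores` (out-of-fold calibrated scores), `seed`,
#'   `impute_means`.
#' @export
train_mvp <- function(X, y, c_grid = c(0.01, 0.1, 1, 10), folds = 10,
                      seed = 1L, control_class = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stopf("need at least 2 classes")
  min_class <- min(table(y))
  if (min_class < folds) {
    warnf("smallest class has %d members; reducing folds from %d to %d",
          min_class, folds, max(2, min_class))
    folds <- max(2, min_class)
  }
  n <- nrow(X)
  with_seed(seed, {
    # stratified fold assignment
    fold <- integer(n)
    for (cl in classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    cv_dec <- array(NA_real_, c(n, length(classes), length(c_grid)),
                    dimnames = list(NULL, classes, NULL))
    for (ci in seq_along(c_grid)) {
      for (k in seq_len(folds)) {
        tr <- fold != k
        for (cl in classes) {
          sv <- fit_ovr_svm(X[tr, , drop = FALSE], y[tr] == cl, c_grid[ci])
          cv_dec[!tr, cl, ci] <- X[!tr, , drop = FALSE] %*% sv$w + sv$b
        }
      }
    }
    acc <- vapply(seq_along(c_grid), function(ci) {
      pred <- classes[max.col(cv_dec[, , ci], ties.method = "first")]
      mean(pred == y)
    }, numeric(1))
    best <- which(acc >= max(acc) - 1e-12)
    ci <- best[which.min(c_grid[best])]
    cost <- c_grid[ci]

    platt <- lapply(classes, function(cl)
      platt_fit(cv_dec[, cl, ci], y == cl))
    names(platt) <- classes
    cv_scores <- vapply(classes, function(cl)
      unname(platt_score(cv_dec[, cl, ci], platt[[cl]])), numeric(n))

    fits <- lapply(classes, function(cl) fit_ovr_svm(X, y == cl, cost))
    weights <- vapply(fits, function(f) f$w, numeric(ncol(X)))
    dimnames(weights) <- list(colnames(X), classes)
    bias <- stats::setNames(vapply(fits, function(f) f$b, numeric(1)),
                            classes)
    if (is.null(control_class))
      control_class <- if ("control" %in% classes) "control" else classes[1]
    impute_means <- colMeans(X[y == control_class, , drop = FALSE])

    structure(list(feature_probes = colnames(X), classes = classes,
                   weights = weights, bias = bias, platt = platt,
                   cost = cost, cv_accuracy = acc[ci],
                   cv_scores = cv_scores, y = y, seed = seed,
                   impute_means = impute_means),
              class = "MvpModel")
  })
}

#' Score samples with an MVP model
#'
#' Applies the per-class linear decision functions and Platt sigmoids to
#' new samples, yielding a score in `[0, 1]` per class; the predicted class
#' is the one with the greatest score. Feature probes missing from the
#' input (at most 10%) are imputed with the training control means.
#'
#' @param model an `MvpModel`.
#' @param betas probes x samples beta matrix covering the feature probes.
#' @return data.frame of class `MvpScore`: sample_id, one score column per
#'   class, `predicted`.
#' @export
mvp_score <- function(model, betas) {
  stopifnot(inherits(model, "MvpModel"))
  feats <- model$feature_probes
  idx <- match(feats, rownames(betas))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0.10 * length(feats))
    stopf("%d of %d feature probes missing (> 10%%)", n_missing,
          length(feats))
  Xs <- matrix(NA_real_, ncol(betas), length(feats),
               dimnames = list(colnames(betas), feats))
  present <- !is.na(idx)
  Xs[, present] <- t(betas[idx[present], , drop = FALSE])
  if (n_missing > 0) {
    warnf("imputing %d missing feature probe(s) with training control means",
          n_missing)
    Xs[, !present] <- matrix(model$impute_means[!present], nrow(Xs),
                             n_missing, byrow = TRUE)
  }
  dec <- Xs %*% model$weights +
    matrix(model$bias, nrow(Xs), length(model$classes), byrow = TRUE)
  scores <- vapply(model$classes, function(cl)
    unname(platt_score(dec[, cl], model$platt[[cl]])),
    numeric(nrow(Xs)))
  scores <- matrix(scores, nrow(Xs), length(model$classes),
                   dimnames = list(rownames(Xs), model$classes))
  out <- data.frame(sample_id = rownames(Xs), scores,
                    predicted = model$classes[max.col(scores,
                                                      ties.method = "first")],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("MvpScore", "data.frame")
  out
}

#' Classical multidimensional scaling embedding
#'
#' Torgerson MDS of the pairwise Euclidean distances between samples;
#' deterministic up to rotation/reflection, and exact for data of rank
#' `<= k`.
#'
#' @param x samples x features matrix (at least 3 samples).
#' @param k embedding dimension (default 2).
#' @return samples x k coordinate matrix.
#' @export
mds_embed <- function(x, k = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stopf("need at least 3 samples")
  d <- stats::dist(x)
  if (max(d) < 1e-12) {
    warnf("degenerate input: all samples identical; returning zeros")
    out <- matrix(0, nrow(x), k, dimnames = list(rownames(x), NULL))
    return(out)
  }
  co <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(co) < k) co <- cbind(co, matrix(0, nrow(co), k - ncol(co)))
  rownames(co) <- rownames(x)
  co
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's criterion on Euclidean distances,
#' cut at `k` clusters.
#'
#' @param x samples x features matrix.
#' @param k number of clusters.
#' @return list with `labels` (cluster assignment) and `tree` (the
#'   `hclust` object).
#' @export
ward_cluster <- function(x, k = 2) {
  x <- as.matrix(x)
  if (k > nrow(x)) stopf("k (%d) exceeds sample count (%d)", k, nrow(x))
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  list(labels = stats::cutree(tree, k = k), tree = tree)
}

#' Leave-two-out cross-validation of the epi-signature
#'
#' Enumerates every pair of cases; for each fold the remaining cases and
#' the controls re-select signature probes ([select_features()]), all
#' samples are embedded by MDS on those probes, and each held-out case is
#' assigned to the nearer of the training-case and control centroids.
#'
#' @param case_betas probes x cases beta matrix (n >= 3 cases).
#' @param control_betas probes x controls beta matrix.
#' @param min_diff feature-selection threshold (default 0.10).
#' @param k MDS dimension (default 2).
#' @return list with `folds` (data.frame: fold, held_out, assigned —
#'   two rows per fold), `n_folds`, and `n_correct` (folds where both
#'   held-out cases joined the case centroid).
#' @export
leave_two_out <- function(case_betas, control_betas, min_diff = 0.10,
                          k = 2) {
  n <- ncol(case_betas)
  if (n < 3) stopf("need at least 3 cases")
  pairs <- utils::combn(n, 2)
  case_ids <- colnames(case_betas)
  ctrl_ids <- colnames(control_betas)
  all_betas <- cbind(case_betas, control_betas)
  rows <- vector("list", ncol(pairs))
  for (f in seq_len(ncol(pairs))) {
    held <- pairs[, f]
    train_cases <- case_ids[-held]
    feats <- select_features(all_betas, train_cases, ctrl_ids,
                             min_diff = min_diff)
    emb <- mds_embed(t(all_betas[feats, , drop = FALSE]), k = k)
    cen_case <- colMeans(emb[train_cases, , drop = FALSE])
    cen_ctrl <- colMeans(emb[ctrl_ids, , drop = FALSE])
    assigned <- vapply(case_ids[held], function(s) {
      dc <- sum((emb[s, ] - cen_case)^2)
      dk <- sum((emb[s, ] - cen_ctrl)^2)
      if (dc < dk) "case" else "control"
    }, character(1))
    rows[[f]] <- data.frame(fold = f, held_out = case_ids[held],
                            assigned = unname(assigned),
                            n_train_cases = length(train_cases),
                            stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, rows)
  correct <- tapply(folds$assigned == "case", folds$fold, all)
  list(folds = folds, n_folds = ncol(pairs),
       n_correct = sum(correct))
}

#' Serialise / restore an MVP model as JSON
#'
#' @param model an `MvpModel`.
#' @param path JSON file path.
#' @return `write_mvp_model` returns `path`; `read_mvp_model` the model.
#' @export
write_mvp_model <- function(model, path) {
  stopifnot(inherits(model, "MvpModel"))
  obj <- list(feature_probes = model$feature_probes,
              classes = model$classes,
              weights = as.data.frame(model$weights),
              bias = as.list(model$bias),
              platt = lapply(model$platt, as.list),
              cost = model$cost, cv_accuracy = model$cv_accuracy,
              seed = model$seed,
              impute_means = as.list(model$impute_means))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mvp_model
#' @export
read_mvp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.matrix(obj$weights)
  rownames(w) <- obj$feature_probes
  structure(list(feature_probes = obj$feature_probes,
                 classes = obj$classes, weights = w,
                 bias = unlist(obj$bias),
                 platt = lapply(obj$platt, unlist),
                 cost = obj$cost, cv_accuracy = obj$cv_accuracy,
                 seed = obj$seed, impute_means = unlist(obj$impute_means)),
            class = "MvpModel")
}
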