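# Reference-based blood cell-type deconvolution: project each sample's betas
# onto cell-type reference profiles under the constraints w >= 0, sum(w) <= 1.

# Exact solution of min ||y - A w||^2 s.t. w >= 0, sum(w) <= 1 for small k
# by enumerating active sets (each subset of zeroed coordinates, with the sum
# constraint active or not) and keeping the feasible candidate with the
# smallest objective. The optimum of this convex QP is the equality-solve of
# its own active set, so enumeration finds it exactly.
solve_simplex_ls <- function(A, y, tol = 1e-9) {
  k <- ncol(A)
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  best <- NULL
  best_obj <- Inf
  consider <- function(w) {
    if (any(w < -tol) || sum(w) > 1 + tol) return()
    w <- pmax(w, 0)
    obj <- sum((y - A %*% w)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <<- obj
      best <<- w
    }
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  for (i in seq_len(nrow(subsets))) {
    free <- which(!unlist(subsets[i, ]))
    w <- numeric(k)
    if (length(free) == 0) {
      consider(w)
      next
    }
    G <- AtA[free, free, drop = FALSE]
    # sum constraint inactive
    wf <- tryCatch(solve(G, Aty[free]), error = function(e) NULL)
    if (!is.null(wf)) {
      w[ ] <- 0; w[free] <- wf
      consider(w)
    }
    # sum constraint active: KKT system with one equality
    nf <- length(free)
    K <- rbind(cbind(2 * G, rep(1, nf)), c(rep(1, nf), 0))
    rhs <- c(2 * Aty[free], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      w[ ] <- 0; w[free] <- sol[seq_len(nf)]
      consider(w)
    }
  }
  best
}

#' Estimate blood cell-type proportions
#'
#' Houseman-style reference-based deconvolution: each sample's betas at the
#' reference's discriminating probes are regressed on the cell-type profiles
#' under the constraints that proportions are non-negative and sum to at
#' most one (projection onto the constrained set). The constrained least
#' squares is solved exactly for the small number of cell types by
#' active-set enumeration.
#'
#' @param sample_betas matrix of betas (probes x samples, probe ids as
#'   rownames) or a named vector for a single sample; must cover the
#'   reference probes.
#' @param reference cell-type reference matrix (cell types x probes), e.g.
#'   from [make_cell_reference()] or a real sorted-cell reference.
#' @return matrix (samples x cell types) of class `CellProportions`.
#' @export
estimate_cell_proportions <- function(sample_betas, reference) {
  if (is.null(dim(sample_betas)))
    sample_betas <- matrix(sample_betas, ncol = 1,
                           dimnames = list(names(sample_betas), "sample"))
  probes <- colnames(reference)
  idx <- match(probes, rownames(sample_betas))
  if (anyNA(idx))
    stopf("sample betas do not cover %d reference probes", sum(is.na(idx)))
  A <- t(reference[, , drop = FALSE])        # probes x cell types
  class(A) <- "matrix"
  if (qr(A)$rank < ncol(A)) stopf("cell reference is rank-deficient")
  Y <- sample_betas[idx, , drop = FALSE]
  props <- t(apply(Y, 2, function(y) solve_simplex_ls(A, y)))
  colnames(props) <- rownames(reference)
  rownames(props) <- colnames(sample_betas)
  class(props) <- c("CellProportions", class(props))
  props
}
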