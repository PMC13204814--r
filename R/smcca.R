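#' Soft-thresholding operator
#'
#' Elementwise `sign(x) * max(|x| - d, 0)`, the proximal map of the L1
#' penalty and the basic shrinkage step of the penalized matrix
#' decomposition.
#'
#' @param x numeric vector.
#' @param d nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' softThreshold(c(-2, 1, 0.3), 1) # -1 0 0
softThreshold <- function(x, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0) {
    stop("threshold d must be a single nonnegative number")
  }
  cpp_soft_threshold(as.numeric(x), d)
}

#' Projection onto the L1/L2 constraint set
#'
#' Returns `w = S(x, d) / ||S(x, d)||_2` with the smallest `d >= 0` such
#' that `||w||_1 <= c` (found by bisection); this `w` maximizes `x'w`
#' subject to `||w||_2 <= 1` and `||w||_1 <= c`.
#'
#' @param x nonzero numeric vector.
#' @param c L1 budget, `1 <= c <= sqrt(length(x))`.
#' @return unit-L2, L1-feasible weight vector.
#' @export
#' @examples
#' projectL1(c(3, 0, 0), 1)       # one-hot
#' projectL1(c(1, 1), sqrt(2))    # plain L2 normalization
projectL1 <- function(x, c) {
  x <- as.numeric(x)
  if (all(x == 0)) stop("projectL1 is undefined for the all-zero vector")
  if (c < 1 - 1e-9 || c > sqrt(length(x)) + 1e-9) {
    stop("L1 budget c must lie in [1, sqrt(length(x))]")
  }
  cpp_l1_project(x, c)
}

#' Cross-product matrices of a block set
#'
#' Computes `C_ij = X_i' X_j` for every block pair on the standardized
#' matrices (covariance-style, identity within-block metric).
#'
#' @param x a [BlockSet-class] or list of aligned matrices.
#' @return named list of upper-pair cross-product matrices
#'   (`"i:j"` entries).
#' @export
crossProducts <- function(x) {
  X <- asBlockMatrices(x)
  K <- length(X)
  nms <- names(X)
  if (is.null(nms)) nms <- as.character(seq_len(K))
  out <- list()
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      out[[paste(nms[i], nms[j], sep = ":")]] <- crossprod(X[[i]], X[[j]])
    }
  }
  out
}

#' Deflate cross-product matrices by a fitted component
#'
#' For every pair, `C_ij <- C_ij - d_ij w_i w_j'` with
#' `d_ij = w_i' C_ij w_j`, removing the fitted dimension's contribution
#' before the next dimension is extracted.
#'
#' @param C named list of cross-products, as from [crossProducts()].
#' @param weights list of per-block weight vectors for one dimension.
#' @return deflated list of cross-products.
#' @export
deflateCrossProducts <- function(C, weights) {
  K <- length(weights)
  nms <- names(weights)
  if (is.null(nms)) nms <- as.character(seq_len(K))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      key <- paste(nms[i], nms[j], sep = ":")
      Cij <- C[[key]]
      wi <- weights[[i]]
      wj <- weights[[j]]
      if (nrow(Cij) != length(wi) || ncol(Cij) != length(wj)) {
        stop("shape mismatch between cross-products and weights")
      }
      dij <- drop(crossprod(wi, Cij %*% wj))
      C[[key]] <- Cij - dij * tcrossprod(wi, wj)
    }
  }
  C
}

#' Fit sparse multiple CCA by penalized matrix decomposition
#'
#' Cyclic block coordinate ascent on the summed bilinear objective
#' `sum_{i<j} w_i' X_i' X_j w_j` under per-block unit-L2 and L1 budget
#' constraints, with deflation between successive dimensions. Each block
#' update is the exact L1/L2 projection of the combined cross-covariance
#' direction, so the objective is non-decreasing across sweeps.
#'
#' Initialization is deterministic: the leading right singular vector of
#' each block, plus a small set of one-hot starts at the strongest
#' coordinates of blocks 2..K (the solution with the highest objective is
#' kept; the extra starts guard against non-global fixed points of the
#' non-convex objective at strong sparsity).
#'
#' Per dimension, block weight signs are flipped to maximize the sum of
#' pairwise score correlations, then the largest-magnitude weight of the
#' first block is made positive. Reported correlations are Pearson
#' correlations of the realized score vectors `X_i w_i`.
#'
#' @param x a [BlockSet-class] or list of standardized aligned matrices.
#' @param penalties per-block L1 budgets, each in `[1, sqrt(p_block)]`.
#' @param nDims number of dimensions to extract.
#' @param tol convergence tolerance on the maximum elementwise weight
#'   change per sweep.
#' @param maxIter maximum number of sweeps per dimension.
#' @param extraStarts number of one-hot initializations per non-leading
#'   block (0 disables multi-start).
#' @return an [SmccaFit-class].
#' @export
fitSmcca <- function(x, penalties, nDims = 1, tol = 1e-6, maxIter = 25,
                     extraStarts = 2) {
  X <- asBlockMatrices(x)
  K <- length(X)
  if (K < 2) stop("need at least two blocks")
  nr <- vapply(X, nrow, integer(1))
  if (length(unique(nr)) != 1) stop("blocks are not aligned on subjects")
  p <- vapply(X, ncol, integer(1))
  checkPenalties(penalties, p)
  if (nDims < 1) stop("nDims must be at least 1")
  nms <- names(X)
  if (is.null(nms)) nms <- paste0("block", seq_len(K))

  res <- cpp_fit_multi(unname(X), as.numeric(penalties), as.integer(nDims),
                       tol, as.integer(maxIter), as.integer(extraStarts))
  W <- res$weights
  names(W) <- nms
  for (i in seq_len(K)) {
    rownames(W[[i]]) <- colnames(X[[i]])
    colnames(W[[i]]) <- paste0("dim", seq_len(nDims))
  }
  corr <- res$corr
  rownames(corr) <- pairLabels(nms)
  colnames(corr) <- paste0("dim", seq_len(nDims))
  if (!all(res$converged)) {
    warning("sMCCA did not converge for dimension(s) ",
            paste(which(!res$converged), collapse = ", "),
            " within ", maxIter, " sweeps")
  }
  new("SmccaFit",
      weights = W,
      correlations = corr,
      objectives = as.numeric(res$objective),
      penalties = as.numeric(penalties),
      iterations = as.integer(res$iterations),
      converged = as.logical(res$converged),
      degenerate = as.logical(res$degenerate),
      objectiveTrace = res$trace,
      blockNames = nms)
}

#' Fit a single sparse multiple CCA component
#'
#' Convenience wrapper around [fitSmcca()] with `nDims = 1`.
#'
#' @inheritParams fitSmcca
#' @return an [SmccaFit-class] with one dimension.
#' @export
fitComponent <- function(x, penalties, tol = 1e-6, maxIter = 25,
                         extraStarts = 2) {
  fitSmcca(x, penalties, nDims = 1, tol = tol, maxIter = maxIter,
           extraStarts = extraStarts)
}

#' Cumulative average squared pairwise correlation
#'
#' Per-dimension average of the squared pairwise score correlations,
#' accumulated over dimensions; the share-of-variance summary used to
#' decide how many dimensions to retain (reported, never an automatic
#' stopping rule).
#'
#' @param fit an [SmccaFit-class].
#' @return numeric vector of cumulative shares in `[0, 1]` per dimension.
#' @export
cumulativeSharedVariance <- function(fit) {
  stopifnot(is(fit, "SmccaFit"))
  r2 <- colMeans(fit@correlations^2)
  pmin(cumsum(r2) / 1, 1)
}

#' Nonzero support of a fitted dimension
#'
#' @param fit an [SmccaFit-class].
#' @param dim dimension index.
#' @param tol magnitude below which a weight counts as zero.
#' @return named logical vector over all variables (blocks concatenated).
#' @export
weightSupport <- function(fit, dim = 1, tol = 1e-10) {
  w <- unlist(lapply(fit@weights, function(m) m[, dim]))
  abs(w) > tol
}
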