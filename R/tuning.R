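#' Default penalty candidate grid
#'
#' Per-block geometric sequence of `nCandidates` values spanning
#' `[1, sqrt(p_block)]` (endpoints included exactly), combined by aligned
#' index — candidate k uses the k-th value of every block — to keep tuning
#' desk-scale. A full Cartesian product is available behind `cartesian`.
#'
#' @param blockDims integer vector of per-block variable counts.
#' @param nCandidates grid length per block.
#' @param cartesian combine blocks by full Cartesian product instead of
#'   aligned index.
#' @return list of per-block penalty vectors (candidate PenaltySets).
#' @export
#' @examples
#' g <- defaultGrid(c(19, 3, 6))
#' g[[1]]        # c(1, 1, 1)
#' g[[length(g)]] # sqrt(c(19, 3, 6))
defaultGrid <- function(blockDims, nCandidates = 8, cartesian = FALSE) {
  if (any(blockDims < 1)) stop("block dimensions must be positive")
  per <- lapply(unname(blockDims), function(p) {
    if (p == 1) rep(1, nCandidates) else
      exp(seq(0, log(sqrt(p)), length.out = nCandidates))
  })
  if (!cartesian) {
    return(lapply(seq_len(nCandidates), function(k) {
      vapply(per, `[`, numeric(1), k)
    }))
  }
  idx <- expand.grid(lapply(per, seq_along))
  lapply(seq_len(nrow(idx)), function(r) {
    vapply(seq_along(per), function(b) per[[b]][idx[r, b]], numeric(1))
  })
}

#' Permutation-based selection of the per-block L1 budgets
#'
#' For each candidate penalty set, the first dimension is fitted on the
#' observed blocks and the statistic `t = sum_{i<j} atanh(r_ij)` (Fisher
#' z-transformed pairwise score correlations) is compared against its null
#' distribution from `nPerm` independent row-wise permutations of every
#' block; the candidate with the largest standardized score
#' `z = (t_obs - mean_null) / sd_null` is selected, ties broken toward the
#' smallest (sparsest) penalties.
#'
#' @param x a [BlockSet-class] or list of standardized matrices.
#' @param grid list of candidate penalty vectors, see [defaultGrid()].
#' @param nPerm number of permutations per candidate.
#' @param seed integer seed for the permutation streams.
#' @param tol,maxIter,extraStarts solver settings, see [fitSmcca()].
#' @return a [TuningResult-class].
#' @export
tunePenalties <- function(x, grid = defaultGrid(blockDims(x)), nPerm = 1000,
                          seed = 1, tol = 1e-6, maxIter = 25,
                          extraStarts = 2) {
  X <- asBlockMatrices(x)
  K <- length(X)
  n <- nrow(X[[1]])
  p <- vapply(X, ncol, integer(1))
  if (!length(grid)) stop("empty candidate grid")
  for (g in grid) checkPenalties(g, p)
  if (nPerm < 1) stop("nPerm must be at least 1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stageSeed(seed, "tune"))
  # one independent permutation stream per block, shared across candidates
  perms <- lapply(seq_len(K), function(i) {
    t(replicate(nPerm, sample.int(n)))
  })

  fisherSum <- function(corr) {
    r <- pmin(pmax(corr[, 1], -1 + 1e-12), 1 - 1e-12)
    sum(atanh(r))
  }

  rows <- NULL
  for (g in grid) {
    fitObs <- fitSmcca(X, g, nDims = 1, tol = tol, maxIter = maxIter,
                       extraStarts = extraStarts)
    tObs <- fisherSum(canonicalCorrelations(fitObs))
    tNull <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      Xp <- lapply(seq_len(K), function(i) X[[i]][perms[[i]][b, ], ,
                                                  drop = FALSE])
      names(Xp) <- names(X)
      fp <- suppressWarnings(
        fitSmcca(Xp, g, nDims = 1, tol = tol, maxIter = maxIter,
                 extraStarts = extraStarts))
      tNull[b] <- fisherSum(canonicalCorrelations(fp))
    }
    mu <- mean(tNull)
    sdv <- sd(tNull)
    z <- if (sdv == 0) NA_real_ else (tObs - mu) / sdv
    if (is.na(z)) {
      warning("degenerate permutation null (sd = 0); candidate skipped: ",
              paste(sprintf("%.3g", g), collapse = ", "))
    }
    rows <- rbind(rows, data.frame(
      t(setNames(g, paste0("c", seq_len(K)))),
      t_obs = tObs, null_mean = mu, null_sd = sdv, z = z))
  }
  rownames(rows) <- NULL
  ok <- which(!is.na(rows$z))
  if (!length(ok)) stop("all candidates had degenerate permutation nulls")
  best <- ok[rows$z[ok] >= max(rows$z[ok]) - 1e-12]
  if (length(best) > 1) {
    sums <- vapply(grid[best], sum, numeric(1))
    best <- best[which.min(sums)]
  } else {
    best <- best[1]
  }
  new("TuningResult", table = rows, selected = unname(grid[[best]]),
      grid = grid, nPerm = as.integer(nPerm))
}

#' Write a tuning report as CSV
#'
#' @param tuning a [TuningResult-class].
#' @param path output CSV path.
#' @export
writeTuningReport <- function(tuning, path) {
  write.csv(tuning@table, path, row.names = FALSE)
  invisible(path)
}
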