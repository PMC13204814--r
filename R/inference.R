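#' Shared permutation-null engine
#'
#' Fits the observed configuration, then refits on `B` datasets in which
#' every block's rows are independently permuted, recording for each
#' permutation the pairwise score correlations and the per-variable weights.
#' Permuted weights keep the solver's canonical per-dimension sign
#' convention — a deterministic function of each fit that never looks at
#' the observed solution — so the recorded null is exchangeable with the
#' observed statistics while arbitrary whole-block sign flips still cannot
#' inflate the null spread. Both the correlation test and the max-z weight
#' test are computed from this one object.
#'
#' @param x a [BlockSet-class] or list of standardized matrices.
#' @param penalties per-block L1 budgets (typically the tuned values; they
#'   are reused, not re-tuned, inside the permutation loop).
#' @param nDims dimensions to extract per fit.
#' @param B number of permutations.
#' @param seed integer seed for the per-block permutation streams.
#' @param tol,maxIter,extraStarts solver settings, see [fitSmcca()].
#' @return list with the observed [SmccaFit-class] (`fit`), `nullCorr`
#'   (B x npairs x nDims array), `nullWeights` (per block:
#'   p x nDims x B array) and `B`.
#' @export
permutationNull <- function(x, penalties, nDims = 2, B = 5000, seed = 1,
                            tol = 1e-6, maxIter = 25, extraStarts = 2) {
  X <- asBlockMatrices(x)
  K <- length(X)
  n <- nrow(X[[1]])
  if (B < 1) stop("B must be at least 1")
  fit <- fitSmcca(X, penalties, nDims = nDims, tol = tol, maxIter = maxIter,
                  extraStarts = extraStarts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stageSeed(seed, "test"))
  perms <- lapply(seq_len(K), function(i) {
    t(replicate(B, sample.int(n)))
  })
  res <- cpp_perm_null(unname(X), as.numeric(penalties), as.integer(nDims),
                       perms, tol, as.integer(maxIter),
                       as.integer(extraStarts))
  nullW <- res$weights
  names(nullW) <- fit@blockNames
  dimnames(res$corr) <- list(NULL, rownames(fit@correlations),
                             colnames(fit@correlations))
  list(fit = fit, nullCorr = res$corr, nullWeights = nullW, B = B)
}

#' Permutation significance of the pairwise canonical correlations
#'
#' Empirical p-values compare the observed absolute score correlation of
#' each block pair and dimension with its permutation null (two-sided via
#' absolute values, since canonical sign is indeterminate), using the
#' add-one convention `p = (1 + #(null >= obs)) / (B + 1)`.
#'
#' @inheritParams permutationNull
#' @param null optionally a precomputed [permutationNull()] result (then
#'   `x`, `penalties`, ... are ignored).
#' @param alpha,m significance level and Bonferroni family size, passed to
#'   [bonferroniFlags()].
#' @return data.frame: dimension, pair, r, p, significant.
#' @export
permTestCorrelations <- function(x, penalties, nDims = 2, B = 5000,
                                 seed = 1, null = NULL, alpha = 0.05,
                                 m = 3, ...) {
  if (is.null(null)) {
    null <- permutationNull(x, penalties, nDims = nDims, B = B, seed = seed,
                            ...)
  }
  fit <- null$fit
  obs <- canonicalCorrelations(fit)
  out <- NULL
  for (d in seq_len(ncol(obs))) {
    for (p in seq_len(nrow(obs))) {
      pv <- empiricalP(abs(obs[p, d]), abs(null$nullCorr[, p, d]))
      out <- rbind(out, data.frame(
        dimension = d, pair = rownames(obs)[p], r = obs[p, d], p = pv))
    }
  }
  bonferroniFlags(out, alpha = alpha, m = m)
}

#' Bonferroni significance flags
#'
#' Marks a test significant iff its empirical p-value is below `alpha / m`
#' (with the three block pairs, `0.05 / 3` reproduces the corrected
#' threshold of about 0.017).
#'
#' @param tests data.frame with a `p` column.
#' @param alpha family-wise level.
#' @param m family size.
#' @return `tests` with columns `threshold` and `significant` appended.
#' @export
bonferroniFlags <- function(tests, alpha = 0.05, m = 3) {
  if (m < 1) stop("family size m must be at least 1")
  tests$threshold <- alpha / m
  tests$significant <- tests$p < alpha / m
  tests
}

#' Max-z permutation significance of individual variable weights
#'
#' Per variable, `z_v = |w_obs,v| / sd_null,v`; the family-wise corrected
#' p-value compares `z_v` with the permutation distribution of the maximum
#' `z` within the variable's family (its block, per dimension), using the
#' add-one convention. Variables whose weight is zero in every permutation
#' (sd_null = 0) get `z = Inf` when the observed weight is nonzero and 0
#' otherwise.
#'
#' @inheritParams permTestCorrelations
#' @param alpha significance level on the corrected p-value.
#' @return data.frame: dimension, block, variable, weight, z, p_corrected,
#'   significant.
#' @export
weightSignificance <- function(x, penalties, nDims = 2, B = 5000, seed = 1,
                               null = NULL, alpha = 0.05, ...) {
  if (is.null(null)) {
    null <- permutationNull(x, penalties, nDims = nDims, B = B, seed = seed,
                            ...)
  }
  fit <- null$fit
  out <- NULL
  for (blk in fit@blockNames) {
    wObs <- fit@weights[[blk]]
    wNull <- null$nullWeights[[blk]]       # p x nDims x B
    for (d in seq_len(ncol(wObs))) {
      wSlice <- matrix(wNull[, d, ], nrow = dim(wNull)[1])   # p x B
      sdNull <- apply(wSlice, 1, sd)
      zObs <- ifelse(sdNull > 0, abs(wObs[, d]) / sdNull,
                     ifelse(abs(wObs[, d]) > 0, Inf, 0))
      zPerm <- sweep(abs(wSlice), 1, ifelse(sdNull > 0, sdNull, Inf), "/")
      maxZ <- apply(zPerm, 2, max)         # null familywise maxima
      pCorr <- vapply(zObs, function(z) empiricalP(z, maxZ), numeric(1))
      out <- rbind(out, data.frame(
        dimension = d, block = blk, variable = rownames(wObs),
        weight = wObs[, d], z = zObs, p_corrected = pCorr,
        significant = pCorr < alpha, row.names = NULL))
    }
  }
  out
}

#' Write correlation-test and weight-test reports as CSV
#'
#' @param tests data.frame from [permTestCorrelations()] or
#'   [weightSignificance()].
#' @param path output CSV path.
#' @export
writeTestReport <- function(tests, path) {
  write.csv(tests, path, row.names = FALSE)
  invisible(path)
}
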