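#' @describeIn smcca-generics list of block matrices of a BlockSet.
#' @export
setMethod("blocks", "BlockSet", function(object, ...) object@blocks)

#' @describeIn smcca-generics block names of a BlockSet.
#' @export
setMethod("blockNames", "BlockSet", function(object, ...) names(object@blocks))

#' @describeIn smcca-generics subject identifiers of a BlockSet.
#' @export
setMethod("subjectIds", "BlockSet", function(object, ...) object@subjectIds)

#' @describeIn smcca-generics per-block variable counts.
#' @export
setMethod("blockDims", "BlockSet", function(object, ...) {
  vapply(object@blocks, ncol, integer(1))
})

#' @describeIn smcca-generics number of subjects (rows).
#' @export
setMethod("nSubjects", "BlockSet", function(object, ...) {
  nrow(object@blocks[[1]])
})

setMethod("show", "BlockSet", function(object) {
  p <- blockDims(object)
  cat(sprintf("BlockSet: %d subjects, %d blocks (%s), %d variables total\n",
              nSubjects(object), length(p),
              paste(sprintf("%s=%d", names(p), p), collapse = ", "),
              sum(p)))
  std <- vapply(object@standardized, sum, integer(1))
  cat(sprintf("  standardized columns: %s\n",
              paste(sprintf("%s=%d", names(std), std), collapse = ", ")))
})

#' @describeIn smcca-generics weight matrix of one block (p x nDims), or the
#'   full named list when `block` is missing.
#' @param block block name or index.
#' @export
setMethod("weightMatrix", "SmccaFit", function(object, block, ...) {
  if (missing(block)) object@weights else object@weights[[block]]
})

#' @describeIn smcca-generics matrix of pairwise score correlations
#'   (pairs x dimensions).
#' @export
setMethod("canonicalCorrelations", "SmccaFit", function(object, ...) {
  object@correlations
})

#' @describeIn smcca-generics per-block L1 budgets of a fit.
#' @export
setMethod("penalties", "SmccaFit", function(object, ...) object@penalties)

#' @describeIn smcca-generics number of fitted dimensions.
#' @export
setMethod("nDims", "SmccaFit", function(object, ...) {
  ncol(object@weights[[1]])
})

setMethod("show", "SmccaFit", function(object) {
  nd <- nDims(object)
  cat(sprintf("SmccaFit: %d block(s), %d dimension(s)\n",
              length(object@weights), nd))
  cat(sprintf("  penalties: %s\n",
              paste(sprintf("%s=%.3g", object@blockNames, object@penalties),
                    collapse = ", ")))
  for (d in seq_len(nd)) {
    nz <- vapply(object@weights, function(w) sum(abs(w[, d]) > 1e-10),
                 integer(1))
    cat(sprintf("  dim %d: r = %s | nonzero = %s%s\n", d,
                paste(sprintf("%s %.3f", rownames(object@correlations),
                              object@correlations[, d]), collapse = ", "),
                paste(nz, collapse = "/"),
                if (object@converged[d]) "" else " (not converged)"))
  }
  css <- cumulativeSharedVariance(object)
  cat(sprintf("  cumulative shared variance: %s\n",
              paste(sprintf("%.1f%%", 100 * css), collapse = ", ")))
})

#' @describeIn smcca-generics selected penalties of a TuningResult.
#' @export
setMethod("selectedPenalties", "TuningResult", function(object, ...) {
  object@selected
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult: %d candidates, %d permutations\n",
              nrow(object@table), object@nPerm))
  cat(sprintf("  selected penalties: %s (z = %.2f)\n",
              paste(sprintf("%.3g", object@selected), collapse = ", "),
              max(object@table$z, na.rm = TRUE)))
})

#' @describeIn smcca-generics per-variable stability table.
#' @export
setMethod("stabilityTable", "StabilityReport", function(object, ...) {
  object@table
})

#' @describeIn smcca-generics per-dimension mean correlation between
#'   leave-one-out and full-fit weight vectors.
#' @export
setMethod("meanLoadingCorrelation", "StabilityReport", function(object, ...) {
  object@meanLoadingCor
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d folds (%d failed)\n",
              object@nFolds, object@failures))
  cat(sprintf("  thresholds: stable-zero < %.2f, stable-nonzero > %.2f\n",
              object@thresholds[1], object@thresholds[2]))
  cat(sprintf("  mean loading correlation: %s\n",
              paste(sprintf("dim%d %.3f", seq_along(object@meanLoadingCor),
                            object@meanLoadingCor), collapse = ", ")))
  print(table(object@table$class, object@table$dimension))
})
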