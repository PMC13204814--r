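#' @title Core S4 containers
#' @name smcca-classes
#' @description S4 classes holding the aligned variable blocks and the
#'   results of sparse multiple CCA fitting, tuning and stability analysis.
NULL

#' BlockSet: aligned subjects-by-variables blocks
#'
#' Holds K aligned numeric matrices sharing one subject index, plus the
#' standardization metadata (per-column centers/scales and which columns were
#' standardized; columns such as binary sex are left on their original 0/1
#' scale).
#'
#' @slot blocks named list of numeric matrices, identical row count and
#'   subject order.
#' @slot subjectIds character vector of subject identifiers (row order).
#' @slot centers,scales named lists (per block) of per-column centering and
#'   scaling constants applied (NA for columns left unstandardized).
#' @slot standardized named list (per block) of logical vectors marking the
#'   standardized columns.
#' @exportClass BlockSet
setClass("BlockSet",
  representation(
    blocks = "list",
    subjectIds = "character",
    centers = "list",
    scales = "list",
    standardized = "list"
  )
)

setValidity("BlockSet", function(object) {
  msgs <- character()
  b <- object@blocks
  if (length(b) < 2) msgs <- c(msgs, "need at least two blocks")
  if (is.null(names(b)) || any(!nzchar(names(b)))) {
    msgs <- c(msgs, "blocks must be named")
  }
  ns <- vapply(b, nrow, integer(1))
  if (length(unique(ns)) > 1) {
    msgs <- c(msgs, "all blocks must have the same number of rows")
  }
  if (length(object@subjectIds) != ns[1]) {
    msgs <- c(msgs, "subjectIds length must equal the number of rows")
  }
  for (nm in names(b)) {
    if (anyNA(b[[nm]])) msgs <- c(msgs, sprintf("block '%s' contains NA", nm))
    if (is.null(colnames(b[[nm]]))) {
      msgs <- c(msgs, sprintf("block '%s' has no column names", nm))
    } else if (anyDuplicated(colnames(b[[nm]]))) {
      msgs <- c(msgs, sprintf("block '%s' has duplicated variable names", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SmccaFit: multi-dimension sparse multiple CCA solution
#'
#' @slot weights named list (per block) of p_block x nDims weight matrices;
#'   each column is unit-L2 (or zero when degenerate) and L1-feasible.
#' @slot correlations npairs x nDims matrix of pairwise Pearson correlations
#'   of the realized score vectors, rows named "block1:block2".
#' @slot objectives per-dimension value of the summed bilinear objective.
#' @slot penalties per-block L1 budgets used.
#' @slot iterations,converged,degenerate per-dimension solver diagnostics.
#' @slot objectiveTrace list of per-sweep objective values per dimension.
#' @slot blockNames character vector of block names.
#' @exportClass SmccaFit
setClass("SmccaFit",
  representation(
    weights = "list",
    correlations = "matrix",
    objectives = "numeric",
    penalties = "numeric",
    iterations = "integer",
    converged = "logical",
    degenerate = "logical",
    objectiveTrace = "list",
    blockNames = "character"
  )
)

setValidity("SmccaFit", function(object) {
  msgs <- character()
  nd <- ncol(object@weights[[1]])
  if (ncol(object@correlations) != nd) {
    msgs <- c(msgs, "correlations and weights disagree on dimension count")
  }
  for (w in object@weights) {
    if (any(abs(w) > 1 + 1e-8)) msgs <- c(msgs, "weights outside [-1, 1]")
    n2 <- sqrt(colSums(w^2))
    if (any(n2 > 1 + 1e-8)) msgs <- c(msgs, "weight column exceeds unit L2 norm")
  }
  if (any(abs(object@correlations) > 1 + 1e-8)) {
    msgs <- c(msgs, "correlations outside [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' TuningResult: permutation-based penalty selection
#'
#' @slot table data.frame with one row per candidate: per-block penalties,
#'   observed Fisher-z statistic, permutation null mean/sd and z-score.
#' @slot selected numeric vector, the selected per-block penalties.
#' @slot grid list of candidate penalty vectors.
#' @slot nPerm number of permutations used.
#' @exportClass TuningResult
setClass("TuningResult",
  representation(
    table = "data.frame",
    selected = "numeric",
    grid = "list",
    nPerm = "integer"
  )
)

#' StabilityReport: leave-one-subject-out stability selection
#'
#' @slot table data.frame with variable, block, dimension, inclusion
#'   fraction and class (stable-nonzero / stable-zero / unstable).
#' @slot meanLoadingCor per-dimension mean Pearson correlation between
#'   sign-aligned leave-one-out weight vectors and the full-fit weights.
#' @slot nFolds number of leave-one-out refits attempted.
#' @slot failures number of refits that failed (excluded from denominators).
#' @slot thresholds the dual classification thresholds (lower, upper).
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(
    table = "data.frame",
    meanLoadingCor = "numeric",
    nFolds = "integer",
    failures = "integer",
    thresholds = "numeric"
  )
)
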