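#' Leave-one-subject-out stability selection
#'
#' Refits the model once per subject with that subject removed (the
#' reduced sample is re-standardized from scratch, so the held-out subject
#' plays no role in the fold's centers and scales; penalties stay fixed at
#' their tuned values). Reports per variable and dimension the inclusion
#' fraction — the share of refits in which its weight is nonzero — and the
#' dual-threshold classification: stable-nonzero above `thresholds[2]`
#' (default 0.75), stable-zero below `thresholds[1]` (default 0.25),
#' unstable in between. Also reports, per dimension, the mean Pearson
#' correlation between each fold's concatenated sign-aligned weight vector
#' and the full-fit weights.
#'
#' @param x a [BlockSet-class].
#' @param penalties per-block L1 budgets.
#' @param nDims dimensions to extract.
#' @param thresholds `c(lower, upper)` classification thresholds on the
#'   inclusion fraction.
#' @param zeroTol magnitude below which a weight counts as zero.
#' @param tol,maxIter,extraStarts solver settings, see [fitSmcca()].
#' @return a [StabilityReport-class].
#' @export
looStability <- function(x, penalties, nDims = 2,
                         thresholds = c(0.25, 0.75), zeroTol = 1e-10,
                         tol = 1e-6, maxIter = 25, extraStarts = 2) {
  stopifnot(is(x, "BlockSet"))
  n <- nSubjects(x)
  if (n < 3) stop("leave-one-out needs at least 3 subjects")
  full <- fitSmcca(x, penalties, nDims = nDims, tol = tol,
                   maxIter = maxIter, extraStarts = extraStarts)
  p <- blockDims(x)
  nms <- blockNames(x)

  inclusion <- array(0, dim = c(sum(p), nDims))
  varNames <- unlist(lapply(full@weights, rownames), use.names = FALSE)
  varBlock <- rep(nms, p)
  loadCor <- matrix(NA_real_, n, nDims)
  failures <- 0L
  counted <- 0L

  fullVec <- lapply(seq_len(nDims), function(d) {
    unlist(lapply(full@weights, function(w) w[, d]), use.names = FALSE)
  })

  for (i in seq_len(n)) {
    fold <- try(suppressWarnings(
      fitSmcca(subsetSubjects(x, setdiff(seq_len(n), i)), penalties,
               nDims = nDims, tol = tol, maxIter = maxIter,
               extraStarts = extraStarts)), silent = TRUE)
    if (inherits(fold, "try-error")) {
      failures <- failures + 1L
      next
    }
    counted <- counted + 1L
    for (d in seq_len(nDims)) {
      wd <- unlist(lapply(fold@weights, function(w) w[, d]),
                   use.names = FALSE)
      # sign alignment per block before concatenation
      off <- 0
      for (b in seq_along(p)) {
        idx <- off + seq_len(p[b])
        if (sum(wd[idx] * fullVec[[d]][idx]) < 0) wd[idx] <- -wd[idx]
        off <- off + p[b]
      }
      inclusion[, d] <- inclusion[, d] + (abs(wd) > zeroTol)
      if (sd(wd) > 0 && sd(fullVec[[d]]) > 0) {
        loadCor[i, d] <- cor(wd, fullVec[[d]])
      } else {
        warning("zero-variance weight vector in fold ", i,
                " (dimension ", d, "); skipped in loading correlation")
      }
    }
  }
  if (counted == 0) stop("every leave-one-out refit failed")
  frac <- inclusion / counted
  cls <- ifelse(frac > thresholds[2], "stable-nonzero",
                ifelse(frac < thresholds[1], "stable-zero", "unstable"))
  tab <- data.frame(
    variable = rep(varNames, nDims),
    block = rep(varBlock, nDims),
    dimension = rep(seq_len(nDims), each = sum(p)),
    inclusion = as.vector(frac),
    class = as.vector(cls),
    stringsAsFactors = FALSE
  )
  new("StabilityReport",
      table = tab,
      meanLoadingCor = colMeans(loadCor, na.rm = TRUE),
      nFolds = as.integer(n),
      failures = failures,
      thresholds = as.numeric(thresholds))
}

#' Star-annotated weight table
#'
#' Combines full-fit weights with the stability classification into the
#' familiar published layout: one row per variable, one weight column per
#' dimension, with a star marking variables whose classification is stable
#' (nonzero weights with inclusion above the upper threshold, zero weights
#' below the lower one).
#'
#' @param fit an [SmccaFit-class].
#' @param stability a [StabilityReport-class] from the same configuration.
#' @param zeroTol magnitude below which a weight counts as zero.
#' @return data.frame: block, variable, then per dimension weight and star.
#' @export
weightTable <- function(fit, stability, zeroTol = 1e-10) {
  nd <- nDims(fit)
  tab <- data.frame(
    block = rep(fit@blockNames, vapply(fit@weights, nrow, integer(1))),
    variable = unlist(lapply(fit@weights, rownames), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  st <- stabilityTable(stability)
  for (d in seq_len(nd)) {
    w <- unlist(lapply(fit@weights, function(m) m[, d]), use.names = FALSE)
    sd_ <- st[st$dimension == d, ]
    sd_ <- sd_[match(tab$variable, sd_$variable), ]
    stable <- ifelse(abs(w) > zeroTol,
                     sd_$class == "stable-nonzero",
                     sd_$class == "stable-zero")
    tab[[paste0("dim", d, "_weight")]] <- w
    tab[[paste0("dim", d, "_stable")]] <- ifelse(stable, "*", "")
  }
  tab
}
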