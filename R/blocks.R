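#' Study variable schema
#'
#' The 19/3/6 variable layout used throughout: 18 tract mean-FA variables
#' plus the EEG alpha peak frequency (biological), age/sex/education
#' (demographic), and the six reaction-time moment summaries (behavioral).
#' Sex is binary (0 = female, 1 = male) and is excluded from
#' standardization.
#'
#' @return named list with character vectors `biological`, `demographic`,
#'   `behavioral`, and `exclude` (variables never standardized).
#' @export
#' @examples
#' s <- studySchema()
#' sum(lengths(s[c("biological", "demographic", "behavioral")])) # 28
studySchema <- function() {
  tracts <- c("ATR", "CGC", "CGH", "CST", "IFOF", "ILF", "SLF", "UNC")
  fa <- as.vector(t(outer(tracts, c("L", "R"), paste, sep = "-")))
  list(
    biological = c(fa, "Fmj", "Fmn", "IAF"),
    demographic = c("age", "sex", "education"),
    behavioral = c("SRT", "CRT", "SDSRT", "SDCRT", "SKWSRT", "SKWCRT"),
    exclude = "sex"
  )
}

#' Standardize the columns of one block
#'
#' Centers each non-excluded column to mean 0 and scales it to sample
#' standard deviation 1 (denominator n-1). Excluded columns (e.g. binary
#' sex) are returned untouched. The applied centers and scales are returned
#' for provenance.
#'
#' @param x numeric matrix (subjects x variables) with column names.
#' @param exclude character vector of column names to leave untouched.
#' @return list with elements `matrix`, `centers`, `scales`,
#'   `standardized` (logical per column; centers/scales are NA for excluded
#'   columns).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(0, 1, 1))
#' standardizeBlock(m, exclude = "b")$matrix[, "a"] # -1 0 1
standardizeBlock <- function(x, exclude = character()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("block must have column names")
  missing <- setdiff(exclude, colnames(x))
  if (length(missing)) {
    stop("exclude names not in block: ", paste(missing, collapse = ", "))
  }
  std <- !(colnames(x) %in% exclude)
  centers <- scales <- rep(NA_real_, ncol(x))
  names(centers) <- names(scales) <- colnames(x)
  for (j in which(std)) {
    s <- sd(x[, j])
    if (s == 0) {
      stop("constant column cannot be standardized: ", colnames(x)[j])
    }
    centers[j] <- mean(x[, j])
    scales[j] <- s
    x[, j] <- (x[, j] - centers[j]) / s
  }
  names(std) <- colnames(x)
  list(matrix = x, centers = centers, scales = scales, standardized = std)
}

#' Assemble and standardize the three aligned variable blocks
#'
#' Aligns the three component tables on their shared subject identifiers
#' (matching by id, not by row position), enforces the declared variable
#' layout, standardizes every column except the declared exceptions, and
#' returns a validated [BlockSet-class].
#'
#' @param biological,demographic,behavioral data.frames, each with a
#'   `subject` column (or subject rownames) and the schema's variables.
#' @param schema variable layout, see [studySchema()].
#' @return a [BlockSet-class].
#' @export
assembleBlocks <- function(biological, demographic, behavioral,
                           schema = studySchema()) {
  tabs <- list(biological = biological, demographic = demographic,
               behavioral = behavioral)
  ids <- NULL
  mats <- list()
  for (nm in names(tabs)) {
    tb <- as.data.frame(tabs[[nm]])
    if ("subject" %in% colnames(tb)) {
      subj <- as.character(tb$subject)
      tb$subject <- NULL
    } else {
      subj <- rownames(tb)
    }
    if (anyDuplicated(subj)) {
      stop(sprintf("duplicated subject id(s) in %s table: %s", nm,
                   paste(unique(subj[duplicated(subj)]), collapse = ", ")))
    }
    want <- schema[[nm]]
    missingv <- setdiff(want, colnames(tb))
    if (length(missingv)) {
      stop(sprintf("missing variable(s) in %s table: %s", nm,
                   paste(missingv, collapse = ", ")))
    }
    m <- as.matrix(tb[, want, drop = FALSE])
    if (anyNA(m)) {
      stop(sprintf("missing values in %s table; complete cases required", nm))
    }
    rownames(m) <- subj
    if (is.null(ids)) {
      ids <- subj
    } else {
      lost <- setdiff(ids, subj)
      extra <- setdiff(subj, ids)
      if (length(lost) || length(extra)) {
        stop(sprintf("subject mismatch in %s table (missing: %s; extra: %s)",
                     nm,
                     if (length(lost)) paste(lost, collapse = ", ") else "-",
                     if (length(extra)) paste(extra, collapse = ", ") else "-"))
      }
      m <- m[ids, , drop = FALSE]
    }
    mats[[nm]] <- m
  }
  stds <- lapply(mats, function(m) {
    standardizeBlock(m, exclude = intersect(schema$exclude, colnames(m)))
  })
  new("BlockSet",
      blocks = lapply(stds, `[[`, "matrix"),
      subjectIds = ids,
      centers = lapply(stds, `[[`, "centers"),
      scales = lapply(stds, `[[`, "scales"),
      standardized = lapply(stds, `[[`, "standardized"))
}

#' Subset a BlockSet by subjects and re-standardize
#'
#' Used by the leave-one-out stability procedure: the retained rows are
#' re-standardized from scratch (the excluded subject plays no role in the
#' fold's means and scales); excluded columns stay on their raw scale.
#'
#' @param bs a [BlockSet-class].
#' @param keep integer or logical index of subjects to retain.
#' @return a re-standardized [BlockSet-class].
#' @export
subsetSubjects <- function(bs, keep) {
  stopifnot(is(bs, "BlockSet"))
  raws <- lapply(names(bs@blocks), function(nm) {
    m <- bs@blocks[[nm]]
    std <- bs@standardized[[nm]]
    for (j in which(std)) {
      m[, j] <- m[, j] * bs@scales[[nm]][j] + bs@centers[[nm]][j]
    }
    m[keep, , drop = FALSE]
  })
  names(raws) <- names(bs@blocks)
  stds <- lapply(names(raws), function(nm) {
    standardizeBlock(raws[[nm]],
                     exclude = names(which(!bs@standardized[[nm]])))
  })
  names(stds) <- names(raws)
  new("BlockSet",
      blocks = lapply(stds, `[[`, "matrix"),
      subjectIds = bs@subjectIds[keep],
      centers = lapply(stds, `[[`, "centers"),
      scales = lapply(stds, `[[`, "scales"),
      standardized = lapply(stds, `[[`, "standardized"))
}
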