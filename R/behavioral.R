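#' Validate a subject-task trial log
#'
#' A trial log is a data.frame with columns `subject`, `task` (one of
#' "simple"/"complex"), `trial` (unique ordered index), `is_go`,
#' `responded` (logicals or 0/1) and `rt_ms` (positive, present iff
#' responded).
#'
#' @param log data.frame trial log for one subject and one task.
#' @return the log, invisibly, after validation.
#' @export
validateTrialLog <- function(log) {
  need <- c("subject", "task", "trial", "is_go", "responded", "rt_ms")
  missing <- setdiff(need, colnames(log))
  if (length(missing)) {
    stop("trial log lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(log$task)) != 1 || length(unique(log$subject)) != 1) {
    stop("a trial log holds one subject on one task")
  }
  if (!log$task[1] %in% c("simple", "complex")) {
    stop("task must be 'simple' or 'complex', got: ", log$task[1])
  }
  if (anyDuplicated(log$trial) || is.unsorted(log$trial)) {
    stop("trial indices must be unique and ordered")
  }
  resp <- as.logical(log$responded)
  if (any(resp & is.na(log$rt_ms)) || any(!resp & !is.na(log$rt_ms))) {
    stop("rt_ms must be present exactly for responded trials")
  }
  if (any(log$rt_ms[resp] <= 0)) stop("rt_ms must be positive")
  invisible(log)
}

#' Reaction-time moment summary of one trial log
#'
#' Computes mean, standard deviation, and bias-adjusted sample skewness
#' (Fisher-Pearson G1) of the reaction times of correct GO responses
#' falling inside the response window, together with error counts.
#'
#' @param log trial log, see [validateTrialLog()].
#' @param minRT,maxRT response window in ms; RTs outside it are discarded
#'   as anticipations/lapses before computing moments.
#' @return one-row data.frame: subject, task, mean_rt, sd_rt, skewness,
#'   degenerate (TRUE when sd_rt = 0 and skewness is reported as 0),
#'   n_correct, commission, omission.
#' @export
summarizeRT <- function(log, minRT = 100, maxRT = 1000) {
  validateTrialLog(log)
  if (minRT >= maxRT) stop("minRT must be smaller than maxRT")
  go <- as.logical(log$is_go)
  resp <- as.logical(log$responded)
  rt <- log$rt_ms[go & resp]
  rt <- rt[rt >= minRT & rt <= maxRT]
  if (length(rt) < 3) {
    stop("fewer than 3 correct in-window responses; skewness undefined")
  }
  sk <- sampleSkewness(rt)
  errs <- countErrors(log)
  data.frame(
    subject = log$subject[1],
    task = log$task[1],
    mean_rt = mean(rt),
    sd_rt = sd(rt),
    skewness = as.numeric(sk),
    degenerate = attr(sk, "degenerate"),
    n_correct = length(rt),
    commission = errs[["commission"]],
    omission = errs[["omission"]],
    stringsAsFactors = FALSE
  )
}

#' Commission and omission error counts
#'
#' Commission = NO-GO trials with a response; omission = GO trials without
#' a response.
#'
#' @param log trial log, see [validateTrialLog()].
#' @return named numeric vector `c(commission = , omission = )`.
#' @export
countErrors <- function(log) {
  validateTrialLog(log)
  go <- as.logical(log$is_go)
  resp <- as.logical(log$responded)
  c(commission = sum(!go & resp), omission = sum(go & !resp))
}

#' Chi-square test of a 2x2 error contingency table
#'
#' Pearson chi-square with expected counts from the margins (df = 1);
#' Yates continuity correction is off by default.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param correct apply the continuity correction.
#' @return list with `statistic`, `p_value`, `df`, `expected`.
#' @export
#' @examples
#' errorContingencyTest(matrix(c(44, 65, 50, 104), 2))
errorContingencyTest <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row/column margin: expected counts undefined")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Per-subject behavioral summary table
#'
#' Reduces a full set of trial logs (both tasks, all subjects) to the
#' behavioral block: SRT, CRT (mean reaction times), SDSRT, SDCRT,
#' SKWSRT, SKWCRT, plus commission/omission counts per task.
#'
#' @param logs data.frame of trials for multiple subjects/tasks (columns as
#'   in [validateTrialLog()]).
#' @param minRT,maxRT response window passed to [summarizeRT()].
#' @return data.frame with one row per subject.
#' @export
behavioralSummary <- function(logs, minRT = 100, maxRT = 1000) {
  parts <- split(logs, list(logs$subject, logs$task), drop = TRUE)
  rows <- do.call(rbind, lapply(parts, summarizeRT, minRT = minRT,
                                maxRT = maxRT))
  wide <- NULL
  for (sub in unique(rows$subject)) {
    s <- rows[rows$subject == sub & rows$task == "simple", ]
    cx <- rows[rows$subject == sub & rows$task == "complex", ]
    if (nrow(s) != 1 || nrow(cx) != 1) {
      stop("subject ", sub, " lacks one of the two task logs")
    }
    wide <- rbind(wide, data.frame(
      subject = sub,
      SRT = s$mean_rt, CRT = cx$mean_rt,
      SDSRT = s$sd_rt, SDCRT = cx$sd_rt,
      SKWSRT = s$skewness, SKWCRT = cx$skewness,
      commission_SRT = s$commission, omission_SRT = s$omission,
      commission_CRT = cx$commission, omission_CRT = cx$omission,
      stringsAsFactors = FALSE
    ))
  }
  rownames(wide) <- NULL
  wide
}

#' Read trial logs from CSV
#'
#' Expects the columns subject, task, trial, is_go, responded, rt_ms (empty
#' rt_ms for unresponded trials).
#'
#' @param path CSV file path.
#' @return data.frame of trials.
#' @export
readTrialLogs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$is_go <- as.logical(df$is_go)
  df$responded <- as.logical(df$responded)
  df$rt_ms <- as.numeric(df$rt_ms)
  df
}

#' Write a behavioral summary table as CSV
#'
#' @param summary data.frame from [behavioralSummary()].
#' @param path output CSV path.
#' @export
writeBehavioralSummary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
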