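#' Build a validated pipeline run configuration
#'
#' A run either simulates its inputs (`synthetic = syntheticSpec(...)`) or
#' reads component tables from `paths` (named list with `biological`,
#' `demographic`, `behavioral` CSVs and optionally `trialLogs`, which
#' triggers the behavioral-features stage). Penalties are either a numeric
#' vector (fixed) or `"tune"`.
#'
#' @param synthetic optional [syntheticSpec()].
#' @param paths optional named list of input CSV paths.
#' @param penalties numeric per-block L1 budgets, or `"tune"`.
#' @param nDims dimensions to extract.
#' @param bTune,bTest permutation counts for tuning and testing.
#' @param alpha significance level.
#' @param mBonferroni Bonferroni family size for the correlation tests.
#' @param stabilityThresholds dual classification thresholds.
#' @param behavioralFrom `"direct"` or `"trials"` (synthetic runs).
#' @param rtWindow response window for trial-log summaries.
#' @param seed top-level integer seed; fanned out into independent named
#'   substreams per stage.
#' @param outDir output directory for the report bundle.
#' @param quiet suppress stage progress messages.
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(synthetic = NULL, paths = NULL, penalties = "tune",
                      nDims = 2, bTune = 1000, bTest = 5000, alpha = 0.05,
                      mBonferroni = 3, stabilityThresholds = c(0.25, 0.75),
                      behavioralFrom = "direct", rtWindow = c(100, 1000),
                      seed = 1, outDir = tempfile("smcca_run"),
                      quiet = FALSE) {
  if (is.null(synthetic) && is.null(paths)) {
    stop("provide either a synthetic spec or input paths")
  }
  if (!is.null(paths)) {
    need <- c("biological", "demographic", "behavioral")
    if ("trialLogs" %in% names(paths)) need <- setdiff(need, "behavioral")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      stop("paths lacks: ", paste(missing, collapse = ", "))
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  if (bTune < 1 || bTest < 1) stop("permutation counts must be >= 1")
  if (nDims < 1) stop("nDims must be >= 1")
  structure(list(
    synthetic = synthetic, paths = paths, penalties = penalties,
    nDims = as.integer(nDims), bTune = as.integer(bTune),
    bTest = as.integer(bTest), alpha = alpha,
    mBonferroni = as.integer(mBonferroni),
    stabilityThresholds = stabilityThresholds,
    behavioralFrom = behavioralFrom, rtWindow = rtWindow,
    seed = as.integer(seed), outDir = outDir, quiet = isTRUE(quiet)
  ), class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML config path; keys mirror the arguments of
#'   [runConfig()], with `synthetic` holding [syntheticSpec()] arguments
#'   and `synthetic$latentEffects` a list of loading maps.
#' @return a validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    sargs <- y$synthetic
    if (!is.null(sargs$latentEffects)) {
      sargs$latentEffects <- lapply(sargs$latentEffects, function(pd) {
        plantedDimension(unlist(pd$loadings),
                         latentSd = if (is.null(pd$latentSd)) 1 else
                           pd$latentSd)
      })
    }
    if (!is.null(sargs$exgaussParams)) {
      sargs$exgaussParams <- lapply(sargs$exgaussParams, unlist)
    }
    y$synthetic <- do.call(syntheticSpec, sargs)
  }
  if (!is.null(y$penalties) && is.numeric(y$penalties)) {
    y$penalties <- as.numeric(y$penalties)
  }
  do.call(runConfig, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> behavioral features (when trial logs
#' are the behavioral input) -> block assembly and standardization ->
#' penalty tuning (unless fixed) -> multi-dimension sparse multiple CCA ->
#' permutation tests of pairwise correlations (Bonferroni) and variable
#' weights (max-z) -> leave-one-out stability. Writes the report bundle as
#' CSVs plus a YAML run manifest sufficient to reproduce every table.
#'
#' @param config a `RunConfig`, see [runConfig()].
#' @return list of class `ReportBundle` with the weight table, correlation
#'   tests, weight tests, tuning report (or NULL), stability report,
#'   behavioral summary (or NULL), the fitted [SmccaFit-class], the
#'   [BlockSet-class] and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!config$quiet) message(...)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  behavSummary <- NULL
  if (!is.null(config$synthetic)) {
    say("stage simulate: generating synthetic study data")
    spec <- config$synthetic
    spec$seed <- stageSeed(config$seed, "simulate")
    tabs <- generateStudyTables(spec, behavioralFrom = config$behavioralFrom)
    if (!is.null(tabs$logs)) behavSummary <- tabs$behavioral
  } else {
    say("stage read: loading input tables")
    tabs <- list(
      biological = read.csv(config$paths$biological, check.names = FALSE),
      demographic = read.csv(config$paths$demographic, check.names = FALSE)
    )
    if (!is.null(config$paths$trialLogs)) {
      say("stage features: summarizing trial logs")
      logs <- readTrialLogs(config$paths$trialLogs)
      behavSummary <- behavioralSummary(logs, minRT = config$rtWindow[1],
                                        maxRT = config$rtWindow[2])
      tabs$behavioral <- behavSummary[, c("subject", studySchema()$behavioral)]
    } else {
      tabs$behavioral <- read.csv(config$paths$behavioral,
                                  check.names = FALSE)
    }
  }

  say("stage assemble: aligning and standardizing blocks")
  bs <- assembleBlocks(tabs$biological, tabs$demographic, tabs$behavioral)

  tuning <- NULL
  if (identical(config$penalties, "tune")) {
    say("stage tune: permutation-based penalty selection (B = ",
        config$bTune, ")")
    tuning <- tunePenalties(bs, nPerm = config$bTune, seed = config$seed)
    pen <- selectedPenalties(tuning)
  } else {
    pen <- as.numeric(config$penalties)
  }

  say("stage fit+test: ", config$bTest, " permutations, ", config$nDims,
      " dimension(s)")
  null <- permutationNull(bs, pen, nDims = config$nDims, B = config$bTest,
                          seed = config$seed)
  corrTests <- permTestCorrelations(null = null, alpha = config$alpha,
                                    m = config$mBonferroni)
  wTests <- weightSignificance(null = null, alpha = config$alpha)

  say("stage stability: leave-one-out refits")
  stability <- looStability(bs, pen, nDims = config$nDims,
                            thresholds = config$stabilityThresholds)
  wTable <- weightTable(null$fit, stability)

  manifest <- list(
    package = "smcca",
    version = as.character(packageVersion("smcca")),
    rversion = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stageSeeds = list(simulate = stageSeed(config$seed, "simulate"),
                      tune = stageSeed(config$seed, "tune"),
                      test = stageSeed(config$seed, "test")),
    penalties = as.numeric(pen),
    nDims = config$nDims,
    bTune = config$bTune,
    bTest = config$bTest,
    alpha = config$alpha,
    blockDims = as.list(blockDims(bs)),
    nSubjects = nSubjects(bs)
  )

  out <- config$outDir
  write.csv(wTable, file.path(out, "weight_table.csv"), row.names = FALSE)
  writeTestReport(corrTests, file.path(out, "correlation_tests.csv"))
  writeTestReport(wTests, file.path(out, "weight_tests.csv"))
  if (!is.null(tuning)) {
    writeTuningReport(tuning, file.path(out, "tuning_report.csv"))
  }
  write.csv(stabilityTable(stability), file.path(out, "stability.csv"),
            row.names = FALSE)
  if (!is.null(behavSummary)) {
    writeBehavioralSummary(behavSummary,
                           file.path(out, "behavioral_summary.csv"))
  }
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  structure(list(
    weightTable = wTable, correlationTests = corrTests,
    weightTests = wTests, tuning = tuning, stability = stability,
    behavioralSummary = behavSummary, fit = null$fit, blocks = bs,
    manifest = manifest
  ), class = "ReportBundle")
}
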