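#' Marginal rescaling targets for the study layout
#'
#' Per-variable mean/sd/min/max used to put generated columns on realistic
#' scales: tract mean-FA and alpha-peak rows follow the published sample
#' summary of the cohort the generator emulates, reaction-time rows follow
#' its behavioral summary, and age follows the sample description (mean
#' 29.54, sd 8.5, range 20-43). The education row is a synthetic default
#' (years of schooling, mean 14, sd 3) because no summary is available for
#' it.
#'
#' @return data.frame with columns variable, mean, sd, min, max.
#' @export
studyMarginals <- function() {
  path <- system.file("extdata", "study_marginals.csv", package = "smcca")
  read.csv(path, stringsAsFactors = FALSE)
}

#' A planted latent dimension
#'
#' @param loadings named numeric vector mapping variable names to signed
#'   loadings; a loading on `sex` shifts the latent factor mean by group
#'   (sex itself stays binary).
#' @param latentSd standard deviation of the shared factor's idiosyncratic
#'   part.
#' @return validated list of class `PlantedDimension`.
#' @export
plantedDimension <- function(loadings, latentSd = 1) {
  if (is.null(names(loadings)) || any(!nzchar(names(loadings)))) {
    stop("loadings must be a named vector")
  }
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  if (latentSd <= 0) stop("latentSd must be positive")
  structure(list(loadings = loadings, latentSd = latentSd),
            class = "PlantedDimension")
}

#' Default planted structure emulating the study's two latent dimensions
#'
#' Dimension 1 links bilateral association tracts (SLF, IFOF, UNC) with
#' complex-task performance (positive mean CRT, negative CRT skewness) and
#' sex; dimension 2 links motor/interhemispheric tracts (CGC, CST, ILF,
#' forceps) with skewness of both tasks and sex. Loadings default to the
#' published canonical weight magnitudes.
#'
#' @return list of two [plantedDimension()] objects.
#' @export
studyLatentEffects <- function() {
  list(
    plantedDimension(c(
      "SLF-L" = 0.423, "SLF-R" = 0.439, "IFOF-L" = 0.333, "IFOF-R" = 0.337,
      "UNC-L" = 0.379, "UNC-R" = 0.345,
      CRT = 0.745, SKWCRT = -0.584, sex = -0.96
    )),
    plantedDimension(c(
      "CGC-L" = 0.363, "CGC-R" = 0.303, "CST-L" = 0.357, "CST-R" = 0.346,
      Fmj = 0.373, Fmn = 0.307, "ILF-L" = 0.301, "ILF-R" = 0.409,
      SKWSRT = -0.738, SKWCRT = -0.589, sex = -0.96
    ))
  )
}

#' Planted structure with the study support pattern at chosen loading size
#'
#' Same two support sets as [studyLatentEffects()] but with loading
#' magnitudes evenly spread over `[low, high]` (signs kept), the
#' configuration used for recovery benchmarking. Sex loads on both
#' dimensions (as in the study pattern), which couples the two planted
#' factors: perfect separation is therefore not attainable even in
#' population, and benchmark results should be read with that in mind.
#'
#' @param low,high loading magnitude range for every planted variable.
#' @param sexLoading signed factor-mean shift per sex group.
#' @return list of two [plantedDimension()] objects.
#' @export
studySupportEffects <- function(low = 0.6, high = 0.8, sexLoading = -0.7) {
  base <- studyLatentEffects()
  lapply(base, function(pd) {
    l <- pd$loadings
    cont <- setdiff(names(l), "sex")
    mags <- seq(low, high, length.out = length(cont))
    l[cont] <- sign(l[cont]) * mags
    l["sex"] <- sexLoading
    plantedDimension(l, pd$latentSd)
  })
}

#' Specification of a synthetic multimodal study
#'
#' Collects every tunable of the generator: sample size, trial counts, GO
#' fractions, per-task ex-Gaussian reaction-time parameters (derived from
#' the published per-subject moment summaries), error rates, the planted
#' cross-block latent structure, and noise scale.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param nTrialsPerTask trials per task.
#' @param goFractionSimple,goFractionComplex GO stimulus fractions in (0,1).
#' @param exgaussParams list with `simple` and `complex`, each a named
#'   vector `c(mu=, sigma=, tau=)` in ms (sigma, tau > 0).
#' @param commissionRate probability of responding on a NO-GO trial.
#' @param omissionRate probability of missing a GO trial.
#' @param rtWindow response window (ms) used when summarizing trial logs.
#' @param latentEffects list of [plantedDimension()] objects (possibly
#'   empty for a global null).
#' @param noiseSd residual standard deviation of each generated variable
#'   (on the latent z-scale, before marginal rescaling).
#' @param pMale probability of sex = 1 (male); default mirrors the 14F/10M
#'   study split.
#' @param seed integer seed making every output deterministic.
#' @return validated list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nSubjects = 24,
                          nTrialsPerTask = 500,
                          goFractionSimple = 0.25,
                          goFractionComplex = 0.25,
                          exgaussParams = list(
                            simple = c(mu = 399.55, sigma = 45.61, tau = 63.99),
                            complex = c(mu = 357.02, sigma = 39.17, tau = 76.35)
                          ),
                          commissionRate = 0.005,
                          omissionRate = 0.017,
                          rtWindow = c(100, 1000),
                          latentEffects = studyLatentEffects(),
                          noiseSd = 1,
                          pMale = 10 / 24,
                          seed = 1) {
  if (nSubjects < 3) stop("nSubjects must be at least 3")
  for (fr in c(goFractionSimple, goFractionComplex)) {
    if (fr <= 0 || fr >= 1) stop("GO fractions must lie strictly in (0, 1)")
  }
  for (task in c("simple", "complex")) {
    p <- exgaussParams[[task]]
    if (is.null(p) || any(!c("mu", "sigma", "tau") %in% names(p))) {
      stop("exgaussParams$", task, " must provide mu, sigma, tau")
    }
    if (p[["sigma"]] <= 0 || p[["tau"]] <= 0) {
      stop("sigma and tau must be positive")
    }
  }
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (commissionRate < 0 || commissionRate > 1 ||
      omissionRate < 0 || omissionRate > 1) {
    stop("error rates must lie in [0, 1]")
  }
  for (pd in latentEffects) {
    if (!inherits(pd, "PlantedDimension")) {
      stop("latentEffects must be a list of plantedDimension() objects")
    }
  }
  structure(list(
    nSubjects = as.integer(nSubjects),
    nTrialsPerTask = as.integer(nTrialsPerTask),
    goFractionSimple = goFractionSimple,
    goFractionComplex = goFractionComplex,
    exgaussParams = exgaussParams,
    commissionRate = commissionRate,
    omissionRate = omissionRate,
    rtWindow = rtWindow,
    latentEffects = latentEffects,
    noiseSd = noiseSd,
    pMale = pMale,
    seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

# ex-Gaussian draws: normal(mu, sigma) + exponential(tau)
rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

#' Analytic ex-Gaussian moments
#'
#' Mean `mu + tau`, sd `sqrt(sigma^2 + tau^2)` and skewness
#' `2 tau^3 / (sigma^2 + tau^2)^{3/2}`.
#'
#' @param mu,sigma,tau ex-Gaussian parameters.
#' @return named vector `c(mean =, sd =, skewness =)`.
#' @export
exgaussMoments <- function(mu, sigma, tau) {
  v <- sigma^2 + tau^2
  c(mean = mu + tau, sd = sqrt(v), skewness = 2 * tau^3 / v^1.5)
}

# deterministic per-(subject, task) stream seed
trialSeed <- function(seed, subjectId, task) {
  sid <- if (is.numeric(subjectId)) {
    as.numeric(subjectId)
  } else {
    sum(utf8ToInt(as.character(subjectId)) *
          seq_along(utf8ToInt(as.character(subjectId))))
  }
  as.integer((as.numeric(seed) * 131 + sid * 7919 +
                (task == "complex") * 104729 + 13) %% 2147483647)
}

#' Simulate one subject-task trial log
#'
#' GO/NO-GO labels are Bernoulli draws at the task's GO fraction; GO trials
#' are answered with probability `1 - omissionRate` and carry an
#' ex-Gaussian reaction time; NO-GO trials are (wrongly) answered at the
#' commission rate. Deterministic given (seed, subjectId, task).
#'
#' @param spec a [syntheticSpec()].
#' @param subjectId subject identifier.
#' @param task `"simple"` or `"complex"`.
#' @param exgauss optional override of the task's `c(mu=, sigma=, tau=)`,
#'   used to modulate a subject's distribution.
#' @return trial-log data.frame, see [validateTrialLog()].
#' @export
generateTrials <- function(spec, subjectId, task,
                           exgauss = spec$exgaussParams[[task]]) {
  if (!task %in% c("simple", "complex")) {
    stop("task must be 'simple' or 'complex', got: ", task)
  }
  if (exgauss[["sigma"]] <= 0 || exgauss[["tau"]] <= 0) {
    stop("sigma and tau must be positive")
  }
  n <- spec$nTrialsPerTask
  goFrac <- if (task == "simple") spec$goFractionSimple else
    spec$goFractionComplex
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(trialSeed(spec$seed, subjectId, task))
  is_go <- runif(n) < goFrac
  responded <- ifelse(is_go,
                      runif(n) >= spec$omissionRate,
                      runif(n) < spec$commissionRate)
  rt <- rep(NA_real_, n)
  nresp <- sum(responded)
  if (nresp > 0) {
    draws <- rexgauss(nresp, exgauss[["mu"]], exgauss[["sigma"]],
                      exgauss[["tau"]])
    rt[responded] <- pmax(draws, 1)
  }
  data.frame(subject = as.character(subjectId), task = task, trial = seq_len(n),
             is_go = is_go, responded = responded, rt_ms = rt,
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# invert target (mean, sd, skewness) to ex-Gaussian parameters, clamping to
# the feasible region (0 < skewness < 2)
exgaussFromMoments <- function(m, s, g) {
  m <- unname(m)
  s <- max(unname(s), 5)
  g <- unname(g)
  g <- min(max(g, 0.05), 1.9)
  tau <- s * (g / 2)^(1 / 3)
  sig2 <- max(s^2 - tau^2, (0.05 * s)^2)
  c(mu = m - tau, sigma = sqrt(sig2), tau = tau)
}

#' Generate the raw synthetic study tables
#'
#' Draws sex, latent factors and residual noise, plants every latent
#' dimension's loadings, rescales continuous columns toward the marginal
#' targets (affine match of sample mean/sd), and returns the three raw
#' component tables. Behavioral summaries are either planted directly at
#' the block level (`behavioralFrom = "direct"`, exact control of effect
#' sizes) or obtained by simulating trial logs whose per-subject
#' ex-Gaussian parameters carry the planted effects and then summarizing
#' them (`"trials"`).
#'
#' @param spec a [syntheticSpec()].
#' @param marginals rescaling targets, see [studyMarginals()].
#' @param behavioralFrom `"direct"` or `"trials"`.
#' @param schema variable layout, see [studySchema()].
#' @return list with data.frames `biological`, `demographic`, `behavioral`
#'   (each with a `subject` column) and `logs` (trial logs, or NULL for the
#'   direct path).
#' @export
generateStudyTables <- function(spec, marginals = studyMarginals(),
                                behavioralFrom = c("direct", "trials"),
                                schema = studySchema()) {
  behavioralFrom <- match.arg(behavioralFrom)
  n <- spec$nSubjects
  allVars <- c(schema$biological, schema$demographic, schema$behavioral)
  if (anyDuplicated(allVars)) stop("duplicate variable names in schema")
  for (pd in spec$latentEffects) {
    unknown <- setdiff(names(pd$loadings), allVars)
    if (length(unknown)) {
      stop("planted loading names not in variable layout: ",
           paste(unknown, collapse = ", "))
    }
    nb <- vapply(schema[c("biological", "demographic", "behavioral")],
                 function(v) any(names(pd$loadings) %in% v), logical(1))
    if (sum(nb) < 2) {
      stop("each planted dimension must load on at least two blocks")
    }
  }
  if (any(marginals$sd <= 0) || any(marginals$min >= marginals$max)) {
    stop("invalid marginal targets")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stageSeed(spec$seed, "simulate"))

  sex <- rbinom(n, 1, spec$pMale)
  sTilde <- (sex - spec$pMale) / sqrt(spec$pMale * (1 - spec$pMale))
  D <- length(spec$latentEffects)
  factors <- matrix(0, n, max(D, 1))
  for (d in seq_len(D)) {
    pd <- spec$latentEffects[[d]]
    lam <- if ("sex" %in% names(pd$loadings)) pd$loadings[["sex"]] else 0
    factors[, d] <- lam * sTilde + pd$latentSd * rnorm(n)
  }

  contVars <- setdiff(allVars, "sex")
  raw <- matrix(0, n, length(contVars), dimnames = list(NULL, contVars))
  for (v in contVars) {
    x <- spec$noiseSd * rnorm(n)
    for (d in seq_len(D)) {
      b <- spec$latentEffects[[d]]$loadings
      if (v %in% names(b)) x <- x + b[[v]] * factors[, d]
    }
    raw[, v] <- x
  }

  # affine rescale toward marginal targets (sample moments match exactly)
  tgt <- marginals[match(contVars, marginals$variable), ]
  for (k in seq_along(contVars)) {
    if (is.na(tgt$variable[k])) next
    x <- raw[, k]
    if (sd(x) > 0) {
      raw[, k] <- tgt$mean[k] + (x - mean(x)) / sd(x) * tgt$sd[k]
    }
  }

  ids <- sprintf("S%02d", seq_len(n))
  bio <- data.frame(subject = ids,
                    raw[, schema$biological, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  demo <- data.frame(subject = ids,
                     age = raw[, "age"], sex = sex,
                     education = raw[, "education"],
                     check.names = FALSE, stringsAsFactors = FALSE)

  logs <- NULL
  if (behavioralFrom == "direct") {
    behav <- data.frame(subject = ids,
                        raw[, schema$behavioral, drop = FALSE],
                        check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    logs <- vector("list", 2 * n)
    for (i in seq_len(n)) {
      ps <- exgaussFromMoments(raw[i, "SRT"], raw[i, "SDSRT"],
                               raw[i, "SKWSRT"])
      pc <- exgaussFromMoments(raw[i, "CRT"], raw[i, "SDCRT"],
                               raw[i, "SKWCRT"])
      logs[[2 * i - 1]] <- generateTrials(spec, ids[i], "simple", ps)
      logs[[2 * i]] <- generateTrials(spec, ids[i], "complex", pc)
    }
    logs <- do.call(rbind, logs)
    behav <- behavioralSummary(logs, minRT = spec$rtWindow[1],
                               maxRT = spec$rtWindow[2])
    behav <- behav[match(ids, behav$subject),
                   c("subject", schema$behavioral)]
  }
  list(biological = bio, demographic = demo, behavioral = behav, logs = logs)
}

#' Generate a standardized BlockSet with planted structure
#'
#' Convenience wrapper: [generateStudyTables()] followed by
#' [assembleBlocks()].
#'
#' @inheritParams generateStudyTables
#' @return a [BlockSet-class].
#' @export
generateBlocks <- function(spec, marginals = studyMarginals(),
                           behavioralFrom = c("direct", "trials"),
                           schema = studySchema()) {
  tabs <- generateStudyTables(spec, marginals, behavioralFrom, schema)
  assembleBlocks(tabs$biological, tabs$demographic, tabs$behavioral, schema)
}

#' Write synthetic tables, trial logs and the generating spec to disk
#'
#' @param tables output of [generateStudyTables()].
#' @param spec the generating [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticData <- function(tables, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("biological", "demographic", "behavioral")) {
    write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(tables$logs)) {
    write.csv(tables$logs, file.path(dir, "trial_logs.csv"),
              row.names = FALSE)
  }
  prov <- spec
  prov$latentEffects <- lapply(spec$latentEffects, function(pd) {
    list(loadings = as.list(pd$loadings), latentSd = pd$latentSd)
  })
  yaml::write_yaml(prov, file.path(dir, "synthetic_spec.yaml"))
  invisible(dir)
}

#' Assess recovery of a planted structure by a fitted model
#'
#' Compares the nonzero support and weights of each fitted dimension with
#' the planted loading pattern. Fitted dimensions are matched to planted
#' dimensions by maximizing total support Jaccard; the weight correlation
#' is the absolute Pearson correlation between the concatenated fitted
#' weight vector and the planted loading vector (zeros off-support), which
#' makes it invariant to the indeterminate canonical sign. Because fitted
#' weights are unit-L2 per block, the planted loadings are likewise
#' normalized within each block before concatenation, so the comparison is
#' not distorted by the arbitrary overall scale of each block's loadings.
#'
#' @param fit an [SmccaFit-class] over the full variable layout.
#' @param effects list of [plantedDimension()] objects that generated the
#'   data.
#' @param zeroTol magnitude below which a fitted weight counts as zero.
#' @return data.frame with one row per planted dimension: planted
#'   dimension, matched fitted dimension, jaccard, weight_cor.
#' @export
supportRecovery <- function(fit, effects, zeroTol = 1e-10) {
  varNames <- unlist(lapply(fit@weights, rownames), use.names = FALSE)
  nd <- nDims(fit)
  D <- length(effects)
  fitted <- lapply(seq_len(nd), function(d) {
    w <- unlist(lapply(fit@weights, function(m) m[, d]), use.names = FALSE)
    names(w) <- varNames
    w
  })
  blockOf <- rep(names(fit@weights),
                 vapply(fit@weights, nrow, integer(1)))
  planted <- lapply(effects, function(pd) {
    v <- setNames(numeric(length(varNames)), varNames)
    v[names(pd$loadings)] <- pd$loadings
    for (b in unique(blockOf)) {
      idx <- blockOf == b
      n2 <- sqrt(sum(v[idx]^2))
      if (n2 > 0) v[idx] <- v[idx] / n2
    }
    v
  })
  jac <- function(a, b) {
    if (!any(a) && !any(b)) return(1)
    sum(a & b) / sum(a | b)
  }
  J <- outer(seq_len(D), seq_len(nd), Vectorize(function(i, d) {
    jac(abs(planted[[i]]) > 0, abs(fitted[[d]]) > zeroTol)
  }))
  # match planted to fitted dimensions maximizing total Jaccard
  perms <- if (nd == 1) matrix(1) else
    as.matrix(expand.grid(rep(list(seq_len(nd)), D)))
  perms <- perms[apply(perms, 1, anyDuplicated) == 0, , drop = FALSE]
  tot <- apply(perms, 1, function(pm) sum(J[cbind(seq_len(D), pm)]))
  pm <- perms[which.max(tot), ]
  out <- NULL
  for (i in seq_len(D)) {
    wf <- fitted[[pm[i]]]
    wc <- if (sd(wf) > 0 && sd(planted[[i]]) > 0) {
      abs(cor(wf, planted[[i]]))
    } else NA_real_
    out <- rbind(out, data.frame(planted_dim = i, fitted_dim = pm[i],
                                 jaccard = J[i, pm[i]], weight_cor = wc))
  }
  out
}

#' Planted structure for stability benchmarking
#'
#' One strong planted dimension over continuous variables only: the
#' dimension-1 tract support (SLF, IFOF, UNC bilaterally) plus mean complex
#' reaction time (positive), its skewness (negative) and age, all at one
#' loading magnitude. Using the continuous demographic variable rather
#' than binary sex isolates the behavior of the dual-threshold stability
#' rule from the scale handicap of the unstandardized 0/1 sex column
#' (whose cross-covariance is intrinsically shrunk by its Bernoulli
#' standard deviation; see the methods vignette).
#'
#' @param loading common loading magnitude.
#' @return list with one [plantedDimension()].
#' @export
stabilityBenchmarkEffects <- function(loading = 0.8) {
  l <- c("SLF-L" = 1, "SLF-R" = 1, "IFOF-L" = 1, "IFOF-R" = 1,
         "UNC-L" = 1, "UNC-R" = 1, CRT = 1, SKWCRT = -1, age = 1) * loading
  list(plantedDimension(l))
}
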