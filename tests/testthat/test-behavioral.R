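makeLog <- function(rt, isGo = rep(TRUE, length(rt)), responded = !is.na(rt),
                    task = "simple", subject = "S01") {
  data.frame(subject = subject, task = task, trial = seq_along(rt),
             is_go = isGo, responded = responded, rt_ms = rt,
             stringsAsFactors = FALSE)
}

test_that("moment summaries handle constant and symmetric samples", {
  s <- summarizeRT(makeLog(c(400, 400, 400)), minRT = 0, maxRT = 1000)
  expect_equal(s$mean_rt, 400)
  expect_equal(s$sd_rt, 0)
  expect_equal(s$skewness, 0)
  expect_true(s$degenerate)

  s2 <- summarizeRT(makeLog(c(300, 400, 500)), minRT = 0, maxRT = 1000)
  expect_equal(s2$skewness, 0)
  expect_false(s2$degenerate)
})

test_that("fewer than 3 in-window responses is an error", {
  expect_error(summarizeRT(makeLog(c(400, 410))), "fewer than 3")
  # window can eat responses down to < 3
  expect_error(summarizeRT(makeLog(c(400, 410, 50, 40, 30))),
               "fewer than 3")
  expect_error(summarizeRT(makeLog(c(400, 410, 420)), minRT = 500,
                           maxRT = 400), "minRT")
})

test_that("the response window filters anticipations and lapses", {
  rt <- c(50, 400, 450, 500, 1500)
  s <- summarizeRT(makeLog(rt), minRT = 100, maxRT = 1000)
  expect_equal(s$n_correct, 3)
  expect_equal(s$mean_rt, 450)
})

test_that("skewness agrees with the bias-adjusted G1 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  for (k in 1:10) {
    x <- rexp(sample(10:60, 1)) * 100 + 300
    s <- summarizeRT(makeLog(x), minRT = 0, maxRT = Inf)
    expect_equal(s$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
  }
})

test_that("simulated ex-Gaussian skewness approaches the analytic value", {
  spec <- syntheticSpec(nTrialsPerTask = 100000, goFractionSimple = 0.999,
                        omissionRate = 0, seed = 99)
  log <- generateTrials(spec, 1, "simple",
                        exgauss = c(mu = 350, sigma = 30, tau = 100))
  s <- summarizeRT(log, minRT = 1, maxRT = 1e9)
  mom <- exgaussMoments(350, 30, 100)
  expect_equal(unname(mom["skewness"]), 2 * 100^3 / (30^2 + 100^2)^1.5)
  expect_lt(abs(s$skewness - mom["skewness"]), 0.05)
})

test_that("error counts follow their definitions and conserve trials", {
  log <- makeLog(c(400, NA, 410, NA, 420),
                 isGo = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # GO answered: 1, 5; GO missed: 2; NO-GO answered: 3; NO-GO quiet: 4
  e <- countErrors(log)
  expect_equal(unname(e["commission"]), 1)
  expect_equal(unname(e["omission"]), 1)

  set.seed(4)
  for (k in 1:10) {
    n <- 200
    isGo <- runif(n) < 0.3
    responded <- runif(n) < 0.8
    rt <- ifelse(responded, 300 + 200 * runif(n), NA)
    log <- makeLog(rt, isGo = isGo, responded = responded)
    e <- countErrors(log)
    correctGo <- sum(isGo & responded)
    correctRej <- sum(!isGo & !responded)
    expect_equal(unname(e["commission"] + e["omission"]) +
                   correctGo + correctRej, n)
  }
})

test_that("moments are equivariant under affine RT rescaling", {
  set.seed(6)
  rt <- 300 + rexp(40, 1 / 80)
  a <- 1.7
  b <- 25
  s1 <- summarizeRT(makeLog(rt), minRT = 0, maxRT = 1e9)
  s2 <- summarizeRT(makeLog(a * rt + b), minRT = 0, maxRT = 1e9)
  expect_equal(s2$mean_rt, a * s1$mean_rt + b)
  expect_equal(s2$sd_rt, a * s1$sd_rt)
  expect_equal(s2$skewness, s1$skewness, tolerance = 1e-12)
})

test_that("trial-log validation rejects malformed logs", {
  bad <- makeLog(c(400, 410, 420))
  bad$rt_ms[1] <- NA # responded but no RT
  expect_error(validateTrialLog(bad), "rt_ms")
  bad2 <- makeLog(c(400, 410, 420))
  bad2$trial <- c(1, 1, 2)
  expect_error(validateTrialLog(bad2), "unique")
  bad3 <- makeLog(c(400, 410, 420), task = "oddball")
  expect_error(validateTrialLog(bad3), "task")
})

test_that("the 2x2 error test matches the direct expected-count formula", {
  r <- errorContingencyTest(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  tab <- rbind(c(44, 50), c(65, 104))
  r2 <- errorContingencyTest(tab)
  expect_equal(r2$statistic, chisqOracle(tab), tolerance = 1e-12)
  expect_equal(r2$df, 1)
  # continuity correction is exposed and changes the statistic
  r3 <- errorContingencyTest(tab, correct = TRUE)
  expect_lt(r3$statistic, r2$statistic)

  expect_error(errorContingencyTest(rbind(c(0, 5), c(0, 7))), "margin")
  expect_error(errorContingencyTest(rbind(c(-1, 5), c(2, 7))), "nonnegative")
})

test_that("behavioral summary produces the six study variables per subject", {
  spec <- syntheticSpec(nTrialsPerTask = 400, seed = 12)
  logs <- rbind(generateTrials(spec, "S01", "simple"),
                generateTrials(spec, "S01", "complex"),
                generateTrials(spec, "S02", "simple"),
                generateTrials(spec, "S02", "complex"))
  bs <- behavioralSummary(logs)
  expect_equal(nrow(bs), 2)
  expect_true(all(c("SRT", "CRT", "SDSRT", "SDCRT", "SKWSRT", "SKWCRT")
                  %in% colnames(bs)))
  expect_true(all(bs$SDSRT > 0))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  writeBehavioralSummary(bs, f)
  back <- read.csv(f)
  expect_equal(back$SRT, bs$SRT, tolerance = 1e-9)
  f2 <- tempfile(fileext = ".csv")
  write.csv(logs, f2, row.names = FALSE)
  logs2 <- readTrialLogs(f2)
  expect_equal(countErrors(logs2[logs2$subject == "S01" &
                                   logs2$task == "simple", ]),
               countErrors(logs[logs$subject == "S01" &
                                  logs$task == "simple", ]))
})
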