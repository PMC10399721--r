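test_that("tumor volume follows the modified ellipsoid formula", {
  expect_equal(tumorVolume(10, 5), 125)
  expect_equal(tumorVolume(c(7, 12), 0), c(0, 0))
  expect_error(tumorVolume(-1, 0), "non-negative")
  expect_warning(v <- tumorVolume(5, 10), "swapped")
  expect_equal(v, 125)
  ## monotone nondecreasing in each argument on a grid
  g <- expand.grid(l = seq(2, 10, 2), w = seq(0, 1.5, 0.5))
  v <- tumorVolume(g$l, g$w)
  expect_true(all(tumorVolume(g$l + 1, g$w) >= v))
  expect_true(all(tumorVolume(g$l, g$w + 0.5) >= v))
})

test_that("percent inhibition and shrinkage reproduce the arithmetic oracles", {
  expect_equal(percentInhibition(c(5, 5), c(5, 5)), 0)
  expect_equal(percentInhibition(c(0, 0), c(5, 10)), 100)
  expect_equal(percentInhibition(0.09 * c(100, 200), c(100, 200)), 91)
  expect_error(percentInhibition(c(1, 2), c(0, 0)), "zero")
  expect_error(percentInhibition(numeric(), 1), "non-empty")
  ## growth-delta variant
  expect_equal(percentInhibition(c(150, 150), c(300, 300),
                                 treatedBaseline = c(100, 100),
                                 controlBaseline = c(100, 100),
                                 method = "delta"), 75)

  expect_equal(percentShrinkage(250, 250), 0)
  expect_equal(percentShrinkage(250, 0), 100)
  expect_equal(percentShrinkage(250, 0.47 * 250), 53)
  expect_equal(percentShrinkage(100, 150), -50)  # growth is negative shrinkage
  expect_error(percentShrinkage(0, 10), "positive")
})

test_that("growth curves are classified CR, DR, SR or NR", {
  days <- c(0, 7, 14, 21)
  expect_equal(as.character(classifyResponse(days, c(250, 120, 30, 0))$class),
               "CR")
  expect_equal(as.character(classifyResponse(days, c(250, 150, 100, 110))$class),
               "DR")
  r <- classifyResponse(days, c(250, 140, 180, 400), responseFraction = 0.8)
  expect_equal(as.character(r$class), "SR")
  expect_equal(r$nadir, 140)
  expect_equal(as.character(classifyResponse(days, c(250, 260, 300, 400))$class),
               "NR")
  expect_error(classifyResponse(0, 250), "2 time points")
  expect_error(classifyResponse(c(0, 7), c(0, 10)), "baseline")
  ## ratio rules are invariant to uniform rescaling (absolute CR cutoff aside)
  for (vol in list(c(250, 150, 100, 110), c(250, 140, 180, 400),
                   c(250, 260, 300, 400))) {
    expect_equal(as.character(classifyResponse(days, vol)$class),
                 as.character(classifyResponse(days, vol * 7)$class))
  }
  ## baseline taken at treatment start, not at day 0
  late <- classifyResponse(c(0, 9, 21, 33), c(100, 250, 150, 180),
                           treatmentStart = 9)
  expect_equal(late$baseline, 250)
  expect_equal(as.character(late$class), "DR")
})

test_that("response summaries render the printed precisions and partition the cohort", {
  s <- summarizeResponses(rep(c("CR", "DR", "SR"), c(10, 6, 5)))
  expect_equal(s$count[s$class == "CR"], 10)
  expect_equal(s$pct[s$class == "CR"], 48)      # 10 of 21
  expect_equal(s$pct_1dp[s$class == "DR"], 28.6)
  expect_equal(sum(s$count), 21)
  expect_equal(summarizeResponses(rep(c("CR", "NR"), c(1, 6)))$pct_1dp[1],
               14.3)                            # 1 of 7
  expect_equal(summarizeResponses(rep(c("CR", "NR"), c(1, 5)))$pct_1dp[1],
               16.7)                            # 1 of 6
  expect_equal(summarizeResponses(rep("NR", 9))$pct[1], 0)
  ## percentages sum to 100 up to rendering rounding
  expect_lt(abs(sum(s$pct_1dp) - 100), 0.3)
  expect_error(summarizeResponses(character()), "no response")
  expect_error(summarizeResponses("XX"), "among")
})

test_that("rounding is half away from zero at both precisions", {
  expect_equal(roundHalfUp(0.5), 1)
  expect_equal(roundHalfUp(-0.5), -1)
  expect_equal(roundHalfUp(2.5), 3)   # base round() would give 2
  expect_equal(roundHalfUp(0.25, 1), 0.3)
})

test_that("Kaplan-Meier estimate matches hand product-limit and empirical oracles", {
  ## no events: survival stays at 1
  km <- kmEstimator(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  ## n = 4, one event at t = 10: S drops to 3/4
  km <- kmEstimator(c(10, 20, 30, 40), c(1, 0, 0, 0))
  expect_equal(km$surv[km$time == 10], 3 / 4)
  expect_equal(km$surv[km$time == 0], 1)
  ## no censoring: equals the empirical survivor function
  set.seed(8)
  t <- sample(1:30, 12, replace = TRUE)
  km <- kmEstimator(t, rep(1, 12))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(t > km$time[i]))
  }
  ## nonincreasing within [0, 1] under censoring
  ev <- rbinom(12, 1, 0.5)
  km <- kmEstimator(t, ev)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_error(kmEstimator(c(0, 3), c(1, 1)), "positive")
})

test_that("log-rank test matches the observed-minus-expected oracle", {
  ## identical groups: statistic 0, p 1
  lr <- logrankTest(c(3, 6, 9), c(1, 1, 0), c(3, 6, 9), c(1, 1, 0))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  ## no events at all: convention (0, 1)
  expect_equal(logrankTest(c(3, 6), c(0, 0), c(4, 8), c(0, 0)),
               list(chisq = 0, p = 1))
  ## 3-vs-3 toy with distinct event times vs the hand O-E table
  tA <- c(10, 20, 30); eA <- c(1, 1, 1)
  tB <- c(15, 25, 40); eB <- c(1, 1, 0)
  got <- logrankTest(tA, eA, tB, eB)
  want <- logrankOracle(tA, eA, tB, eB)
  expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)
  ## swapping group labels changes nothing
  swp <- logrankTest(tB, eB, tA, eA)
  expect_equal(swp$chisq, got$chisq)
  ## random instances against the oracle
  set.seed(14)
  for (i in 1:10) {
    t1 <- sample(1:40, 8, replace = TRUE); e1 <- rbinom(8, 1, 0.7)
    t2 <- sample(1:40, 8, replace = TRUE) + 5; e2 <- rbinom(8, 1, 0.7)
    if (sum(e1) + sum(e2) == 0) next
    expect_equal(logrankTest(t1, e1, t2, e2)$chisq,
                 logrankOracle(t1, e1, t2, e2)$chisq, tolerance = 1e-6)
  }
})

test_that("delta-delta-Ct returns the housekeeping-normalized log2 fold change", {
  expect_equal(ddctLog2fc(20, 15, 20, 15), 0)
  expect_equal(ddctLog2fc(19, 15, 20, 15), 1)   # one cycle lower = 2-fold up
  expect_equal(ddctLog2fc(20, 15, 24, 16), 3)
  expect_error(ddctLog2fc(20, NA, 24, 16), "finite")
})

test_that("the preclinical pipeline classifies a written growth log end to end", {
  cfg <- simConfig(seed = 31)
  sim <- simulateGrowthCohort(cfg)
  dir <- withr::local_tempdir()
  writeSimulatedInputs(dir, growth = sim)
  out <- runPreclinical(file.path(dir, "growth.csv"),
                        survival = file.path(dir, "survival.csv"),
                        treatmentStart = cfg$treatmentStartDay,
                        outDir = dir)
  expect_true(all(c("calls", "summary", "km", "logrank") %in% names(out)))
  ## classes partition every arm
  for (arm in unique(out$calls$arm)) {
    s <- out$summary[out$summary$arm == arm, ]
    expect_equal(sum(s$count), sum(out$calls$arm == arm))
  }
  expect_true(file.exists(file.path(dir, "response_summary.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  ## control (all NR) dies earlier than the responding arm
  expect_true(out$logrank$p[out$logrank$arm == "triple"] < 0.05)
})
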