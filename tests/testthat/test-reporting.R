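test_that("exponential fits recover noiseless generating parameters", {
  x <- seq(0, 2, length.out = 20)
  y <- -0.5 * exp(-x / 0.1) + 0.8
  fit <- fitExponential(x, y)
  expect_equal(unname(fit$estimate["a"]), -0.5, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["b"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["c"]), 0.8, tolerance = 1e-6)

  # negative b (growing curve, as in cutoff sweeps) is reachable too
  y2 <- -7.8e-6 * exp(-x / -0.0864) + 0.7765
  fit2 <- fitExponential(x, y2)
  expect_equal(unname(fit2$estimate["c"]), 0.7765, tolerance = 1e-4)
  expect_lt(max(abs(fit2$fitted - y2)), 1e-8)
})

test_that("a constant series fits with a ~ 0 and c at the constant", {
  x <- seq(0, 5, length.out = 12)
  fit <- fitExponential(x, rep(0.62, 12))
  expect_lt(abs(fit$estimate["a"]), 1e-6)
  expect_equal(unname(fit$estimate["c"]) + unname(fit$estimate["a"]) *
                 mean(exp(-x / fit$estimate["b"])), 0.62, tolerance = 1e-6)
  expect_error(fitExponential(c(1, 2), c(1, 2)), "at least 4")
})

test_that("linear fits are exact on exact lines", {
  x <- seq(-2, 3, length.out = 15)
  fit <- fitLinear(x, 2 * x + 1)
  expect_equal(unname(fit$estimate), c(2, 1), tolerance = 1e-12)
  expect_equal(unname(fit$se), c(0, 0), tolerance = 1e-10)

  fit2 <- fitLinear(x, -0.1 * x + 0.7)
  expect_equal(unname(fit2$estimate), c(-0.1, 0.7), tolerance = 1e-12)

  # bounded influence sanity: one outlier cannot flip the slope sign
  y <- x; y[15] <- y[15] + 10
  fit3 <- fitLinear(x, y)
  expect_gt(unname(fit3$estimate["slope"]), 0)
  expect_lt(unname(fit3$estimate["slope"]), 2)

  expect_error(fitLinear(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitLinear(rep(1, 5), 1:5), "zero variance")
})

test_that("noisy fits cover the generating parameters at their standard errors", {
  # 2-SE intervals should cover each true parameter in >= 90% of trials
  xe <- seq(0, 2, length.out = 40)
  ye0 <- -0.5 * exp(-xe / 0.4) + 0.8
  xl <- seq(0, 1, length.out = 40)
  yl0 <- 0.3 * xl + 0.2
  sdN <- 0.05 * diff(range(ye0))
  okExp <- matrix(NA, 100, 3)
  okLin <- matrix(NA, 100, 2)
  set.seed(2025)
  for (i in 1:100) {
    fe <- tryCatch(fitExponential(xe, ye0 + rnorm(40, 0, sdN)),
                   error = function(e) NULL)
    if (!is.null(fe)) {
      okExp[i, ] <- abs(fe$estimate - c(-0.5, 0.4, 0.8)) <= 2 * fe$se
    }
    fl <- fitLinear(xl, yl0 + rnorm(40, 0, 0.05 * diff(range(yl0))))
    okLin[i, ] <- abs(fl$estimate - c(0.3, 0.2)) <= 2 * fl$se
  }
  expect_true(all(colMeans(okExp, na.rm = TRUE) >= 0.9))
  expect_true(all(colMeans(okLin) >= 0.9))
})

test_that("cutoff sweep behaves at its limits and keeps edges monotone", {
  cfg <- syntheticConfig(gridRows = 4, gridCols = 4, nFrames = 400,
                         clusterSpec = list(list(fraction = 0.75,
                                                 frequency = 18,
                                                 phaseJitterSd = 0.3,
                                                 frequencyDriftSd = 0)),
                         nonOscillatingFraction = 0.25, noiseSd = 0.15,
                         seed = 21)
  sim <- simulateNetwork(cfg)
  sw <- cutoffSweep(sim$signals, cutoffs = seq(0.05, 0.995, length.out = 20),
                    frames = seq(100, 300, by = 50), Tw = 70)
  expect_true(all(diff(sw$curve$meanEdges) <= 0))
  # near cutoff 1 the graph is essentially empty on noisy data
  expect_lt(sw$curve$meanC[20], 0.4)
  expect_lt(sw$curve$meanEdges[20], sw$curve$meanEdges[1])
  # near cutoff 0 the oscillating block connects almost completely
  expect_gt(sw$curve$meanC[1], 0.6)
  expect_error(cutoffSweep(sim$signals, cutoffs = c(0.5, 0.4), Tw = 70),
               "increasing")
})

test_that("cutoff sweep fit reproduces exact model data", {
  # build a curve sampled exactly from f(theta) = a exp(-theta/b) + c
  th <- seq(0.05, 0.95, length.out = 19)
  y <- -0.02 * exp(-th / 0.25) + 0.9
  fit <- fitExponential(th, y)
  expect_equal(unname(fit$estimate), c(-0.02, 0.25, 0.9), tolerance = 1e-6)
})

test_that("the pipeline is deterministic: identical config gives identical files", {
  sim <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                         nFrames = 400, seed = 33))
  cfg <- pipelineConfig(seed = 7, frameBy = 16, coherenceBy = 32, nNull = 5)
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  writeReport(runPipeline(sim$signals, cfg), d1)
  writeReport(runPipeline(sim$signals, cfg), d2)
  for (f in c("summary.csv", "membership.csv", "events.csv",
              "relations.csv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pipeline configuration is validated before any computation", {
  expect_error(pipelineConfig(cutoff = 1.2), "cutoff")
  expect_error(pipelineConfig(TwMult = -1), "TwMult")
  expect_error(pipelineConfig(mergeThreshold = 0), "mergeThreshold")
  expect_error(runPipeline(NULL, pipelineConfig()), "synthetic")
})

test_that("relation samples pair C and cluster properties frame by frame", {
  sim <- simulateNetwork(syntheticConfig(gridRows = 5, gridCols = 5,
                                         nFrames = 512, seed = 3))
  rep <- runPipeline(sim$signals,
                     pipelineConfig(seed = 2, frameBy = 8, coherenceBy = 16,
                                    nNull = 5))
  s <- reportSummary(rep)
  # every row carries a single frame's worth of aligned quantities
  expect_true(all(!duplicated(s$frame)))
  expect_equal(s$time, (s$frame - 1) * frameInterval(sim$signals))
  rel <- reportRelations(rep)
  expect_true(length(rel) >= 1)
  for (r in rel) {
    if (!isTRUE(r$failed)) expect_true(all(is.finite(r$estimate)))
  }
})

test_that("myocyte aggregation averages on the normalized grid", {
  sim1 <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                          nFrames = 400, seed = 41))
  cfg <- pipelineConfig(seed = 3, frameBy = 16, coherenceBy = 32, nNull = 5)
  r1 <- runPipeline(sim1$signals, cfg)
  agg <- aggregateMyocytes(list(r1, r1))
  # identical reports -> zero SD, mean equal to the series
  expect_true(all(agg$C$sd == 0, na.rm = TRUE))
  norm <- normalizeTime(reportSummary(r1)$time, reportSummary(r1)$C)
  expect_equal(agg$C$mean, norm$value, tolerance = 1e-12)

  # planted between-run difference shows up as the correct mean
  sim2 <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                          nFrames = 448, seed = 42))
  r2 <- runPipeline(sim2$signals, cfg)
  agg2 <- aggregateMyocytes(list(r1, r2))
  n1 <- normalizeTime(reportSummary(r1)$time, reportSummary(r1)$C)$value
  n2 <- normalizeTime(reportSummary(r2)$time, reportSummary(r2)$C)$value
  expect_equal(agg2$C$mean, (n1 + n2) / 2, tolerance = 1e-12)
  expect_equal(agg2$C$sd, apply(cbind(n1, n2), 1, sd), tolerance = 1e-12)
})
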