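make_trace <- function(samples, dt = 1e-4, meta = list(n_channels = 1L)) {
  new("CurrentTrace", dt = dt, samples = samples, meta = meta)
}

test_that("baseline is the all-points histogram mode", {
  withr::with_seed(1, {
    tr <- make_trace(2 + rnorm(2e4, 0, 0.2))
    expect_equal(estimateBaseline(tr), 2, tolerance = 0.05)
  })
  expect_equal(estimateBaseline(make_trace(rep(0, 1500))), 0)
  # 90 % closed at 0, 10 % open at 5.5: mode sits at the closed level
  withr::with_seed(2, {
    x <- c(rnorm(18000, 0, 0.4), rnorm(2000, 5.5, 0.4))
    expect_equal(estimateBaseline(make_trace(x)), 0, tolerance = 0.1)
  })
  expect_error(estimateBaseline(make_trace(rep(0, 10))), "1000 samples")
})

test_that("Gaussian mixture EM recovers the closed and open levels", {
  m <- wildtypeModel()
  tr <- renderTrace(simulateStates(m, 10, seed = 21), m, seed = 22)
  fit <- fitAmplitudeGaussians(tr, 2)
  mu <- sort(fit@means)
  expect_equal(mu[1], 0, tolerance = 0.1)
  expect_equal(mu[2], 5.5, tolerance = 0.1)
  expect_equal(fittedOpenAmplitude(fit), 5.5, tolerance = 0.1)
  expect_equal(sum(mixtureWeights(fit)), 1, tolerance = 1e-6)
  expect_identical(sum(fit@classMap == "closed"), 1L)
  # the open-component weight reflects the realized open fraction of the sweep
  realized <- openTimeFraction(simulateStates(m, 10, seed = 21), m)
  expect_lt(abs(fit@weights[fit@classMap == "open"] - realized), 0.02)

  # single level, k = 1: mean equals the level
  one <- fitAmplitudeGaussians(make_trace(withr::with_seed(3, rnorm(5e3, -3, 0.3))), 1)
  expect_equal(one@means, -3, tolerance = 0.02)
  expect_error(fitAmplitudeGaussians(tr, 0), "k must be")
})

test_that("EM agrees with an independent mixture fitter", {
  withr::local_package("mclust")
  m <- wildtypeModel()
  tr <- renderTrace(simulateStates(m, 2, seed = 31), m, seed = 32)
  fit <- fitAmplitudeGaussians(tr, 2)
  ref <- Mclust(traceSamples(tr), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(logLikelihood(fit), as.numeric(ref$loglik), tolerance = 1e-3)
})

test_that("half-amplitude idealization recovers a noiseless square wave", {
  # 50 samples closed, 30 open at 5, 20 closed
  x <- c(rep(0, 50), rep(5, 30), rep(0, 20))
  rec <- halfAmplitudeIdealize(make_trace(x), baseline = 0, open_amplitude = 5,
                               dead_time = 0)
  ev <- dwellEvents(rec)
  expect_equal(ev$level, c(0, 1, 0))
  expect_equal(ev$duration_s, c(50, 30, 20) * 1e-4, tolerance = 1e-12)
  expect_equal(ev$mean_pA, c(0, 5, 0))
  expect_equal(sum(ev$duration_s), length(x) * 1e-4)

  # constant closed trace: one closed event spanning the sweep
  rec0 <- halfAmplitudeIdealize(make_trace(rep(0, 1000)), baseline = 0,
                                open_amplitude = 5)
  expect_equal(nrow(dwellEvents(rec0)), 1L)
  expect_equal(dwellEvents(rec0)$class, "closed")
  expect_error(halfAmplitudeIdealize(make_trace(x), baseline = 0,
                                     open_amplitude = 0), "non-zero")
})

test_that("idealization matches the dead-time-filtered generator path", {
  m <- model_from(rate_sets$wt_like)
  for (s in c(7, 19)) {
    sq <- simulateStates(m, 10, seed = s)
    tr <- renderTrace(sq, m, noise_sd = 0, filter_cutoff = NA)
    rec <- halfAmplitudeIdealize(tr, baseline = 0, open_amplitude = 5.5,
                                 dead_time = 2e-4)
    truth <- idealizeFromPath(sq, m, dead_time = 2e-4)
    n_t <- nrow(dwellEvents(truth)); n_r <- nrow(dwellEvents(rec))
    expect_lt(abs(n_r - n_t) / n_t, 0.10)
    expect_equal(sum(dwellEvents(rec)$duration_s),
                 length(traceSamples(tr)) * samplingInterval(tr),
                 tolerance = 1e-9)
  }
  # with realistic noise the resolvable event count stays within 10 %
  sq <- simulateStates(m, 10, seed = 57)
  trn <- renderTrace(sq, m, noise_sd = 0.5, seed = 58)
  recn <- halfAmplitudeIdealize(trn, baseline = 0, open_amplitude = 5.5)
  truth <- idealizeFromPath(sq, m, dead_time = 2e-4)
  expect_lt(abs(nrow(dwellEvents(recn)) - nrow(dwellEvents(truth))) /
              nrow(dwellEvents(truth)), 0.10)
})

test_that("idealization is invariant to a constant offset with re-estimated baseline", {
  m <- wildtypeModel()
  tr <- renderTrace(simulateStates(m, 5, seed = 41), m, seed = 42)
  shifted <- new("CurrentTrace", dt = tr@dt, samples = traceSamples(tr) + 3.7,
                 meta = tr@meta)
  r1 <- halfAmplitudeIdealize(tr, open_amplitude = 5.5)
  r2 <- halfAmplitudeIdealize(shifted, open_amplitude = 5.5)
  expect_equal(dwellEvents(r1)$level, dwellEvents(r2)$level)
  expect_equal(dwellEvents(r1)$duration_s, dwellEvents(r2)$duration_s,
               tolerance = 1e-9)
})

test_that("dead-time imposition merges unresolvable events and is idempotent", {
  ev <- data.frame(level = c(0L, 1L, 0L), class = c("closed", "open", "closed"),
                   start_s = c(0, 0.010, 0.01005),
                   duration_s = c(0.010, 0.00005, 0.008),
                   mean_pA = c(0, 5.5, 0))
  rec <- new("IdealizedRecord", events = ev, deadTime = 0, meta = list())
  out <- imposeDeadTime(rec, 2e-4)
  expect_equal(nrow(dwellEvents(out)), 1L)
  expect_equal(dwellEvents(out)$duration_s, 0.01805)
  expect_equal(dwellEvents(out)$class, "closed")

  # dead_time 0 is the identity
  expect_equal(dwellEvents(imposeDeadTime(rec, 0)), ev)
  # idempotence
  expect_identical(dwellEvents(imposeDeadTime(out, 2e-4)), dwellEvents(out))
  # applying twice = once on a long random record
  m <- wildtypeModel()
  tr <- renderTrace(simulateStates(m, 5, seed = 77), m, seed = 78)
  r1 <- halfAmplitudeIdealize(tr, open_amplitude = 5.5, dead_time = 3e-4)
  r2 <- imposeDeadTime(r1, 3e-4)
  expect_identical(dwellEvents(r1), dwellEvents(r2))
  # a too-short leading event is absorbed forward
  ev2 <- data.frame(level = c(1L, 0L), class = c("open", "closed"),
                    start_s = c(0, 1e-4), duration_s = c(1e-4, 0.01),
                    mean_pA = c(5.5, 0))
  rec2 <- new("IdealizedRecord", events = ev2, deadTime = 0, meta = list())
  out2 <- imposeDeadTime(rec2, 2e-4)
  expect_equal(dwellEvents(out2)$class, "closed")
  expect_equal(dwellEvents(out2)$duration_s, 0.0101)
})

test_that("multi-channel traces idealize to integer open levels", {
  m <- model_from(rate_sets$classic)
  tr <- superposeChannels(2, m, 10, noise_sd = 0.4, seed = 91)
  rec <- halfAmplitudeIdealize(tr, baseline = 0, open_amplitude = 5.5)
  ev <- dwellEvents(rec)
  expect_true(all(ev$level %in% 0:2))
  expect_true(any(ev$level == 2))     # double openings occur at Po ~ 0.14
  st <- empiricalOpenProbability(rec, n_channels = 2)
  expect_lt(abs(openProbability(st) - analyticOpenProbability(m)), 0.03)
})
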