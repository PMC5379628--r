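test_that("buildThreeState assembles the chain generator and validates rates", {
  m <- buildThreeState(100, 50, 20, 10, 5.5)
  Q <- generatorMatrix(m)
  expect_equal(Q[1, ], c(-100, 100, 0))          # O row: exit only to C2
  expect_equal(Q[1, 3], 0)                        # no direct O <-> C1
  expect_equal(Q[3, 1], 0)
  expect_equal(unname(rowSums(Q)), rep(0, 3))
  expect_identical(stateClasses(m), c("open", "closed", "closed"))

  sym <- buildThreeState(1, 1, 1, 1, 1)
  expect_equal(unname(rowSums(generatorMatrix(sym))), rep(0, 3))

  expect_error(buildThreeState(100, 50, 20, -1, 5.5), "k_12 must be > 0")
  expect_error(buildThreeState(100, 0, 20, 10, 5.5), "k_co must be > 0")
  expect_error(buildThreeState(100, 50, 20, 10, Inf), "open_amplitude")
})

test_that("stationary distribution solves pi Q = 0 and normalizes", {
  m <- buildThreeState(100, 50, 20, 10)
  # hand-derived by detailed balance on the chain: pi proportional to (1, 2, 4)
  expect_equal(unname(stationaryDistribution(m)), c(1, 2, 4) / 7,
               tolerance = 1e-9)
  # symmetric two-state chain
  two <- new("RateModel", stateLabels = c("O", "C"),
             stateClass = c("open", "closed"),
             generator = matrix(c(-5, 5, 5, -5), 2, byrow = TRUE),
             openAmplitude = 5.5, closedLevel = 0)
  expect_equal(unname(stationaryDistribution(two)), c(0.5, 0.5))
  for (rs in rate_sets) {
    pi_hat <- stationaryDistribution(model_from(rs))
    expect_equal(sum(pi_hat), 1, tolerance = 1e-9)
    expect_true(all(pi_hat > 0))
    expect_equal(drop(pi_hat %*% generatorMatrix(model_from(rs))),
                 rep(0, 3), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("analytic open probability matches the chain closed form", {
  m <- buildThreeState(100, 50, 20, 10)
  expect_equal(analyticOpenProbability(m), 1 / 7, tolerance = 1e-12)
  for (rs in rate_sets) {
    po <- analyticOpenProbability(model_from(rs))
    closed_form <- 1 / (1 + rs[1] / rs[2] + rs[1] * rs[3] / (rs[2] * rs[4]))
    expect_equal(po, closed_form, tolerance = 1e-12)
    # scale invariance
    for (c_scale in c(0.5, 3, 20)) {
      expect_equal(analyticOpenProbability(model_from(rs * c_scale)), po,
                   tolerance = 1e-12)
    }
  }
  # k_21 -> 0 limit approaches the two-state closed form k_co/(k_co + k_oc)
  m_eps <- buildThreeState(100, 50, 1e-7, 10)
  expect_equal(analyticOpenProbability(m_eps), 50 / 150, tolerance = 1e-6)
})

test_that("analytic dwell mixtures come from the class sub-generator spectrum", {
  m <- buildThreeState(100, 50, 20, 10)
  op <- analyticDwellMixture(m, "open")
  expect_equal(timeConstants(op), 1 / 100, tolerance = 1e-12)
  expect_equal(mixtureWeights(op), 1)

  cl <- analyticDwellMixture(m, "closed")
  # oracle: direct eigendecomposition of the negated closed sub-generator
  ev <- eigen(matrix(c(70, -20, -10, 10), 2, byrow = TRUE))$values
  expect_equal(sort(timeConstants(cl)), sort(1 / ev), tolerance = 1e-9)
  expect_equal(timeConstants(cl), c(0.1463, 0.01367), tolerance = 1e-3)
  expect_equal(sum(mixtureWeights(cl)), 1, tolerance = 1e-9)
  expect_true(all(diff(timeConstants(cl)) < 0))

  # k_21 -> 0: C1 effectively unreachable, single tau = 1/k_co
  cl0 <- analyticDwellMixture(buildThreeState(100, 50, 1e-9, 10), "closed")
  i <- which.min(abs(timeConstants(cl0) - 1 / 50))
  expect_gt(mixtureWeights(cl0)[i], 0.999)
  expect_equal(timeConstants(cl0)[i], 1 / 50, tolerance = 1e-6)

  # tau scales as 1/c under rate scaling
  cl2 <- analyticDwellMixture(buildThreeState(200, 100, 40, 20), "closed")
  expect_equal(timeConstants(cl2), timeConstants(cl) / 2, tolerance = 1e-9)
})

test_that("Gillespie simulation is seed-deterministic and time-exact", {
  m <- model_from(rate_sets$classic)
  s1 <- simulateStates(m, 5, seed = 42)
  s2 <- simulateStates(m, 5, seed = 42)
  expect_identical(s1@states, s2@states)
  expect_identical(s1@durations, s2@durations)
  expect_false(identical(s1@durations, simulateStates(m, 5, seed = 43)@durations))
  expect_equal(sum(s1@durations), 5, tolerance = 1e-12)
  expect_true(all(diff(s1@states) != 0))
  expect_true(s1@truncatedLast)
  expect_error(simulateStates(m, 0, seed = 1), "duration")
})

test_that("long-run occupancy converges to the stationary distribution", {
  # two-state symmetric: open fraction 1/2 within 3 MC SE
  two <- new("RateModel", stateLabels = c("O", "C"),
             stateClass = c("open", "closed"),
             generator = matrix(c(-50, 50, 50, -50), 2, byrow = TRUE),
             openAmplitude = 5.5, closedLevel = 0)
  fr <- vapply(1:12, function(b)
    openTimeFraction(simulateStates(two, 20, seed = 100 + b), two), numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 1e-4)

  # three-state occupancy vs (1/7, 2/7, 4/7)
  m <- model_from(rate_sets$classic)
  occ <- t(vapply(1:12, function(b)
    stateOccupancy(simulateStates(m, 25, seed = 300 + b), m), numeric(3)))
  mc <- segment_mc(occ)
  expect_true(all(abs(mc$mean - c(1, 2, 4) / 7) < 3 * mc$se + 1e-3))
})

test_that("renderTrace reproduces the path and emulates noise and filtering", {
  m <- model_from(rate_sets$classic)
  sq <- simulateStates(m, 2, seed = 5)
  # noiseless, unfiltered: exact piecewise-constant recovery at sample times
  tr <- renderTrace(sq, m, dt = 1e-4, noise_sd = 0, filter_cutoff = NA)
  lev_true <- gatekin:::.sequence_levels(sq, m, 1e-4, length(traceSamples(tr)))
  expect_equal(traceSamples(tr), 5.5 * lev_true)
  expect_equal(samplingInterval(tr), 1e-4)

  # noise sd on a constant-closed path: sample sd ~ 0.5 pre-filter
  closed_seq <- new("StateSequence", states = 3L, durations = 10,
                    startTime = 0, seed = 1L, truncatedLast = TRUE)
  trn <- renderTrace(closed_seq, m, dt = 1e-4, noise_sd = 0.5,
                     filter_cutoff = NA, seed = 9)
  n <- length(traceSamples(trn))
  expect_equal(sd(traceSamples(trn)), 0.5, tolerance = 3 / sqrt(2 * n) * 2)

  # filtering reduces the noise variance for the same seed
  trf <- renderTrace(closed_seq, m, dt = 1e-4, noise_sd = 0.5,
                     filter_cutoff = 1000, seed = 9)
  expect_lt(var(traceSamples(trf)), var(traceSamples(trn)))
  expect_error(renderTrace(sq, m, dt = -1), "dt")
})

test_that("superposed channels occupy integer amplitude levels", {
  m <- model_from(rate_sets$classic)
  tr2 <- superposeChannels(2, m, 5, noise_sd = 0, filter_cutoff = NA, seed = 3)
  lev <- sort(unique(round(traceSamples(tr2) / 5.5)))
  expect_true(all(lev %in% 0:2))
  expect_identical(traceMeta(tr2)$n_channels, 2L)

  # n = 1 equals a plain render under the derived sub-seeds
  s1 <- superposeChannels(1, m, 3, noise_sd = 0.4, filter_cutoff = 5000, seed = 11)
  path <- simulateStates(m, 3, seed = gatekin:::.child_seed(11L, 1))
  r1 <- renderTrace(path, m, noise_sd = 0.4, filter_cutoff = 5000,
                    seed = gatekin:::.child_seed(11L, 0L))
  expect_equal(traceSamples(s1), traceSamples(r1))

  # n = 3 long-run mean current -> 3 * A * Po
  po <- analyticOpenProbability(m)
  means <- vapply(1:8, function(b)
    mean(traceSamples(superposeChannels(3, m, 12, noise_sd = 0,
                                        filter_cutoff = NA, seed = 700 + b))),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 3 * 5.5 * po), 3 * se + 0.02)
  expect_error(superposeChannels(0, m, 1), "n must be")
})

test_that("model JSON and trace CSV round-trips preserve the objects", {
  m <- wildtypeModel()
  f <- tempfile(fileext = ".json")
  writeRateModel(m, f)
  m2 <- readRateModel(f)
  expect_equal(generatorMatrix(m2), generatorMatrix(m))
  expect_equal(openAmplitude(m2), openAmplitude(m))

  tr <- renderTrace(simulateStates(m, 0.5, seed = 2), m, seed = 2)
  csv <- tempfile(fileext = ".csv")
  writeTrace(tr, csv)
  tr2 <- readTrace(csv)
  expect_equal(traceSamples(tr2), traceSamples(tr), tolerance = 1e-12)
  expect_equal(samplingInterval(tr2), samplingInterval(tr))
  expect_equal(tr2@meta$filter_Hz, 5000)
  expect_true(file.exists(sub("\\.csv$", ".meta.json", csv)))
})
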