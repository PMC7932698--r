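# Fluorescence conservation, association-rate fitting, binding models.

test_that("conservation statistic matches the symmetric closed form", {
  # algebraic fixture: Iu = M(1 - t/T), Ic = M t/T
  Tt <- 10; M <- 100
  t <- seq(0, Tt, by = 0.5)
  tr <- SegmentTrace(time = t, Iu = M * (1 - t / Tt), Ic = M * t / Tt,
                     frameInterval = 0.5)
  out <- yoyoConservation(tr)
  expect_equal(out, 2 * t / Tt - 1, tolerance = 1e-12)
  expect_equal(range(out), c(-1, 1), tolerance = 1e-12)
  expect_equal(out[t == Tt / 2], 0, tolerance = 1e-12)

  # division-by-zero contract
  tr0 <- SegmentTrace(time = t, Iu = M * (1 - t / Tt), Ic = rep(0, length(t)))
  expect_error(yoyoConservation(tr0), "Ic")
})

test_that("conservation statistic holds on noiseless kymogram segments", {
  sp <- fullCompactionSpec(association_rate_kappa = 0, dna_intensity = 50,
                           noise_sigma = 0, compacted_gain = 1)
  sim <- genKymogram(sp)
  trace <- computeSegmentTrace(sim$kymogram, sim$truth$endTrack)
  out <- yoyoConservation(trace)
  t <- trace@time
  Tt <- (sp$end_start - 1) / sp$compaction_rate_v * sp$frame_interval
  expect_lt(max(abs(out - (2 * t / Tt - 1))), 1e-6)
})

test_that("uncompacted density slope recovers kappa", {
  # exact line rho = 3 + 2 * frame
  f <- 0:19
  tr <- SegmentTrace(time = f, Iu = (3 + 2 * f) * 10, Ic = f,
                     rho = 3 + 2 * f, lc = f, frameInterval = 1)
  fit <- fitUncompactedDensityRate(tr)
  expect_equal(fit$kappa, 2, tolerance = 1e-12)
  expect_false(fit$degenerate)

  # constant density: zero rate, flagged degenerate
  trc <- SegmentTrace(time = f, Iu = rep(30, 20), Ic = f,
                      rho = rep(3, 20), lc = f, frameInterval = 1)
  fitc <- fitUncompactedDensityRate(trc)
  expect_equal(fitc$kappa, 0)
  expect_equal(fitc$r_squared, 0)
  expect_true(fitc$degenerate)

  # noisy generator: within 10%
  sp <- kymogramSpec(n_frames = 90, end_start = 200, compaction_rate_v = 2,
                     association_rate_kappa = 0.5, dna_intensity = 0,
                     noise_sigma = 2, seed = 5)
  sim <- genKymogram(sp)
  trace <- computeSegmentTrace(sim$kymogram, sim$truth$endTrack)
  fitn <- fitUncompactedDensityRate(trace)
  expect_lt(abs(fitn$kappa - 0.5) / 0.5, 0.1)
})

test_that("association models give kappa*v*t^2 and half of it when blocked", {
  expect_equal(modelIntensityEqual(2, 3, 2), 24)
  expect_equal(modelIntensityBlocked(2, 3, 2), 12)
  expect_equal(modelIntensityEqual(2, 3, 0), 0)
  expect_equal(modelIntensityEqual(0, 3, 5), 0)
  expect_error(modelIntensityEqual(-1, 3, 5), "non-negative")

  # blocked model equals the capture-time integral of rho(s) * v
  for (s in 1:10) {
    par <- withr::with_seed(s, runif(3, 0.1, 5))
    quad <- stats::integrate(function(u) par[1] * u * par[2], 0, par[3],
                             rel.tol = 1e-12)$value
    expect_equal(modelIntensityBlocked(par[1], par[2], par[3]), quad,
                 tolerance = 1e-9)
  }
})

test_that("normalized compacted intensity separates equal from blocked binding", {
  # exact construction Ic = rho * lc gives exactly 1
  f <- 1:30
  tr <- SegmentTrace(time = f, Iu = rep(1, 30), Ic = (2 + f) * f,
                     rho = 2 + f, lc = f, frameInterval = 1)
  expect_equal(unname(normalizedCompactedIntensity(tr)), rep(1, 30),
               tolerance = 1e-12)

  mkTrace <- function(binding, seed) {
    sp <- kymogramSpec(n_frames = 90, end_start = 200,
                       compaction_rate_v = 2, association_rate_kappa = 0.5,
                       dna_intensity = 0, noise_sigma = 2,
                       binding = binding, seed = seed)
    sim <- genKymogram(sp)
    computeSegmentTrace(sim$kymogram, sim$truth$endTrack)
  }
  late <- 30:90  # once the punctum holds appreciable signal
  eq <- normalizedCompactedIntensity(mkTrace("equal", 3))
  expect_gt(mean(eq[late], na.rm = TRUE), 0.9)
  expect_lt(mean(eq[late], na.rm = TRUE), 1.1)
  bl <- normalizedCompactedIntensity(mkTrace("blocked", 3))
  expect_gt(mean(bl[late], na.rm = TRUE), 0.4)
  expect_lt(mean(bl[late], na.rm = TRUE), 0.6)

  # all-masked contract
  trm <- SegmentTrace(time = f, Iu = rep(1, 30), Ic = rep(1, 30),
                      rho = rep(1, 30), lc = rep(0, 30), frameInterval = 1)
  expect_error(normalizedCompactedIntensity(trm), "masked")
})

test_that("valency helpers follow their fixed conversions", {
  expect_equal(pseudoFirstOrderRatio(5, 0.5), 10)
  expect_error(pseudoFirstOrderRatio(0, 1), "positive")
  expect_equal(bindingSitesPerDna(2700), 45)
  expect_equal(bindingSitesPerDna(147), 2)
  expect_error(bindingSitesPerDna(-1), "positive")
})
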