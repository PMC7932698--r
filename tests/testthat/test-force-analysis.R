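# Worm-like chain, energy between curves, deficits, site-size conversion.

test_that("Marko-Siggia force has the right values, limits and monotonicity", {
  p <- wlcParams(persistenceLength = 50, contourLength = 16)
  expect_equal(wlcForce(0, p), 0)
  expect_equal(wlcForce(8, p), (4.114 / 50) * 1.25, tolerance = 1e-12)

  x <- seq(0, 15.9, by = 0.05)
  expect_true(all(diff(wlcForce(x, p)) > 0))
  expect_error(wlcForce(16, p), "contour")
  expect_error(wlcForce(-1, p), "non-negative")

  # entropic-spring limit at small relative extension (the interpolation
  # exceeds the pure spring by u/2 + O(u^2), so 5% holds up to u ~ 0.08)
  xs <- seq(0.01, 0.08, by = 0.01) * 16
  spring <- 3 * 4.114 / (2 * 50 * 16) * xs
  expect_true(all(abs(wlcForce(xs, p) - spring) / spring < 0.05))
})

test_that("energy between curves integrates rectangles exactly in kBT/bp", {
  x <- seq(1, 5.114, length.out = 412)  # span exactly 4.114 um
  bare <- ForceExtensionCurve(x, rep(2, length(x)))
  same <- energyBetweenCurves(bare, bare, 500)
  expect_equal(same@energyPerBp, 0)

  hp1 <- ForceExtensionCurve(x, rep(3, length(x)))  # +1 pN offset
  est <- energyBetweenCurves(bare, hp1, 1000)
  expect_equal(est@area, 4.114, tolerance = 1e-12)
  expect_equal(est@energyPerBp, 1, tolerance = 1e-12)

  # linear in the offset, additive over disjoint intervals
  twice <- energyBetweenCurves(bare,
    ForceExtensionCurve(x, rep(4, length(x))), 1000)
  expect_equal(twice@area, 2 * est@area, tolerance = 1e-12)
  xa <- c(x[x < 3], 3); xb <- c(3, x[x > 3])  # shared breakpoint, no gap
  a1 <- energyBetweenCurves(ForceExtensionCurve(xa, rep(2, length(xa))),
                            ForceExtensionCurve(xa, rep(3, length(xa))),
                            1000)
  a2 <- energyBetweenCurves(ForceExtensionCurve(xb, rep(2, length(xb))),
                            ForceExtensionCurve(xb, rep(3, length(xb))),
                            1000)
  expect_equal(a1@area + a2@area, est@area, tolerance = 1e-9)

  disjoint <- ForceExtensionCurve(x + 10, rep(3, length(x)))
  expect_error(energyBetweenCurves(bare, disjoint, 100), "disjoint")
  expect_error(energyBetweenCurves(bare, hp1, 0), "positive")
})

test_that("unit conversion between pN um and kBT round-trips", {
  v <- c(1e-6, 0.4114, 3, 250)
  expect_equal(pnUmFromKbt(kbtFromPnUm(v)), v, tolerance = 1e-12)
  expect_equal(kbtFromPnUm(4.114e-3), 1, tolerance = 1e-12)
})

test_that("generator ground-truth area is recovered by the estimator", {
  off <- list(type = "gaussian", amplitude = 3, center = 8, width = 2)
  clean <- genForceExtension(forceExtensionSpec(noise_sigma = 0,
                                                extra_force_offset = off))
  est <- energyBetweenCurves(clean$bare, clean$hp1,
                             clean$truth$compacted_bp)
  expect_lt(abs(est@area - clean$truth$area) / clean$truth$area, 0.01)

  noisy <- genForceExtension(forceExtensionSpec(noise_sigma = 0.5,
                                                extra_force_offset = off,
                                                seed = 3))
  estN <- energyBetweenCurves(noisy$bare, noisy$hp1,
                              noisy$truth$compacted_bp)
  expect_lt(abs(estN@area - noisy$truth$area) / noisy$truth$area, 0.05)
})

test_that("extension deficit converts to compacted base pairs", {
  x <- seq(0.5, 16, by = 0.1)
  bare <- ForceExtensionCurve(x, 20 * x / 15)   # reaches 20 pN at 15 um
  hp1x <- x[x < 14]
  hp1 <- ForceExtensionCurve(hp1x, 20 * hp1x / 12)  # 20 pN at 12 um
  bp <- compactedLengthFromDeficit(bare, hp1, atForce = 20,
                                   totalBp = 48502)
  expect_equal(bp, 3 / (15 / 48502), tolerance = 1e-6)  # ~9,700 bp

  expect_equal(compactedLengthFromDeficit(bare, bare, 10), 0,
               tolerance = 1e-12)
  expect_error(compactedLengthFromDeficit(bare, hp1, atForce = 100),
               "range")

  sim <- genForceExtension(forceExtensionSpec(compacted_bp = 5000,
                                              noise_sigma = 0.2, seed = 2))
  bpSim <- compactedLengthFromDeficit(sim$bare, sim$hp1, atForce = 20)
  expect_lt(abs(bpSim - 5000) / 5000, 0.05)
})

test_that("binding-site size conversion rounds nm to base pairs", {
  expect_equal(bindingSiteSize(22.2), 65)   # open dimer conformation
  expect_equal(bindingSiteSize(12.9), 38)   # closed dimer conformation
  expect_equal(bindingSiteSize(0.34), 1)
  expect_error(bindingSiteSize(0), "positive")
})

test_that("rupture detector flags abrupt force drops only", {
  x <- seq(1, 10, by = 0.1)
  f <- 2 * x
  f[50:length(f)] <- f[50:length(f)] - 3  # 3 pN drop at one step
  r <- detectRuptures(ForceExtensionCurve(x, f), dropThreshold = 2)
  expect_equal(nrow(r), 1)
  expect_equal(r$index, 49)
  expect_equal(r$force_drop_pN, 3 - 0.2, tolerance = 1e-9)
  expect_equal(nrow(detectRuptures(ForceExtensionCurve(x, 2 * x))), 0)
})
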