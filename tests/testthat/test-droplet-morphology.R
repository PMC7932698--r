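# Fourier high-pass, multi-scale Canny segmentation, radius statistics.

test_that("Fourier high-pass removes the baseband and keeps the passband", {
  expect_lt(max(abs(highpassFourier(matrix(5, 32, 32)))), 1e-9)

  cb <- outer(1:64, 1:64, function(i, j) (-1)^(i + j))
  expect_lt(sqrt(mean((highpassFourier(cb, cutoff_frac = 0.05) - cb)^2)),
            1e-6)

  expect_error(highpassFourier(cb, cutoff_frac = 0), "cutoff")
  expect_error(highpassFourier(cb, cutoff_frac = 1), "cutoff")

  # slow illumination gradient is removed while rim contrast survives
  sp <- dropletFieldSpec(image_shape = c(128, 128), radii = c(6, 10),
                         noise_sigma = 0, seed = 3)
  im <- genDropletImage(sp)
  plane <- outer(seq(0, 0.5, length.out = 128),
                 seq(0, 0.25, length.out = 128), "+")
  hp <- highpassFourier(im$image + plane, cutoff_frac = 0.05)
  pf <- stats::lm.fit(cbind(1, row(hp)[TRUE], col(hp)[TRUE]), hp[TRUE])
  planeRms <- sqrt(mean(pf$fitted.values^2))
  expect_lt(planeRms, 0.05 * sp$edge_ring_contrast)
})

test_that("multi-scale Canny handles blank input and duplicate sigmas", {
  blank <- matrix(0, 64, 64)
  expect_equal(max(multiscaleCanny(blank)), 0)
  expect_error(multiscaleCanny(blank, sigmas = numeric(0)), "sigma")

  sp <- dropletFieldSpec(image_shape = c(96, 96), radii = c(5, 9),
                         noise_sigma = 0, seed = 2)
  im <- genDropletImage(sp)$image
  hp <- highpassFourier(im)
  expect_identical(multiscaleCanny(hp, sigmas = c(2, 2, 2)),
                   multiscaleCanny(hp, sigmas = 2))
})

test_that("scales complement each other on a constructed two-scale field", {
  fx <- twoScaleDropletFixture()
  detect <- function(sigmas) {
    ds <- filterRegions(regionProperties(multiscaleCanny(
      highpassFourier(fx$image), sigmas = sigmas)))
    sort(matchDroplets(fx$centers, fx$radii, ds)$matches$truth_index)
  }
  expect_identical(detect(1), 1L)        # fine scale: small droplet only
  expect_identical(detect(4), 2L)        # coarse scale: large droplet only
  expect_identical(detect(c(1, 4)), c(1L, 2L))  # combined: both
})

test_that("region filter applies the area and eccentricity thresholds exactly", {
  mk <- function(area, ecc) data.frame(
    centroid_row = 1, centroid_col = 1, area_px = area,
    radius_px = sqrt(area / pi), radius_um = sqrt(area / pi),
    eccentricity = ecc, perimeter_px = 1)
  regions <- rbind(mk(3, 0.5),     # at the area threshold: removed
                   mk(10, 0.94),   # at the eccentricity threshold: kept
                   mk(10, 0.95),   # just above: removed
                   mk(4, 0.2))     # plainly fine
  out <- dropletRegions(filterRegions(regions))
  expect_equal(nrow(out), 2)
  expect_true(all(out$area_px > 3 & out$eccentricity <= 0.94))

  # pure and idempotent
  again <- dropletRegions(filterRegions(out))
  expect_identical(again, out)
  expect_equal(nrow(dropletRegions(filterRegions(mk(1, 0)[0, ]))), 0)
})

test_that("segmentation recovers noiseless synthetic fields", {
  sc <- pooledSegmentationScore(1:4)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})

test_that("radius CCD follows the >= convention and integrates to the mean", {
  d <- radiusCcd(c(1, 2, 3), nBoot = 50, seed = 1)
  ccdAt2 <- d@ccd[d@grid == 2]
  expect_equal(ccdAt2, 2 / 3)
  expect_equal(expectedRadius(d), 2)
  expect_equal(d@ccd[1], 1)          # CCD(0) = 1
  expect_true(all(diff(d@ccd) <= 1e-12))

  r <- withr::with_seed(9, rgamma(200, 2, 1))
  d2 <- radiusCcd(r, nBoot = 50, seed = 1)
  expect_equal(expectedRadius(d2), mean(r), tolerance = 1e-9)
  expect_equal(d2@ccd[which(d2@grid == min(r))], 1)

  expect_error(radiusCcd(numeric(0)), "empty")
})

test_that("bootstrap interval covers the true mean radius", {
  hits <- vapply(1:50, function(s) {
    r <- withr::with_seed(1000 + s, rexp(500, 1 / 5))
    d <- radiusCcd(r, nBoot = 500, ciLevel = 0.95, seed = s)
    d@expectedRadiusCi[1] <= 5 && 5 <= d@expectedRadiusCi[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("power-law fit is exact on exact data and recovers noisy exponents", {
  cc <- c(1, 4, 16)
  fit <- fitPowerLaw(cc, 2 * cc^0.5)
  expect_equal(fit@amplitude, 2, tolerance = 1e-9)
  expect_equal(fit@exponent, 0.5, tolerance = 1e-9)

  expect_error(fitPowerLaw(1, 2), "3 conditions")
  expect_error(fitPowerLaw(c(1, 2, 3), c(-1, 1, 1)), "positive")

  errs <- vapply(1:20, function(s) {
    conc <- 2^(0:7)
    r <- 1.5 * conc^0.33 *
      withr::with_seed(s, exp(rnorm(8, sd = 0.05)))
    fitPowerLaw(conc, r)@exponent - 0.33
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})
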