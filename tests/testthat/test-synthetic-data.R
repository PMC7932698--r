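# Generators: determinism, identity cases, ground-truth contracts.

test_that("kymogram generator honours identity and linear-motion cases", {
  # static, silent spec: every frame equals frame 0
  sp <- kymogramSpec(n_frames = 20, n_pixels = 64, end_start = 40,
                     compaction_rate_v = 0, association_rate_kappa = 0,
                     noise_sigma = 0)
  m <- intensity(genKymogram(sp)$kymogram)
  for (i in 2:nrow(m)) expect_identical(m[i, ], m[1, ])

  # linear motion: v = 2 px/frame from 100 puts the end at 50 after 25 frames
  sp2 <- kymogramSpec(n_frames = 40, n_pixels = 128, end_start = 100,
                      compaction_rate_v = 2, noise_sigma = 0)
  truth <- genKymogram(sp2)$truth
  expect_equal(truth$end_px[26], 50)  # frame index 25, 0-based
  expect_equal(truth$end_px[1], 100)
  # the true end never passes the tether
  expect_true(all(truth$end_px >= 1))
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  sp <- kymogramSpec(noise_sigma = 5, seed = 42)
  expect_identical(intensity(genKymogram(sp)$kymogram),
                   intensity(genKymogram(sp)$kymogram))

  ds <- dropletFieldSpec(radii = c(4, 7), noise_sigma = 0.05, seed = 42)
  expect_identical(genDropletImage(ds)$image, genDropletImage(ds)$image)

  fs <- frapSpec(n_frames = 30, noise_sigma = 0.5, seed = 42)
  expect_identical(genFrapMovie(fs)$movie, genFrapMovie(fs)$movie)

  fe <- forceExtensionSpec(noise_sigma = 0.3, seed = 42)
  expect_identical(force(genForceExtension(fe)$hp1),
                   force(genForceExtension(fe)$hp1))

  # no global RNG state leak
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(genKymogram(sp)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless kymogram conserves injected intensity at unit gain", {
  sp <- fullCompactionSpec(association_rate_kappa = 0.5, dna_intensity = 50,
                           noise_sigma = 0, compacted_gain = 1,
                           background = 100)
  sim <- genKymogram(sp)
  m <- intensity(sim$kymogram)
  tFinal <- nrow(m) - 1
  L <- sp$end_start - 1  # DNA pixels swept during full compaction
  expected <- ncol(m) * sp$background + sp$dna_intensity * L +
    sp$association_rate_kappa * tFinal * L
  expect_equal(sum(m[nrow(m), ]), expected, tolerance = 1e-12)
  # truth record always accompanies the data
  expect_s4_class(sim$truth$endTrack, "EndTrack")
  expect_equal(length(sim$truth$end_px), sp$n_frames)
})

test_that("kymogram spec validation rejects bad geometry and rates", {
  expect_error(kymogramSpec(n_frames = 0), "dimensions")
  expect_error(kymogramSpec(compaction_rate_v = -1), "non-negative")
  expect_error(kymogramSpec(end_start = 300, n_pixels = 256), "end_start")
})

test_that("droplet image generator matches its stated geometry", {
  # zero droplets: pure background
  sp0 <- dropletFieldSpec(radii = numeric(0), noise_sigma = 0)
  out0 <- genDropletImage(sp0)
  expect_true(all(out0$image == sp0$background))
  expect_equal(length(out0$truth$radii), 0)

  # single droplet: the radial intensity extremum sits at the rim
  sp1 <- dropletFieldSpec(image_shape = c(64, 64), radii = 10,
                          centers = matrix(c(32, 32), 1),
                          interior_contrast = 0, noise_sigma = 0)
  img <- genDropletImage(sp1)$image
  dev <- abs(img - sp1$background)
  idx <- which(dev == max(dev), arr.ind = TRUE)[1, ]
  expect_equal(sqrt(sum((idx - c(32, 32))^2)), 10,
               tolerance = 0.25)  # extremum within the ring width of R

  # overlapping droplets are rejected
  expect_error(dropletFieldSpec(radii = c(10, 10),
                                centers = matrix(c(30, 30, 35, 35), 2,
                                                 byrow = TRUE)),
               "overlap")
})

test_that("FRAP movie generator: uniform decay, no bleach, half-time truth", {
  dp0 <- list(a_mean = 0.7, b_mean = 0.3, k1_0 = 0.05, alpha1 = 0,
              beta1 = 0, k2_0 = 0.005, alpha2 = 0, beta2 = 0)
  # ROI in an empty corner: nothing is bleached, all droplets decay alike
  sp <- frapSpec(n_frames = 40, decay_params = dp0, noise_sigma = 0,
                 bleach_roi = c(1, 4, 1, 4))
  mv <- genFrapMovie(sp)
  expect_true(is.na(mv$truth$bleached_index))
  seg <- segmentFrapDroplets(mv$movie[[1]])
  traces <- vapply(seq_len(nrow(seg$centroids)), function(i) {
    m <- seg$labels == i
    vapply(mv$movie, function(f) mean(f[m]), numeric(1))
  }, numeric(length(mv$movie)))
  spread <- apply(traces, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-9)

  # single-exponential recovery: t_half = ln 2 / k1
  expect_equal(CondensateKit:::frapTrueHalfTime(
    c(a = 0.8, b = 0, k1 = log(2) / 2, k2 = 1)), 2, tolerance = 1e-8)

  expect_error(frapSpec(bleach_frame = 200, n_frames = 100), "bleach_frame")
  expect_error(frapSpec(bleach_roi = c(-5, 10, 1, 10)), "ROI")
})

test_that("force-extension generator records a faithful ground-truth area", {
  # no offset, nothing compacted: identical curves, zero area
  sp0 <- forceExtensionSpec(compacted_bp = 0, noise_sigma = 0)
  out0 <- genForceExtension(sp0)
  expect_equal(out0$truth$area, 0, tolerance = 1e-12)
  expect_equal(force(out0$bare), force(out0$hp1), tolerance = 1e-12)

  # constant offset over the whole grid: rectangle area
  grid <- seq(2, 10, by = 0.05)
  spc <- forceExtensionSpec(compacted_bp = 0, extension_grid = grid,
                            extra_force_offset = list(type = "constant",
                                                      amplitude = 1.5,
                                                      from = 0, to = 20))
  outc <- genForceExtension(spc)
  expect_equal(outc$truth$area, 1.5 * (max(grid) - min(grid)),
               tolerance = 1e-12)

  expect_error(forceExtensionSpec(extension_grid = seq(1, 17, by = 0.5)),
               "contour")
})
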