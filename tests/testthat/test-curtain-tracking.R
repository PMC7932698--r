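# Strand detection, kymogram extraction, end tracking, rate fitting.

test_that("findStrands locates strand columns and honours min separation", {
  fr <- genCurtainFrame(strand_cols = c(20L, 40L), noise_sigma = 0)
  expect_identical(findStrands(fr$frame), c(20L, 40L))

  fr2 <- genCurtainFrame(strand_cols = c(20L, 40L), noise_sigma = 3,
                         seed = 2)
  expect_identical(findStrands(fr2$frame), c(20L, 40L))

  # uniform background: nothing to find
  expect_identical(findStrands(matrix(100, 64, 64)), integer(0))
  expect_identical(findStrands(genCurtainFrame(noise_sigma = 2,
                                               seed = 1)$frame), integer(0))

  # strands 1 px apart merge into a single detection (min separation 3)
  fr3 <- genCurtainFrame(strand_cols = c(30L, 31L), noise_sigma = 0)
  expect_length(findStrands(fr3$frame), 1L)
})

test_that("extractKymogram averages the three columns around the strand", {
  movie <- lapply(1:5, function(i) matrix(7, 32, 16))
  kym <- extractKymogram(movie, 8)
  expect_true(all(intensity(kym) == 7))

  m <- matrix(0, 32, 16); m[, 7] <- 1; m[, 8] <- 2; m[, 9] <- 3
  kym2 <- extractKymogram(list(m, m), 8)
  expect_true(all(intensity(kym2) == 2))

  expect_error(extractKymogram(list(m), 1), "edge")
  expect_error(extractKymogram(list(m), 16), "edge")

  # a noiseless movie reproduces the generator's internal kymogram
  sp <- kymogramSpec(n_frames = 30, n_pixels = 64, end_start = 50,
                     noise_sigma = 0)
  mv <- genCurtainMovie(sp, strand_cols = 10L, n_cols = 24L)
  internal <- intensity(genKymogram(sp)$kymogram)
  expect_equal(intensity(extractKymogram(mv$movie, 10L)), internal,
               tolerance = 1e-12)
})

test_that("trackDnaEnd follows the true end within a pixel when noiseless", {
  sp <- kymogramSpec(n_frames = 100, n_pixels = 256, end_start = 200,
                     compaction_rate_v = 2, noise_sigma = 0)
  sim <- genKymogram(sp)
  track <- trackDnaEnd(sim$kymogram)
  ok <- qualityFlags(track) == "accepted"
  expect_gt(mean(ok), 0.9)
  expect_lte(max(abs(endPositions(track)[ok] - sim$truth$end_px[ok])), 1)
})

test_that("tracking flags degenerate inputs rather than failing silently", {
  # static end: constant track, no outliers
  sp <- kymogramSpec(n_frames = 50, n_pixels = 64, end_start = 40,
                     compaction_rate_v = 0, association_rate_kappa = 0,
                     noise_sigma = 0)
  track <- trackDnaEnd(genKymogram(sp)$kymogram)
  expect_equal(length(unique(endPositions(track))), 1L)
  expect_false(any(qualityFlags(track) == "outlier_rejected"))

  # pure noise: still returns a track with a reported accepted fraction
  noise <- Kymogram(matrix(rnorm(50 * 64, 100, 10), 50, 64))
  tn <- tryCatch(trackDnaEnd(noise), error = function(e) e)
  if (is(tn, "EndTrack")) {
    expect_true(all(qualityFlags(tn) %in%
                    c("accepted", "edge_excluded", "outlier_rejected")))
  } else {
    expect_match(conditionMessage(tn), "rejected")
  }

  # too short for the Savitzky-Golay window
  short <- Kymogram(matrix(rnorm(5 * 64, 100, 1), 5, 64))
  expect_error(trackDnaEnd(short), "Savitzky-Golay")
})

test_that("accepted positions never enter the edge margins", {
  for (s in 1:5) {
    sim <- genKymogram(kymogramSpec(noise_sigma = 10, seed = s))
    track <- trackDnaEnd(sim$kymogram)
    p <- endPositions(track)[qualityFlags(track) == "accepted"]
    expect_true(all(p >= track@edgeMargin &
                    p <= track@nPixels - track@edgeMargin))
  }
})

test_that("fitCompactionRate reproduces exact slopes and unit conversion", {
  # two points: slope -2 px/frame
  tr <- EndTrack(frame = 0:1, position = c(10, 8))
  fit <- fitCompactionRate(tr, frameInterval = 0.1, pixelSize = 0.16)
  expect_equal(compactionRate(fit), -2)
  expect_equal(compactionRate(fit, "um_per_s"), -2 * 0.16 / 0.1)

  # constant track: zero rate
  trc <- EndTrack(frame = 0:9, position = rep(30, 10))
  expect_equal(compactionRate(fitCompactionRate(trc)), 0)

  single <- EndTrack(frame = 0L, position = 10)
  expect_error(fitCompactionRate(single), "insufficient")
})

test_that("compaction rate is recovered and error shrinks as noise drops", {
  errAt <- function(noise, seeds) {
    vapply(seeds, function(s) {
      sim <- genKymogram(kymogramSpec(noise_sigma = noise, seed = s))
      fit <- fitCompactionRate(trackDnaEnd(sim$kymogram), sim$kymogram)
      abs(abs(compactionRate(fit)) - sim$truth$v) / sim$truth$v
    }, numeric(1))
  }
  # SNR 5 (dna_intensity 50, noise 10): 5% median recovery
  expect_lt(median(errAt(10, 1:8)), 0.05)
  # robustness ladder: recovery error must not grow as noise falls.
  # The bright compacted punctum keeps the error at a sub-percent
  # discretisation floor over this whole range, so the comparison allows
  # fluctuation within that floor (0.5%).
  ladder <- vapply(c(10, 2, 0), function(ns) median(errAt(ns, 1:5)),
                   numeric(1))
  expect_true(all(diff(ladder) <= 5e-3))
  expect_true(all(ladder < 5e-3))
})
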