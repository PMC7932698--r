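# Line FRAP normalization, biexponential fits, spatial photobleach model.

test_that("line-FRAP normalization cancels shared decay", {
  t <- seq(0, 30, by = 0.5)
  shared <- 100 * exp(-0.02 * t) + 10
  tr <- FrapTrace(time = t, iFrap = shared,
                  iUnbleached = cbind(shared, shared), iBackground = 10,
                  bleachFrame = 10L)
  expect_equal(unname(normalizeLineFrap(tr)), rep(1, length(t)),
               tolerance = 1e-12)

  # degenerate reference: unbleached equals background
  trBad <- FrapTrace(time = t, iFrap = shared,
                     iUnbleached = matrix(10, length(t), 1),
                     iBackground = 10, bleachFrame = 10L)
  expect_error(normalizeLineFrap(trBad), "degenerate")
  trNone <- FrapTrace(time = t, iFrap = shared,
                      iUnbleached = matrix(numeric(0), length(t), 0),
                      iBackground = 10, bleachFrame = 10L)
  expect_error(normalizeLineFrap(trNone), "unbleached")
})

test_that("line-FRAP on a movie with global photobleaching matches truth", {
  dp0 <- list(a_mean = 0.7, b_mean = 0.3, k1_0 = 0.02, alpha1 = 0,
              beta1 = 0, k2_0 = 0.002, alpha2 = 0, beta2 = 0)
  sp <- frapSpec(noise_sigma = 0.5, seed = 7, decay_params = dp0,
                 bleach_roi = c(70, 72, 1, 144))
  mv <- genFrapMovie(sp)
  tr <- extractFrapTraces(mv$movie, sp$bleach_roi, sp$bleach_frame,
                          frameInterval = sp$frame_interval,
                          excludeFactor = 0.3)
  norm <- normalizeLineFrap(tr)
  truthCurve <- CondensateKit:::frapRecoveryCurve(
    sp$recovery_params, pmax(tr@time - mv$truth$bleach_time, 0))
  truthCurve[seq_len(sp$bleach_frame)] <- 1
  expect_lt(sqrt(mean((norm - truthCurve)^2)), 0.02)

  fit <- fitBiexponential(norm, tr@time, bleachFrame = tr@bleachFrame)
  expect_true(fit@converged)
  expect_lt(abs(halfTime(fit) - mv$truth$t_half) / mv$truth$t_half, 0.05)
})

test_that("biexponential half-time matches the closed form on one exponential", {
  t <- seq(0, 20, by = 0.25)
  k <- log(2) / 2
  fit <- fitBiexponential(1 - 0.8 * exp(-k * t), t)
  expect_true(fit@converged)
  expect_equal(halfTime(fit), 2, tolerance = 1e-6)

  flat <- fitBiexponential(rep(1, 40), seq_len(40))
  expect_false(flat@converged)
  expect_true(is.na(halfTime(flat)))

  expect_error(fitBiexponential(1:5, 1:5), "8")
})

test_that("biexponential parameters are recovered at 1% noise", {
  truth <- c(a = 0.6, b = 0.3, k1 = 1.0, k2 = 0.1)
  thTrue <- CondensateKit:::frapTrueHalfTime(truth)
  t <- seq(0, 40, by = 0.2)
  res <- vapply(1:20, function(s) {
    y <- recoverySeries(t, 0.6, 0.3, 1.0, 0.1, noise = 0.01, seed = s)
    f <- fitBiexponential(y, t)
    c(abs(f@a - 0.6) / 0.6, abs(f@b - 0.3) / 0.3, abs(f@k1 - 1),
      abs(f@k2 - 0.1) / 0.1, abs(halfTime(f) - thTrue) / thTrue)
  }, numeric(5))
  med <- apply(res, 1, median)
  expect_true(all(med[1:4] < 0.10))
  expect_lt(med[5], 0.05)
})

test_that("spatial decay model reduces to the uniform model and validates input", {
  t <- seq(0, 150, by = 1)
  centroids <- cbind(x = c(10, 60, 110, 20, 80, 130, 40, 100),
                     y = c(15, 40, 20, 90, 120, 70, 130, 110))
  uniform <- vapply(1:8, function(i)
    0.7 * exp(-0.05 * t) + 0.3 * exp(-0.005 * t), numeric(length(t)))
  m <- fitSpatialDecay(uniform, time = t, centroids = centroids)
  expect_lt(abs(m@alpha1), 1e-6)
  expect_lt(abs(m@beta1), 1e-6)
  expect_equal(m@k10, 0.05, tolerance = 1e-4)
  expect_equal(m@k20, 0.005, tolerance = 1e-4)

  expect_error(fitSpatialDecay(uniform[, 1:2], time = t,
                               centroids = centroids[1:2, ]), "6")
  coll <- cbind(x = seq(10, 80, by = 10), y = seq(10, 80, by = 10))
  expect_error(fitSpatialDecay(uniform, time = t, centroids = coll),
               "collinear")
})

test_that("spatial gradients are recovered without bias", {
  dp <- frapSpec()$decay_params
  res <- vapply(1:50, function(s) {
    g <- genFrapTraces(frapSpec(noise_sigma = 1, seed = s))
    m <- fitSpatialDecay(g$trace)
    c((m@alpha1 - dp$alpha1) / dp$alpha1, (m@beta1 - dp$beta1) / dp$beta1,
      (m@alpha2 - dp$alpha2) / dp$alpha2, (m@beta2 - dp$beta2) / dp$beta2)
  }, numeric(4))
  expect_true(all(abs(rowMeans(res)) < 0.02))
})

test_that("whole-droplet correction flattens decay and recovers the plateau", {
  sp <- frapSpec(noise_sigma = 0.5, seed = 4)
  mv <- genFrapMovie(sp)
  tr <- extractFrapTraces(mv$movie, sp$bleach_roi, sp$bleach_frame,
                          frameInterval = sp$frame_interval,
                          excludeFactor = 0.6)
  model <- fitSpatialDecay(tr)
  corr <- correctWholeDropFrap(tr, model)
  pre <- seq_len(sp$bleach_frame)
  expect_equal(mean(corr$corrected[pre]), 1, tolerance = 0.01)
  expect_equal(mean(utils::tail(corr$corrected, 20)), 1, tolerance = 0.05)
  # unbleached droplets normalized by their own decay sit near 1
  expect_lt(max(abs(colMeans(corr$band) - 1)), 0.1)

  fit <- fitBiexponential(corr$corrected, tr@time,
                          bleachFrame = tr@bleachFrame)
  expect_lt(abs(halfTime(fit) - mv$truth$t_half) / mv$truth$t_half, 0.1)
})

test_that("zero-gradient spatial model equals global-decay normalization", {
  t <- seq(0, 100, by = 1)
  decay <- 0.7 * exp(-0.05 * t) + 0.3 * exp(-0.005 * t)
  model <- new("SpatialDecayModel", aMean = 0.7, bMean = 0.3, k10 = 0.05,
               k20 = 0.005, alpha1 = 0, beta1 = 0, alpha2 = 0, beta2 = 0,
               perDroplet = data.frame())
  tr <- FrapTrace(time = t, iFrap = 100 * decay, iUnbleached = 100 * decay,
                  iBackground = 0, bleachFrame = 10L,
                  centroids = cbind(x = 50, y = 50),
                  bleachCentroid = c(30, 40))
  corr <- correctWholeDropFrap(tr, model)
  pre <- 1:10
  global <- (decay / mean(decay[pre])) / (decay / mean(decay[pre]))
  expect_equal(corr$corrected, global, tolerance = 1e-9)
})

test_that("without true recovery the corrected trace has no trend", {
  dp <- frapSpec()$decay_params
  slopes <- vapply(1:20, function(s) {
    sp <- frapSpec(noise_sigma = 1, seed = s,
                   recovery_params = c(a = 0.5, b = 0.3, k1 = 1e-9,
                                       k2 = 1e-9))
    g <- genFrapTraces(sp)
    m <- fitSpatialDecay(g$trace)
    corr <- correctWholeDropFrap(g$trace, m)
    post <- (sp$bleach_frame + 1L):length(corr$corrected)
    unname(coef(lm(corr$corrected[post] ~ corr$time[post]))[2])
  }, numeric(1))
  # across seeds the post-bleach slope is indistinguishable from zero
  expect_gt(stats::t.test(slopes)$p.value, 0.05)
})
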