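#' Segment droplets in a FRAP frame by threshold
#'
#' Confocal FRAP droplets are bright on a dark background, so plain
#' thresholding (halfway between background and peak by default) is
#' sufficient. Masks are eroded to drop boundary pixels, whose intensity
#' fluctuates with droplet motion.
#'
#' @param frame 2-D numeric matrix (typically a pre-bleach frame)
#' @param threshold absolute threshold; NULL picks background + half the
#'   peak-to-background amplitude
#' @param erodePx erosion depth in pixels applied to each mask
#' @param minArea minimum droplet area after erosion, pixels
#' @return List with \code{labels} (integer matrix), \code{centroids}
#'   (n x 2, columns x = col, y = row) and \code{regions} (data.frame).
#' @export
segmentFrapDroplets <- function(frame, threshold = NULL, erodePx = 2L,
                                minArea = 9) {
  stopifnot(is.matrix(frame))
  if (is.null(threshold)) {
    bg <- stats::median(frame)
    threshold <- bg + 0.5 * (max(frame) - bg)
  }
  mask <- frame > threshold
  if (erodePx > 0)
    mask <- as.matrix(EBImage::erode(mask * 1,
      EBImage::makeBrush(2L * as.integer(erodePx) + 1L, "disc"))) > 0
  labels <- EBImage::bwlabel(mask * 1)
  props <- regionProperties(labels)
  keep <- which(props$area_px >= minArea)
  # relabel compactly in keep order
  out <- matrix(0L, nrow(frame), ncol(frame))
  for (i in seq_along(keep))
    out[labels == keep[i]] <- i
  props <- props[keep, , drop = FALSE]
  row.names(props) <- NULL
  list(labels = out,
       centroids = cbind(x = props$centroid_col, y = props$centroid_row),
       regions = props)
}

#' Extract FRAP traces from a movie
#'
#' Measures the per-frame mean intensity of the bleached ROI, of every
#' unbleached droplet and of the background (pixels off all droplets).
#' The droplet overlapping the bleach ROI is identified as bleached;
#' droplets within \code{excludeFactor} times the ROI diagonal of the ROI
#' centre are excluded from the unbleached set (they are affected by the
#' bleach strike).
#'
#' @param movie list of frame matrices
#' @param roi bleach ROI, c(row1, row2, col1, col2)
#' @param bleachFrame last pre-bleach frame index
#' @param frameInterval seconds per frame
#' @param segmentation optional result of \code{\link{segmentFrapDroplets}}
#'   on a pre-bleach frame; computed from frame 1 when NULL
#' @param excludeFactor exclusion radius around the bleach ROI as a
#'   multiple of the ROI diagonal
#' @param roiWithinDroplet when TRUE (default) the bleached-ROI mean is
#'   taken over ROI pixels inside the bleached droplet mask only
#' @return A \linkS4class{FrapTrace}.
#' @export
extractFrapTraces <- function(movie, roi, bleachFrame, frameInterval = 1,
                              segmentation = NULL, excludeFactor = 3,
                              roiWithinDroplet = TRUE) {
  stopifnot(is.list(movie), length(movie) > bleachFrame)
  if (is.null(segmentation))
    segmentation <- segmentFrapDroplets(movie[[1]])
  labels <- segmentation$labels
  cent <- segmentation$centroids
  nd <- nrow(cent)
  if (nd < 1) stop("no droplets found")
  roiMask <- matrix(FALSE, nrow(labels), ncol(labels))
  roiMask[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
  overlap <- vapply(seq_len(nd), function(i)
    sum(labels == i & roiMask), numeric(1))
  bleached <- which.max(overlap)
  if (overlap[bleached] == 0) stop("bleach ROI hits no droplet")
  roiCentre <- c((roi[3] + roi[4]) / 2, (roi[1] + roi[2]) / 2)  # (x, y)
  diagLen <- sqrt((roi[2] - roi[1])^2 + (roi[4] - roi[3])^2)
  distRoi <- sqrt((cent[, "x"] - roiCentre[1])^2 +
                  (cent[, "y"] - roiCentre[2])^2)
  unb <- setdiff(which(distRoi > excludeFactor * diagLen), bleached)
  frapMask <- if (roiWithinDroplet) roiMask & (labels == bleached)
              else roiMask
  bgMask <- labels == 0 & !roiMask
  nf <- length(movie)
  iFrap <- vapply(movie, function(f) mean(f[frapMask]), numeric(1))
  iBg <- vapply(movie, function(f) stats::median(f[bgMask]), numeric(1))
  iUnb <- if (length(unb))
    vapply(unb, function(i) {
      m <- labels == i
      vapply(movie, function(f) mean(f[m]), numeric(1))
    }, numeric(nf))
  else matrix(numeric(0), nf, 0)
  FrapTrace(time = (seq_len(nf) - 1) * frameInterval, iFrap = iFrap,
            iUnbleached = iUnb, iBackground = iBg,
            bleachFrame = bleachFrame,
            centroids = cent[unb, , drop = FALSE],
            bleachCentroid = c(cent[bleached, "x"], cent[bleached, "y"]))
}

#' Normalize a line-FRAP trace
#'
#' Background-subtracts the bleached-ROI trace and the unbleached droplet
#' traces, averages the unbleached traces, and returns
#' (I_FRAP(t) / I_FRAP(0)) / (I_unb(t) / I_unb(0)) with I(0) taken as the
#' mean over all pre-bleach frames. Division by the unbleached reference
#' cancels acquisition photobleaching.
#'
#' @param trace a \linkS4class{FrapTrace}
#' @param perDroplet when TRUE, returns a matrix normalized against each
#'   unbleached droplet separately instead of their average
#' @return Numeric normalized recovery series (or a matrix when
#'   \code{perDroplet}).
#' @export
normalizeLineFrap <- function(trace, perDroplet = FALSE) {
  stopifnot(is(trace, "FrapTrace"))
  if (ncol(trace@iUnbleached) == 0) stop("no unbleached droplets")
  pre <- seq_len(trace@bleachFrame)
  fr <- trace@iFrap - trace@iBackground
  un <- trace@iUnbleached - trace@iBackground
  fr0 <- mean(fr[pre])
  if (!is.finite(fr0) || fr0 <= 0) stop("zero pre-bleach ROI intensity")
  normOne <- function(u) {
    u0 <- mean(u[pre])
    if (!is.finite(u0) || abs(u0) <= 1e-9 * max(abs(u), 1))
      stop("degenerate unbleached reference")
    (fr / fr0) / (u / u0)
  }
  if (perDroplet) return(apply(un, 2, normOne))
  u <- rowMeans(un)
  normOne(u)
}

# two-segment log-linear initial guesses for biexponential rates applied
# to a decaying positive series y over times t
biexpInit <- function(t, y) {
  y <- pmax(y, 1e-12 * max(y))
  n <- length(t)
  cut <- max(2L, floor(n / 3))
  early <- seq_len(cut)
  late <- seq(max(cut + 1L, n - floor(n / 2)), n)
  kFast <- -stats::coef(stats::lm(log(y[early]) ~ t[early]))[2]
  kSlow <- -stats::coef(stats::lm(log(y[late]) ~ t[late]))[2]
  kFast <- max(kFast, 1e-3, na.rm = TRUE)
  kSlow <- max(min(kSlow, kFast / 2, na.rm = TRUE), 1e-4)
  c(k1 = unname(kFast), k2 = unname(kSlow))
}

#' Fit a biexponential recovery and extract the half-time
#'
#' Fits y(t) = plateau - a exp(-k1 t) - b exp(-k2 t) to the post-bleach
#' part of a normalized recovery series by nonlinear least squares
#' (Levenberg-Marquardt), with a, b >= 0 and k bounded in (1e-4, 1e3)/s.
#' The recovery half-time is the time at which the fitted curve crosses
#' halfway between its post-bleach floor and the fitted plateau, solved
#' numerically from the fit.
#'
#' @param series normalized recovery values
#' @param time times, seconds; same length as \code{series}. Time zero is
#'   taken at the first post-bleach point internally.
#' @param bleachFrame when given, only points after this index are fit
#'   (pass the full series); otherwise the series is assumed post-bleach
#' @return A \linkS4class{BiExpFit} (recovery form). On non-convergence
#'   the flag is set and tHalf is NA.
#' @export
fitBiexponential <- function(series, time, bleachFrame = NULL) {
  if (!is.null(bleachFrame)) {
    post <- (bleachFrame + 1L):length(series)
    series <- series[post]; time <- time[post]
  }
  ok <- is.finite(series) & is.finite(time)
  series <- series[ok]; time <- time[ok]
  if (length(series) < 8L) stop("need at least 8 post-bleach points")
  tau <- time - time[1]
  failed <- function() new("BiExpFit", a = NA_real_, b = NA_real_,
                           k1 = NA_real_, k2 = NA_real_,
                           plateau = NA_real_, tHalf = NA_real_,
                           residualSd = NA_real_, converged = FALSE,
                           form = "recovery")
  plateau0 <- mean(utils::tail(series, max(3L, length(series) %/% 5)))
  depth0 <- plateau0 - series[1]
  if (!is.finite(depth0) || depth0 <= 1e-6 * max(abs(series), 1) ||
      stats::sd(series) < 1e-12)
    return(failed())
  ks <- biexpInit(tau, pmax(plateau0 - series, 1e-9))
  df <- data.frame(tau = tau, y = series)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ p - a * exp(-k1 * tau) - b * exp(-k2 * tau), data = df,
    start = list(p = plateau0, a = depth0 / 2, b = depth0 / 2,
                 k1 = ks[["k1"]], k2 = ks[["k2"]]),
    lower = c(p = -Inf, a = 0, b = 0, k1 = 1e-4, k2 = 1e-4),
    upper = c(p = Inf, a = Inf, b = Inf, k1 = 1e3, k2 = 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  co <- stats::coef(fit)
  # order components so k1 is the fast rate
  if (co[["k2"]] > co[["k1"]])
    co[c("a", "b", "k1", "k2")] <- co[c("b", "a", "k2", "k1")]
  floorv <- co[["p"]] - co[["a"]] - co[["b"]]
  target <- floorv + (co[["p"]] - floorv) / 2
  curve <- function(x) co[["p"]] - co[["a"]] * exp(-co[["k1"]] * x) -
    co[["b"]] * exp(-co[["k2"]] * x)
  tHalf <- tryCatch({
    upper <- 20 / min(co[["k1"]], co[["k2"]])
    stats::uniroot(function(x) curve(x) - target, c(0, upper),
                   tol = 1e-10)$root
  }, error = function(e) NA_real_)
  new("BiExpFit", a = co[["a"]], b = co[["b"]], k1 = co[["k1"]],
      k2 = co[["k2"]], plateau = co[["p"]], tHalf = tHalf,
      residualSd = stats::sd(stats::residuals(fit)),
      converged = TRUE, form = "recovery")
}

#' Fit a biexponential decay
#'
#' Fits y(t) = a exp(-k1 t) + b exp(-k2 t) to a photobleaching decay
#' trace (typically normalized to its initial value).
#'
#' @param series decay values
#' @param time times, seconds
#' @return A \linkS4class{BiExpFit} (decay form; plateau and tHalf NA).
#' @export
fitBiexpDecay <- function(series, time) {
  ok <- is.finite(series) & is.finite(time)
  series <- series[ok]; time <- time[ok]
  if (length(series) < 8L) stop("need at least 8 points")
  tau <- time - time[1]
  ks <- biexpInit(tau, pmax(series, 1e-9))
  y0 <- series[1]
  df <- data.frame(tau = tau, y = series)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ a * exp(-k1 * tau) + b * exp(-k2 * tau), data = df,
    start = list(a = 0.6 * y0, b = 0.4 * y0, k1 = ks[["k1"]],
                 k2 = ks[["k2"]]),
    lower = c(a = 0, b = 0, k1 = 1e-4, k2 = 1e-4),
    upper = c(a = Inf, b = Inf, k1 = 1e3, k2 = 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("BiExpFit", a = NA_real_, b = NA_real_, k1 = NA_real_,
               k2 = NA_real_, plateau = NA_real_, tHalf = NA_real_,
               residualSd = NA_real_, converged = FALSE, form = "decay"))
  co <- stats::coef(fit)
  if (co[["k2"]] > co[["k1"]])
    co[c("a", "b", "k1", "k2")] <- co[c("b", "a", "k2", "k1")]
  new("BiExpFit", a = co[["a"]], b = co[["b"]], k1 = co[["k1"]],
      k2 = co[["k2"]], plateau = NA_real_, tHalf = NA_real_,
      residualSd = stats::sd(stats::residuals(fit)), converged = TRUE,
      form = "decay")
}

#' Fit the spatially varying photobleach decay model
#'
#' Fits a biexponential decay to each unbleached droplet trace
#' (background-subtracted, normalized to its pre-bleach mean), then
#' linearly regresses each rate constant on the droplet centroid:
#' k1(x, y) = k1_0 + x alpha1 + y beta1, and likewise k2. Amplitudes are
#' averaged across droplets.
#'
#' @param trace a \linkS4class{FrapTrace} carrying unbleached traces and
#'   centroids, or a plain matrix of traces (frames x droplets)
#' @param time times, seconds (ignored when \code{trace} is a FrapTrace)
#' @param centroids n x 2 matrix (x, y) (ignored for a FrapTrace)
#' @param background scalar or per-frame background (matrix input only)
#' @return A \linkS4class{SpatialDecayModel}.
#' @export
fitSpatialDecay <- function(trace, time = NULL, centroids = NULL,
                            background = 0) {
  if (is(trace, "FrapTrace")) {
    time <- trace@time
    centroids <- trace@centroids
    mat <- trace@iUnbleached - trace@iBackground
  } else {
    mat <- trace - background
  }
  nd <- ncol(mat)
  if (nd < 6L) stop("need at least 6 unbleached droplets")
  x <- centroids[, 1]; y <- centroids[, 2]
  if (qr(cbind(1, x, y))$rank < 3L)
    stop("collinear droplet centroids: spatial regression is rank-deficient")
  per <- lapply(seq_len(nd), function(i) {
    tr <- mat[, i] / mat[1, i]
    fitBiexpDecay(tr, time)
  })
  conv <- vapply(per, function(f) f@converged, logical(1))
  if (sum(conv) < 6L) stop("too few converged droplet decay fits")
  pd <- data.frame(
    x = x[conv], y = y[conv],
    a = vapply(per[conv], function(f) f@a, numeric(1)),
    b = vapply(per[conv], function(f) f@b, numeric(1)),
    k1 = vapply(per[conv], function(f) f@k1, numeric(1)),
    k2 = vapply(per[conv], function(f) f@k2, numeric(1)))
  f1 <- stats::lm(k1 ~ x + y, data = pd)
  f2 <- stats::lm(k2 ~ x + y, data = pd)
  c1 <- stats::coef(f1); c2 <- stats::coef(f2)
  new("SpatialDecayModel", aMean = mean(pd$a), bMean = mean(pd$b),
      k10 = unname(c1[1]), k20 = unname(c2[1]),
      alpha1 = unname(c1["x"]), beta1 = unname(c1["y"]),
      alpha2 = unname(c2["x"]), beta2 = unname(c2["y"]),
      perDroplet = pd)
}

#' Photobleach-corrected whole-droplet FRAP recovery
#'
#' Divides the bleached droplet's background-subtracted, pre-bleach
#' normalized trace by the model decay
#' ybar(t) = <a> exp(-k1(x, y) t) + <b> exp(-k2(x, y) t) evaluated at the
#' bleached droplet's centroid. The unbleached traces are normalized the
#' same way (each at its own centroid) and returned as the expected
#' spread of the data.
#'
#' @param trace a \linkS4class{FrapTrace}
#' @param model a fitted \linkS4class{SpatialDecayModel}
#' @return List with \code{time}, \code{corrected} (bleached series),
#'   \code{band} (matrix of normalized unbleached traces) and
#'   \code{ybar}.
#' @export
correctWholeDropFrap <- function(trace, model) {
  stopifnot(is(trace, "FrapTrace"), is(model, "SpatialDecayModel"))
  t <- trace@time
  pre <- seq_len(trace@bleachFrame)
  ybarAt <- function(x, y) {
    k <- decayRateAt(model, x, y)
    model@aMean * exp(-k$k1 * t) + model@bMean * exp(-k$k2 * t)
  }
  yb <- ybarAt(trace@bleachCentroid[1], trace@bleachCentroid[2])
  if (any(yb <= 0)) stop("model decay non-positive over the trace")
  # reference the model decay to the same pre-bleach window as I(0), so
  # the pre-bleach corrected trace sits at 1
  yb <- yb / mean(yb[pre])
  fr <- trace@iFrap - trace@iBackground
  corrected <- (fr / mean(fr[pre])) / yb
  band <- if (ncol(trace@iUnbleached)) {
    vapply(seq_len(ncol(trace@iUnbleached)), function(i) {
      u <- trace@iUnbleached[, i] - trace@iBackground
      ybi <- ybarAt(trace@centroids[i, 1], trace@centroids[i, 2])
      ybi <- ybi / mean(ybi[pre])
      (u / mean(u[pre])) / ybi
    }, numeric(length(t)))
  } else matrix(numeric(0), length(t), 0)
  list(time = t, corrected = corrected, band = band, ybar = yb)
}
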