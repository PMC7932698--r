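#' High-pass filter an image in Fourier space
#'
#' Removes low-frequency content (slow illumination gradients and the DC
#' level) before edge detection. Frequencies below \code{cutoff_frac} of
#' Nyquist are attenuated with a Gaussian rolloff (or zeroed when
#' \code{rolloff = "hard"}); the DC component is always removed, so the
#' output has (numerically) zero mean.
#'
#' @param image 2-D numeric matrix
#' @param cutoff_frac cutoff as a fraction of the Nyquist frequency,
#'   in (0, 1)
#' @param rolloff "gaussian" (smooth attenuation) or "hard"
#' @return Filtered real image of the same shape.
#' @export
highpassFourier <- function(image, cutoff_frac = 0.02,
                            rolloff = c("gaussian", "hard")) {
  stopifnot(is.matrix(image))
  rolloff <- match.arg(rolloff)
  if (cutoff_frac <= 0 || cutoff_frac >= 1)
    stop("cutoff_frac must lie in (0, 1)")
  nr <- nrow(image); nc <- ncol(image)
  # reflect (without duplicating the border samples) to make the image
  # periodic; avoids wrap-around ringing at the borders
  ri <- c(seq_len(nr), if (nr > 2) (nr - 1):2)
  ci <- c(seq_len(nc), if (nc > 2) (nc - 1):2)
  padded <- image[ri, ci]
  pr <- nrow(padded); pc <- ncol(padded)
  fr <- fftFreq(pr); fc <- fftFreq(pc)
  f <- sqrt(outer(fr^2, fc^2, "+"))  # cycles per pixel
  fcut <- cutoff_frac * 0.5
  H <- if (rolloff == "gaussian") 1 - exp(-f^2 / (2 * fcut^2))
       else (f >= fcut) * 1
  H[1, 1] <- 0
  out <- Re(stats::fft(stats::fft(padded) * H, inverse = TRUE)) / (pr * pc)
  out[seq_len(nr), seq_len(nc)]
}

fftFreq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}

#' Multi-scale Canny segmentation of condensates
#'
#' Runs Canny edge detection at several smoothing scales, closes and
#' fills each edge map into candidate regions, and unions the results:
#' large condensates are picked up at large sigma, small ones at small
#' sigma. Returns labelled connected components.
#'
#' @param image 2-D numeric matrix (typically high-pass filtered first)
#' @param sigmas vector of Canny smoothing sigmas, pixels
#' @param low,high,thresholdMode passed to \code{\link{cannyEdges}}
#' @param closeSize size of the box brush used to close edge chains
#'   before hole filling
#' @param erodeFinal erosion depth (pixels) applied to the combined mask,
#'   trimming the halo left by weak outer edges and closing; also
#'   re-separates marginally bridged neighbours
#' @return Integer matrix of labelled regions (0 = background).
#' @export
multiscaleCanny <- function(image, sigmas = c(1, 2, 4, 8), low = 0.08,
                            high = 0.2,
                            thresholdMode = c("auto", "relative",
                                              "quantile", "absolute"),
                            closeSize = 3L, erodeFinal = 2L) {
  thresholdMode <- match.arg(thresholdMode)
  if (!length(sigmas)) stop("at least one sigma required")
  brush <- EBImage::makeBrush(closeSize, "box")
  combined <- matrix(FALSE, nrow(image), ncol(image))
  # finest scale first: a droplet already segmented at a small sigma keeps
  # that footprint; coarser scales only contribute where nothing was
  # detected yet (their blurred edges would otherwise inflate the regions)
  for (s in sort(unique(sigmas))) {
    e <- cannyEdges(image, sigma = s, low = low, high = high,
                    thresholdMode = thresholdMode)
    if (!any(e)) next
    closed <- EBImage::closing(e * 1, brush)
    filled <- as.matrix(EBImage::fillHull(closed)) > 0
    lab <- EBImage::bwlabel(filled * 1)
    hit <- unique(lab[combined & lab > 0])
    fresh <- filled & !matrix(lab %in% hit, nrow(lab), ncol(lab))
    combined <- combined | fresh
  }
  if (erodeFinal > 0 && any(combined))
    combined <- as.matrix(EBImage::erode(combined * 1,
      EBImage::makeBrush(2L * as.integer(erodeFinal) + 1L, "box"))) > 0
  m <- EBImage::bwlabel(combined * 1)
  matrix(as.integer(m), nrow(image), ncol(image))
}

#' Region properties of labelled condensates
#'
#' Computes centroid, area, equivalent radius (sqrt(area/pi)),
#' eccentricity (from second central moments) and perimeter for every
#' labelled region.
#'
#' @param labels integer label matrix from \code{\link{multiscaleCanny}}
#' @param pixelSize micrometres per pixel for the radius conversion
#' @return data.frame with one row per region.
#' @export
regionProperties <- function(labels, pixelSize = 1) {
  if (max(labels) == 0)
    return(data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      area_px = numeric(0), radius_px = numeric(0),
                      radius_um = numeric(0), eccentricity = numeric(0),
                      perimeter_px = numeric(0)))
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1,
                                       dimnames = list(NULL, names(shp)))
  area <- shp[, "s.area"]
  # EBImage indexes images [x, y]; with a plain matrix x is the row index
  data.frame(centroid_row = mom[, "m.cx"], centroid_col = mom[, "m.cy"],
             area_px = area, radius_px = sqrt(area / pi),
             radius_um = sqrt(area / pi) * pixelSize,
             eccentricity = mom[, "m.eccentricity"],
             perimeter_px = shp[, "s.perimeter"], row.names = NULL)
}

#' Filter candidate regions on area and eccentricity
#'
#' Retains regions strictly larger than \code{areaMin} pixels with
#' eccentricity at or below \code{eccMax}; everything else is treated as
#' segmentation noise. The filter is pure (output is a subset of input)
#' and idempotent.
#'
#' @param regions data.frame from \code{\link{regionProperties}}, or a
#'   \linkS4class{DropletSet}
#' @param areaMin minimum area, pixels (strict inequality)
#' @param eccMax maximum eccentricity (inclusive)
#' @param imageId,condition,pixelSize metadata for the returned set
#' @return A \linkS4class{DropletSet}.
#' @export
filterRegions <- function(regions, areaMin = 3, eccMax = 0.94,
                          imageId = "image", condition = list(),
                          pixelSize = NULL) {
  if (is(regions, "DropletSet")) {
    if (is.null(pixelSize)) pixelSize <- regions@pixelSize
    imageId <- regions@imageId
    condition <- regions@condition
    regions <- regions@regions
  }
  if (is.null(pixelSize)) pixelSize <- 1
  keep <- if (nrow(regions)) regions$area_px > areaMin &
    regions$eccentricity <= eccMax else logical(0)
  DropletSet(regions[keep, , drop = FALSE], imageId = imageId,
             condition = condition, pixelSize = pixelSize)
}

#' Segment condensates in a brightfield image
#'
#' Full segmentation chain: Fourier high-pass, multi-scale Canny with
#' closing and hole filling, region properties, and the area and
#' eccentricity filters.
#'
#' @param image 2-D numeric matrix
#' @param pixelSize micrometres per pixel
#' @param sigmas,low,high,thresholdMode,closeSize,erodeFinal see
#'   \code{\link{multiscaleCanny}}
#' @param cutoff_frac see \code{\link{highpassFourier}}
#' @param areaMin,eccMax see \code{\link{filterRegions}}
#' @param imageId,condition metadata
#' @return A \linkS4class{DropletSet}.
#' @export
segmentDroplets <- function(image, pixelSize = 1, sigmas = c(1, 2, 4, 8),
                            low = 0.08, high = 0.2,
                            thresholdMode = "auto", closeSize = 3L,
                            erodeFinal = 2L, cutoff_frac = 0.02,
                            areaMin = 3, eccMax = 0.94,
                            imageId = "image", condition = list()) {
  hp <- highpassFourier(image, cutoff_frac = cutoff_frac)
  labels <- multiscaleCanny(hp, sigmas = sigmas, low = low, high = high,
                            thresholdMode = thresholdMode,
                            closeSize = closeSize, erodeFinal = erodeFinal)
  filterRegions(regionProperties(labels, pixelSize), areaMin = areaMin,
                eccMax = eccMax, imageId = imageId, condition = condition,
                pixelSize = pixelSize)
}

#' Complementary cumulative distribution of condensate radii
#'
#' CCD(r) = fraction of condensates with radius >= r, evaluated on the
#' observed support (plus r = 0 where the CCD is 1), with percentile
#' bootstrap confidence bands and the expectation value of the radius
#' obtained by integrating the CCD over the observed support (which, for
#' the empirical CCD, equals the sample mean).
#'
#' @param droplets a \linkS4class{DropletSet}, or a numeric vector of
#'   radii (pooled over images of one condition)
#' @param nBoot number of bootstrap resamples
#' @param ciLevel confidence level of the percentile interval
#' @param seed optional seed for the bootstrap
#' @return A \linkS4class{RadiusDistribution}.
#' @export
radiusCcd <- function(droplets, nBoot = 1000L, ciLevel = 0.95,
                      seed = NULL) {
  r <- if (is(droplets, "DropletSet")) radii(droplets) else
    as.numeric(droplets)
  if (!length(r)) stop("empty droplet set")
  if (any(r < 0)) stop("radii must be non-negative")
  grid <- c(0, sort(unique(r)))
  # fraction of x at or above each grid value, via a sorted strict count
  ccdAt <- function(x, at) {
    xs <- sort(x)
    1 - findInterval(at, xs, left.open = TRUE) / length(xs)
  }
  ccd <- ccdAt(r, grid)
  expect <- ccdIntegral(r)
  doBoot <- function() {
    bs <- matrix(0, nBoot, length(grid))
    be <- numeric(nBoot)
    for (i in seq_len(nBoot)) {
      xi <- sample(r, replace = TRUE)
      bs[i, ] <- ccdAt(xi, grid)
      be[i] <- mean(xi)
    }
    a <- (1 - ciLevel) / 2
    list(lo = apply(bs, 2, stats::quantile, probs = a),
         hi = apply(bs, 2, stats::quantile, probs = 1 - a),
         eci = stats::quantile(be, c(a, 1 - a), names = FALSE))
  }
  b <- if (is.null(seed)) doBoot() else withSeed(seed, doBoot())
  new("RadiusDistribution", radii = r, grid = grid, ccd = ccd,
      ciLo = unname(b$lo), ciHi = unname(b$hi), expectedRadius = expect,
      expectedRadiusCi = b$eci, nBoot = as.integer(nBoot),
      ciLevel = ciLevel)
}

#' Power-law fit of radius versus concentration
#'
#' Fits r = A c^b by ordinary least squares on log r versus log c.
#'
#' @param concentration positive concentrations (one per condition)
#' @param radius positive expected radii
#' @param sem optional standard errors (carried through, not used as
#'   weights)
#' @return A \linkS4class{PowerLawFit}.
#' @examples
#' f <- fitPowerLaw(c(1, 4, 16), 2 * c(1, 4, 16)^0.5)
#' f@exponent
#' @export
fitPowerLaw <- function(concentration, radius, sem = NULL) {
  if (length(concentration) != length(radius))
    stop("concentration and radius must match")
  if (length(concentration) < 3L) stop("need at least 3 conditions")
  if (any(concentration <= 0) || any(radius <= 0))
    stop("concentrations and radii must be positive")
  fit <- stats::lm(log(radius) ~ log(concentration))
  # suppressed: summary.lm warns on exactly power-law input
  co <- suppressWarnings(summary(fit))$coefficients
  new("PowerLawFit", amplitude = exp(co[1, 1]), exponent = co[2, 1],
      amplitudeSe = exp(co[1, 1]) * co[1, 2], exponentSe = co[2, 2],
      n = length(concentration))
}

#' Match detected droplets to ground truth
#'
#' Greedy one-to-one matching of detected to true droplets: a detection
#' matches a truth entry when their centroids are within
#' \code{maxDistFactor} times the true radius. Used to score segmentation
#' recall and precision on synthetic fields.
#'
#' @param truthCenters n x 2 matrix of true (row, col) centres
#' @param truthRadii true radii, pixels
#' @param detected a \linkS4class{DropletSet}
#' @param maxDistFactor match radius as a multiple of the true radius
#' @return List with \code{recall}, \code{precision}, \code{nMatched},
#'   \code{matches} (data.frame truth_index, detected_index).
#' @export
matchDroplets <- function(truthCenters, truthRadii, detected,
                          maxDistFactor = 1) {
  reg <- dropletRegions(detected)
  nT <- nrow(truthCenters); nD <- nrow(reg)
  if (nT == 0)
    return(list(recall = NA_real_, precision = if (nD) 0 else NA_real_,
                nMatched = 0L, matches = data.frame()))
  if (nD == 0)
    return(list(recall = 0, precision = NA_real_, nMatched = 0L,
                matches = data.frame()))
  d <- sqrt(outer(truthCenters[, 1], reg$centroid_row, "-")^2 +
            outer(truthCenters[, 2], reg$centroid_col, "-")^2)
  usedD <- logical(nD)
  matches <- data.frame(truth_index = integer(0), detected_index = integer(0))
  for (i in order(truthRadii, decreasing = TRUE)) {
    cand <- which(!usedD & d[i, ] <= maxDistFactor * truthRadii[i])
    if (length(cand)) {
      j <- cand[which.min(d[i, cand])]
      usedD[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(truth_index = i, detected_index = j))
    }
  }
  list(recall = nrow(matches) / nT, precision = nrow(matches) / nD,
       nMatched = nrow(matches), matches = matches)
}
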