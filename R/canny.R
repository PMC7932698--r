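#' Canny edge detection
#'
#' Classic Canny detector: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (weak edge chains are kept only when they
#' contain a strong pixel). Thresholds can be given relative to the
#' maximum gradient magnitude (default), as quantiles of the non-zero
#' magnitudes, or as absolute values.
#'
#' @param image 2-D numeric matrix
#' @param sigma Gaussian smoothing sigma, pixels
#' @param low,high thresholds; interpretation set by \code{thresholdMode}
#' @param thresholdMode "auto" (fractions of the max gradient, floored
#'   at a robust noise level estimated as median + 6 MAD of the gradient
#'   magnitude), "relative" (plain fractions of max gradient), "quantile"
#'   (quantiles of positive magnitudes) or "absolute"
#' @return Logical matrix of edge pixels.
#' @export
cannyEdges <- function(image, sigma = 1, low = 0.08, high = 0.2,
                       thresholdMode = c("auto", "relative", "quantile",
                                         "absolute")) {
  stopifnot(is.matrix(image))
  thresholdMode <- match.arg(thresholdMode)
  if (low > high) stop("low threshold above high threshold")
  sm <- if (sigma > 0) EBImage::gblur(image, sigma = sigma) else image
  sobel <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(sm, t(sobel))       # gradient along rows (dim 1)
  gy <- EBImage::filter2(sm, sobel)          # gradient along cols (dim 2)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax <= .Machine$double.eps)
    return(matrix(FALSE, nrow(image), ncol(image)))
  ang <- atan2(gy, gx)  # direction of steepest change, radians
  # quantize to 4 directions and suppress non-maxima along each
  bin <- (round(ang / (pi / 4)) %% 4) + 1  # 1: row dir, 2: diag, 3: col, 4: anti-diag
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (b in 1:4) {
    o <- offs[[b]]
    fwd <- shiftMatrix(mag, -o[1], -o[2])
    bck <- shiftMatrix(mag, o[1], o[2])
    nms <- nms | (bin == b & mag >= fwd & mag >= bck)
  }
  thr <- switch(thresholdMode,
    auto = {
      noiseFloor <- stats::median(mag) + 6 * stats::mad(mag)
      c(max(low * mmax, 0.5 * noiseFloor), max(high * mmax, noiseFloor))
    },
    relative = c(low, high) * mmax,
    quantile = stats::quantile(mag[mag > 1e-12 * mmax], c(low, high),
                               names = FALSE),
    absolute = c(low, high))
  weak <- nms & mag >= thr[1]
  strong <- nms & mag >= thr[2]
  if (!any(strong)) return(matrix(FALSE, nrow(image), ncol(image)))
  # hysteresis: keep weak chains that contain at least one strong pixel;
  # dilate the weak mask so 8-connected chains survive 4-connected labeling
  lab <- EBImage::bwlabel(EBImage::dilate(weak * 1,
                                          EBImage::makeBrush(3, "box")))
  keepLabels <- unique(lab[strong])
  keepLabels <- keepLabels[keepLabels > 0]
  out <- weak & matrix(lab %in% keepLabels, nrow(lab), ncol(lab))
  out
}
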