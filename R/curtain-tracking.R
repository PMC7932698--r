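#' Tracking parameters
#'
#' Defaults for kymogram end tracking. The smoothing sigma, the
#' Savitzky-Golay window/order and the outlier cutoff are tunable because
#' reasonable values depend on magnification and frame rate.
#'
#' @param smooth_sigma Gaussian smoothing sigma along the position axis,
#'   pixels
#' @param smooth_sigma_t optional smoothing sigma along the time axis,
#'   frames (0 disables; end motion between frames blurs the edge when
#'   this is large)
#' @param edge_margin pixels excluded at either border of the kymogram
#' @param savgol_window Savitzky-Golay window, frames (odd)
#' @param savgol_order Savitzky-Golay polynomial order
#' @param outlier_px positions further than this from the smoothed
#'   trajectory are rejected
#' @return A list of class \code{"trackingParams"}.
#' @export
trackingParams <- function(smooth_sigma = 1, smooth_sigma_t = 0,
                           edge_margin = 3L, savgol_window = 11L,
                           savgol_order = 2L, outlier_px = 3) {
  if (savgol_window %% 2L == 0L) stop("savgol_window must be odd")
  if (savgol_order >= savgol_window)
    stop("savgol_order must be below savgol_window")
  structure(list(smooth_sigma = smooth_sigma, smooth_sigma_t = smooth_sigma_t,
                 edge_margin = as.integer(edge_margin),
                 savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order),
                 outlier_px = outlier_px),
            class = "trackingParams")
}

#' Locate DNA strands in a curtain frame
#'
#' Finds columns that behave like vertical DNA strands: a contiguous run
#' of bright pixels covering at least \code{min_length_frac} of the image
#' height, peaking at a local maximum of the column-mean profile.
#' Detections closer than \code{min_separation} pixels are merged (the
#' brighter column wins), so each strand yields one 3-px-wide ROI.
#'
#' @param frame image matrix (rows = position along DNA, cols = lateral)
#' @param min_length_frac minimum fraction of rows a strand must span
#' @param min_separation minimum distance between strand centres, pixels
#' @param min_contrast minimum intensity above background (in units of the
#'   background noise MAD, floored at \code{abs_contrast}) for a column to
#'   count as strand-bearing
#' @param abs_contrast absolute floor on the required contrast
#' @return Integer vector of strand column indices (empty when nothing is
#'   detected).
#' @export
findStrands <- function(frame, min_length_frac = 0.5, min_separation = 3L,
                        min_contrast = 4, abs_contrast = 1e-8) {
  stopifnot(is.matrix(frame))
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  amp <- max(frame) - bg
  thr <- bg + max(min_contrast * noise, abs_contrast, 0.3 * amp)
  if (amp <= max(min_contrast * noise, abs_contrast)) return(integer(0))
  colfrac <- colMeans(frame > thr)
  profile <- colMeans(frame)
  candidates <- which(colfrac >= min_length_frac)
  if (!length(candidates)) return(integer(0))
  # local maxima of the profile among candidate columns
  nc <- ncol(frame)
  isMax <- vapply(candidates, function(j) {
    lo <- max(1L, j - 1L); hi <- min(nc, j + 1L)
    profile[j] >= max(profile[lo:hi])
  }, logical(1))
  peaks <- candidates[isMax]
  if (!length(peaks)) return(integer(0))
  # greedy min-separation merge, brightest first
  peaks <- peaks[order(profile[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in peaks)
    if (!length(kept) || all(abs(kept - p) >= min_separation))
      kept <- c(kept, p)
  # refine each peak to the intensity-weighted centre of its local
  # neighbourhood; noise can otherwise pick either side of a flat-topped
  # 3-px strand profile
  kept <- vapply(kept, function(p) {
    j <- max(2L, p - 2L):min(nc - 1L, p + 2L)
    w <- pmax(profile[j] - bg, 0)
    if (sum(w) <= 0) p else as.integer(round(sum(j * w) / sum(w)))
  }, integer(1))
  sort(unique(kept))
}

#' Extract the kymogram of one strand from a movie
#'
#' Per frame, averages the three pixel columns centred on the strand and
#' stacks the averaged slices over frames.
#'
#' @param movie list of image matrices (rows = position, cols = lateral),
#'   or a 3-D array with frames along the third dimension
#' @param strand_column centre column of the strand (must be at least
#'   2 px from the lateral edges)
#' @param frameInterval,pixelSize acquisition metadata for the result
#' @return A \linkS4class{Kymogram} (frames x positions).
#' @export
extractKymogram <- function(movie, strand_column, frameInterval = 1,
                            pixelSize = 0.16) {
  if (is.array(movie) && length(dim(movie)) == 3L)
    movie <- lapply(seq_len(dim(movie)[3]), function(i) movie[, , i])
  stopifnot(is.list(movie), length(movie) >= 1L)
  nc <- ncol(movie[[1]])
  if (strand_column < 2 || strand_column > nc - 1)
    stop("strand within 1 px of image edge")
  cols <- (strand_column - 1L):(strand_column + 1L)
  prof <- t(vapply(movie, function(f) rowMeans(f[, cols, drop = FALSE]),
                   numeric(nrow(movie[[1]]))))
  Kymogram(prof, frameInterval = frameInterval, pixelSize = pixelSize,
           strandId = sprintf("col%d", strand_column))
}

#' Track the free DNA end through a kymogram
#'
#' Per frame: Gaussian-smooth the kymogram, take the first difference
#' along the position axis (oriented tether-to-free-end, so the
#' DNA-to-background transition is the minimum), and take the argmin
#' within the edge-exclusion window. A Savitzky-Golay curve is then fit
#' through the raw positions and frames deviating by more than
#' \code{outlier_px} are flagged \code{outlier_rejected}; frames whose
#' detection pinned to the exclusion window boundary are flagged
#' \code{edge_excluded}. Flagged frames are excluded downstream, never
#' interpolated.
#'
#' @param kymogram a \linkS4class{Kymogram}
#' @param params a \code{\link{trackingParams}} list
#' @return An \linkS4class{EndTrack}.
#' @export
trackDnaEnd <- function(kymogram, params = trackingParams()) {
  stopifnot(is(kymogram, "Kymogram"))
  m <- intensity(kymogram)
  nf <- nrow(m); np <- ncol(m)
  if (nf < params$savgol_window)
    stop("kymogram shorter than the Savitzky-Golay window")
  sm <- gaussianSmooth1D(m, params$smooth_sigma, "position")
  if (params$smooth_sigma_t > 0)
    sm <- gaussianSmooth1D(sm, params$smooth_sigma_t, "time")
  d <- sm[, -1L, drop = FALSE] - sm[, -np, drop = FALSE]
  em <- params$edge_margin
  lo <- max(1L, em)
  hi <- min(np - 1L, np - em)
  if (hi <= lo) stop("edge margins leave no search window")
  win <- d[, lo:hi, drop = FALSE]
  raw <- max.col(-win, ties.method = "first") + lo - 1L
  flag <- rep("accepted", nf)
  flag[raw <= lo | raw >= hi] <- "edge_excluded"
  smoothed <- signal::sgolayfilt(raw, p = params$savgol_order,
                                 n = params$savgol_window)
  dev <- abs(raw - smoothed)
  flag[flag == "accepted" & dev > params$outlier_px] <- "outlier_rejected"
  if (!any(flag == "accepted")) stop("all frames rejected")
  EndTrack(frame = seq_len(nf) - 1L, position = raw, flag = flag,
           nPixels = np, edgeMargin = em)
}

#' Fit the linear compaction rate
#'
#' Least-squares line through the accepted (time, end position) points of
#' an \linkS4class{EndTrack}, optionally restricted to a frame window.
#' The slope is reported both in pixels/frame and, using the kymogram
#' metadata, in micrometres/second. The slope is negative during
#' compaction; its magnitude is the compaction rate v.
#'
#' @param track an \linkS4class{EndTrack}
#' @param kymogram the source \linkS4class{Kymogram} (supplies
#'   frame interval and pixel size), or NULL if given explicitly
#' @param frameInterval,pixelSize metadata overrides
#' @param fitWindow optional c(first, last) frame (0-based) to fit within
#' @return A \linkS4class{CompactionFit}.
#' @export
fitCompactionRate <- function(track, kymogram = NULL, frameInterval = NULL,
                              pixelSize = NULL, fitWindow = NULL) {
  stopifnot(is(track, "EndTrack"))
  if (!is.null(kymogram)) {
    if (is.null(frameInterval)) frameInterval <- frameInterval(kymogram)
    if (is.null(pixelSize)) pixelSize <- pixelSize(kymogram)
  }
  if (is.null(frameInterval)) frameInterval <- 1
  if (is.null(pixelSize)) pixelSize <- 1
  keep <- track@flag == "accepted"
  if (!is.null(fitWindow))
    keep <- keep & track@frame >= fitWindow[1] & track@frame <= fitWindow[2]
  f <- track@frame[keep]; p <- track@position[keep]
  if (length(f) < 2L) stop("insufficient accepted points")
  fit <- stats::lm.fit(cbind(1, f), p)
  slope <- unname(fit$coefficients[2])
  res <- if (length(f) > 2L) stats::sd(fit$residuals) else 0
  new("CompactionFit", ratePxPerFrame = slope,
      rateUmPerS = slope * pixelSize / frameInterval,
      intercept = unname(fit$coefficients[1]),
      fitWindow = as.integer(range(f)), residualSd = res,
      nAccepted = length(f))
}
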