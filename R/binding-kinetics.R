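#' Segment a kymogram into compacted and uncompacted intensity traces
#'
#' Splits each kymogram frame at the DNA end position: the uncompacted
#' segment runs from the tether (column 1) up to just before the end, the
#' compacted segment from the end position to the far edge (the punctum
#' sits at the end; everything beyond it is background and contributes
#' zero after background subtraction). Produces the background-subtracted
#' totals Iu and Ic, the uncompacted mean density rho, and the compacted
#' length lc.
#'
#' @param kymogram a \linkS4class{Kymogram}
#' @param endPositions per-frame end positions: an \linkS4class{EndTrack}
#'   (all positions used, including flagged frames) or a numeric vector
#' @param background scalar background; when NULL it is estimated as the
#'   median of pixels lying beyond the initial end position plus a margin
#'   (off-DNA at all times)
#' @param punctumMargin pixels before the end position that are counted
#'   into the compacted segment. With exact end positions 0 is correct;
#'   with tracked positions the Gaussian smoothing in the tracker can
#'   place the detected end one pixel beyond the punctum, so a margin of
#'   about twice the smoothing sigma keeps the punctum on the compacted
#'   side.
#' @return A \linkS4class{SegmentTrace}.
#' @export
computeSegmentTrace <- function(kymogram, endPositions, background = NULL,
                                punctumMargin = 0L) {
  stopifnot(is(kymogram, "Kymogram"))
  if (is(endPositions, "EndTrack")) endPositions <- endPositions@position
  m <- intensity(kymogram)
  nf <- nrow(m); np <- ncol(m)
  if (length(endPositions) != nf)
    stop("one end position per frame required")
  e <- as.integer(round(pmin(pmax(endPositions, 1), np)))
  if (is.null(background)) {
    offStart <- min(np, max(e) + 5L)
    background <- if (offStart < np)
      stats::median(m[, offStart:np]) else stats::median(m)
  }
  Iu <- Ic <- rho <- numeric(nf)
  eSplit <- pmax(e - as.integer(punctumMargin), 1L)
  for (i in seq_len(nf)) {
    uc <- if (eSplit[i] > 1L) seq_len(eSplit[i] - 1L) else integer(0)
    cw <- eSplit[i]:np
    Iu[i] <- sum(m[i, uc]) - background * length(uc)
    Ic[i] <- sum(m[i, cw]) - background * length(cw)
    rho[i] <- if (length(uc)) Iu[i] / length(uc) else NA_real_
  }
  lc <- e[1] - e
  SegmentTrace(time = (seq_len(nf) - 1) * frameInterval(kymogram),
               Iu = Iu, Ic = Ic, rho = rho, lc = lc,
               frameInterval = frameInterval(kymogram))
}

#' Fluorescence-conservation statistic for DNA dye signal
#'
#' Tests whether dye fluorescence is conserved between the compacted and
#' uncompacted DNA segments during compaction: Iu is fit to a line, the
#' linear-fit value is subtracted from Ic at each frame, and the result is
#' divided by max(Ic). For conserved signal the statistic spans [-1, 1]
#' and crosses zero at the midpoint of compaction.
#'
#' @param trace a \linkS4class{SegmentTrace}
#' @return Numeric series (Ic - fit(Iu)) / max(Ic), one value per frame.
#' @export
yoyoConservation <- function(trace) {
  stopifnot(is(trace, "SegmentTrace"))
  Ic <- trace@Ic; Iu <- trace@Iu
  mIc <- max(Ic)
  if (!is.finite(mIc) || mIc <= 0)
    stop("max(Ic) must be positive")
  fit <- stats::lm.fit(cbind(1, trace@time), Iu)
  (Ic - (fit$coefficients[1] + fit$coefficients[2] * trace@time)) / mIc
}

#' Fit the uncompacted association rate constant
#'
#' Least-squares slope of the uncompacted fluorescence density rho versus
#' frame, giving the apparent linear association rate constant kappa
#' (intensity per pixel per frame). Frames after compaction completes
#' (no uncompacted pixels left) are excluded.
#'
#' @param trace a \linkS4class{SegmentTrace}
#' @return List of class \code{"bindingRateFit"} with \code{kappa} (per
#'   frame), \code{kappa_per_s}, \code{r_squared}, \code{fit_window}
#'   (frames) and \code{degenerate} flag.
#' @export
fitUncompactedDensityRate <- function(trace) {
  stopifnot(is(trace, "SegmentTrace"))
  ok <- is.finite(trace@rho)
  f <- trace@frame[ok]; r <- trace@rho[ok]
  if (length(f) < 5L) stop("need at least 5 frames with uncompacted signal")
  if (stats::var(r) < .Machine$double.eps * max(1, mean(r)^2)) {
    out <- list(kappa = 0, kappa_per_s = 0, r_squared = 0,
                fit_window = range(f), degenerate = TRUE)
    return(structure(out, class = "bindingRateFit"))
  }
  fit <- stats::lm(r ~ f)
  slope <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((r - mean(r))^2)
  structure(list(kappa = max(slope, 0),
                 kappa_per_s = max(slope, 0) / trace@frameInterval,
                 r_squared = r2,
                 fit_window = range(f),
                 degenerate = slope < 0),
            class = "bindingRateFit")
}

#' @export
print.bindingRateFit <- function(x, ...) {
  cat(sprintf("bindingRateFit: kappa = %.4g /frame (%.4g /s), r^2 = %.3f%s\n",
              x$kappa, x$kappa_per_s, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Model compacted-segment intensity under equal binding
#'
#' Predicted fluorescence of the compacted segment when protein associates
#' to compacted and uncompacted DNA at the same rate:
#' Ia(t) = kappa v t^2.
#'
#' @param kappa association rate constant (intensity per pixel per frame)
#' @param v linear compaction rate (pixels per frame)
#' @param t time (frames); vectorized
#' @return Predicted intensity.
#' @examples
#' modelIntensityEqual(2, 3, 2)   # 24
#' @export
modelIntensityEqual <- function(kappa, v, t) {
  if (any(kappa < 0) || any(v < 0) || any(t < 0))
    stop("kappa, v and t must be non-negative")
  kappa * v * t^2
}

#' Model compacted-segment intensity under blocked binding
#'
#' Predicted fluorescence when association to previously compacted DNA is
#' blocked, so the punctum only accumulates protein bound at the moment of
#' capture: Ib(t) = (1/2) kappa v t^2 - exactly half the equal-binding
#' prediction at every time.
#'
#' @inheritParams modelIntensityEqual
#' @return Predicted intensity.
#' @examples
#' modelIntensityBlocked(2, 3, 2)  # 12
#' @export
modelIntensityBlocked <- function(kappa, v, t) {
  0.5 * modelIntensityEqual(kappa, v, t)
}

#' Normalized compacted-segment intensity
#'
#' Divides the measured compacted intensity by the expected intensity
#' under equal binding, rho(t) * lc(t). The series centres on 1 when
#' binding to compacted DNA matches uncompacted DNA and on 0.5 when
#' binding to the compacted segment is blocked; values in between (or
#' trends) report partial impairment or enhancement.
#'
#' @param trace a \linkS4class{SegmentTrace} with rho and lc populated
#' @param minLc frames with lc below this are masked (NA)
#' @return Numeric series Ic / (rho * lc), NA on masked frames.
#' @export
normalizedCompactedIntensity <- function(trace, minLc = 1) {
  stopifnot(is(trace, "SegmentTrace"))
  denom <- trace@rho * trace@lc
  out <- ifelse(trace@lc >= minLc & is.finite(denom) & denom > 0,
                trace@Ic / denom, NA_real_)
  if (all(is.na(out))) stop("all frames masked")
  out
}

#' Pseudo-first-order rate ratio
#'
#' Predicted fold change of an association rate under a pseudo-first-order
#' model, i.e. the ratio of the two protein concentrations.
#'
#' @param conc1,conc2 concentrations in the same units
#' @return conc1 / conc2.
#' @examples
#' pseudoFirstOrderRatio(5, 0.5)  # 10-fold
#' @export
pseudoFirstOrderRatio <- function(conc1, conc2) {
  if (any(conc1 <= 0) || any(conc2 <= 0))
    stop("concentrations must be positive")
  conc1 / conc2
}

#' Binding sites per DNA molecule
#'
#' Estimated number of protein binding sites on a DNA of given length,
#' at one site per \code{site_bp} base pairs.
#'
#' @param dna_bp DNA length, base pairs
#' @param site_bp base pairs per binding site (default 60, the footprint
#'   probed by a 60-bp duplex)
#' @return Rounded number of sites.
#' @examples
#' bindingSitesPerDna(2700)  # ~45
#' bindingSitesPerDna(147)   # ~2
#' @export
bindingSitesPerDna <- function(dna_bp, site_bp = 60) {
  if (any(dna_bp <= 0) || any(site_bp <= 0))
    stop("lengths must be positive")
  round(dna_bp / site_bp)
}
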