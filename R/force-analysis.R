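#' Worm-like-chain parameters
#'
#' @param persistenceLength persistence length, nm (double-stranded DNA:
#'   ~50 nm)
#' @param contourLength contour length, micrometres
#' @param kBT thermal energy, pN nm (4.114 at 25 degrees C)
#' @param stretchModulus optional enthalpic stretch modulus, pN; NULL
#'   disables the extensible correction (second-order below ~40 pN)
#' @return List of class \code{"wlcParams"}.
#' @export
wlcParams <- function(persistenceLength = 50, contourLength = 16.49,
                      kBT = 4.114, stretchModulus = NULL) {
  if (persistenceLength <= 0 || contourLength <= 0 || kBT <= 0)
    stop("WLC parameters must be positive")
  structure(list(persistenceLength = persistenceLength,
                 contourLength = contourLength, kBT = kBT,
                 stretchModulus = stretchModulus),
            class = "wlcParams")
}

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation
#' F = (kBT / Lp) * (1 / (4 (1 - x/L0)^2) - 1/4 + x/L0). With a stretch
#' modulus S the relative extension is corrected iteratively to
#' x/L0 - F/S.
#'
#' @param extension extension, micrometres (0 <= x < L0); vectorized
#' @param params a \code{\link{wlcParams}} list
#' @return Force in pN.
#' @examples
#' p <- wlcParams(persistenceLength = 50, contourLength = 16)
#' wlcForce(8, p)   # x/L0 = 0.5 -> (4.114/50) * 1.25
#' @export
wlcForce <- function(extension, params = wlcParams()) {
  stopifnot(inherits(params, "wlcParams"))
  if (any(extension < 0)) stop("extension must be non-negative")
  if (any(extension >= params$contourLength))
    stop("extension must stay below the contour length")
  u <- extension / params$contourLength
  pref <- params$kBT / params$persistenceLength
  f <- pref * (1 / (4 * (1 - u)^2) - 0.25 + u)
  if (!is.null(params$stretchModulus)) {
    for (i in seq_len(50)) {
      ue <- pmax(pmin(u - f / params$stretchModulus, 1 - 1e-9), 0)
      f <- pref * (1 / (4 * (1 - ue)^2) - 0.25 + ue)
    }
  }
  f
}

#' Energy barrier between two force-extension curves
#'
#' Interpolates both curves onto the union grid of their shared extension
#' range, trapezoid-integrates the force difference (protein-bound minus
#' bare), converts pN um to kBT, and divides by the number of compacted
#' base pairs.
#'
#' @param bare,hp1 \linkS4class{ForceExtensionCurve}s
#' @param compactedBp base pairs of compacted DNA (> 0)
#' @param kBT thermal energy, pN nm
#' @return An \linkS4class{EnergyEstimate}.
#' @examples
#' x <- seq(1, 5.114, by = 0.1)
#' bare <- ForceExtensionCurve(x, rep(0, length(x)))
#' hp1 <- ForceExtensionCurve(x, rep(1, length(x)))
#' energyBetweenCurves(bare, hp1, compactedBp = 1000)  # 1 kBT/bp
#' @export
energyBetweenCurves <- function(bare, hp1, compactedBp, kBT = 4.114) {
  stopifnot(is(bare, "ForceExtensionCurve"), is(hp1, "ForceExtensionCurve"))
  if (compactedBp <= 0) stop("compactedBp must be positive")
  lo <- max(min(extension(bare)), min(extension(hp1)))
  hi <- min(max(extension(bare)), max(extension(hp1)))
  if (hi <= lo) stop("curves cover disjoint extension ranges")
  grid <- sort(unique(c(extension(bare), extension(hp1))))
  grid <- grid[grid >= lo & grid <= hi]
  fb <- stats::approx(extension(bare), force(bare), xout = grid)$y
  fh <- stats::approx(extension(hp1), force(hp1), xout = grid)$y
  area <- pracma::trapz(grid, fh - fb)
  new("EnergyEstimate", area = area, compactedBp = compactedBp,
      energyPerBp = kbtFromPnUm(area, kBT) / compactedBp, kBT = kBT)
}

#' Compacted DNA length from the extension deficit
#'
#' Extension deficit between the bare and protein-bound curves at a query
#' force, converted to base pairs using the extension-per-base-pair of
#' the bare curve at that force (deficit / (x_bare / total_bp)).
#'
#' @param bare,hp1 \linkS4class{ForceExtensionCurve}s; both must cross
#'   the query force
#' @param atForce query force, pN
#' @param totalBp total base pairs of the bare construct (lambda DNA:
#'   48,502)
#' @param nmPerBp crystallographic rise, nm per base pair (recorded for
#'   provenance; the conversion itself uses the bare curve)
#' @return Estimated compacted base pairs.
#' @examples
#' # 15 um at 20 pN for 48,502 bp; protein curve at 12 um -> about 9,700 bp
#' @export
compactedLengthFromDeficit <- function(bare, hp1, atForce, totalBp = 48502,
                                       nmPerBp = 0.34) {
  stopifnot(is(bare, "ForceExtensionCurve"), is(hp1, "ForceExtensionCurve"))
  xAt <- function(curve) {
    f <- force(curve); x <- extension(curve)
    if (atForce < min(f) || atForce > max(f))
      stop("force outside measured range")
    # invert on the monotone envelope of the pass
    stats::approx(f, x, xout = atForce, ties = "ordered")$y
  }
  xb <- xAt(bare); xh <- xAt(hp1)
  deficit <- xb - xh
  deficit / (xb / totalBp)
}

#' Minimal binding-site size from a dimer end-to-end distance
#'
#' Converts a protein dimer's end-to-end distance to the DNA length it
#' spans, assuming B-form DNA at 0.34 nm per base pair, rounded to the
#' nearest base pair.
#'
#' @param endToEndNm end-to-end distance, nm
#' @param nmPerBp rise per base pair, nm
#' @return Base pairs (integer-valued numeric).
#' @examples
#' bindingSiteSize(22.2)  # ~65 bp (open dimer)
#' bindingSiteSize(12.9)  # ~38 bp (closed dimer)
#' @export
bindingSiteSize <- function(endToEndNm, nmPerBp = 0.34) {
  if (any(endToEndNm <= 0) || nmPerBp <= 0)
    stop("distances must be positive")
  round(endToEndNm / nmPerBp)
}

#' Detect rupture events in a force-extension pass
#'
#' Flags force drops larger than \code{dropThreshold} within one grid
#' step during a stretch, the signature of a protein-DNA structure
#' rupturing.
#'
#' @param curve a \linkS4class{ForceExtensionCurve}
#' @param dropThreshold minimum force drop, pN
#' @return data.frame with \code{index}, \code{extension_um},
#'   \code{force_drop_pN} per event (zero rows when none).
#' @export
detectRuptures <- function(curve, dropThreshold = 2) {
  stopifnot(is(curve, "ForceExtensionCurve"))
  d <- diff(force(curve))
  idx <- which(d < -dropThreshold)
  data.frame(index = idx, extension_um = extension(curve)[idx],
             force_drop_pN = -d[idx])
}
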