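#' Kymogram of a single DNA strand
#'
#' Space-time intensity matrix for one DNA molecule on a curtain: rows are
#' movie frames, columns are positions along the DNA (column 1 is the
#' tethered barrier end; the free end moves toward column 1 during
#' compaction).
#'
#' @slot intensity numeric matrix, frames x positions
#' @slot frameInterval seconds per frame
#' @slot pixelSize micrometres per pixel
#' @slot strandId character label for the strand
#' @export
setClass("Kymogram",
  representation(intensity = "matrix", frameInterval = "numeric",
                 pixelSize = "numeric", strandId = "character"),
  prototype(frameInterval = 1, pixelSize = 0.16, strandId = "strand"))

setValidity("Kymogram", function(object) {
  m <- object@intensity
  if (!is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L)
    return("intensity must be a non-empty numeric matrix")
  if (any(!is.finite(m)))
    return("intensity must be finite")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Construct a Kymogram
#'
#' @param intensity frames x positions numeric matrix
#' @param frameInterval seconds per frame
#' @param pixelSize micrometres per pixel
#' @param strandId label
#' @return A \linkS4class{Kymogram}.
#' @examples
#' k <- Kymogram(matrix(rnorm(200, 10), 20, 10), frameInterval = 0.1)
#' dim(intensity(k))
#' @export
Kymogram <- function(intensity, frameInterval = 1, pixelSize = 0.16,
                     strandId = "strand") {
  new("Kymogram", intensity = intensity, frameInterval = frameInterval,
      pixelSize = pixelSize, strandId = strandId)
}

#' @rdname accessors
#' @export
setMethod("intensity", "Kymogram", function(object, ...) object@intensity)
#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymogram", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymogram", function(object) object@pixelSize)

setMethod("show", "Kymogram", function(object) {
  cat(sprintf("Kymogram '%s': %d frames x %d px (%.3g s/frame, %.3g um/px)\n",
              object@strandId, nrow(object@intensity), ncol(object@intensity),
              object@frameInterval, object@pixelSize))
})

#' Tracked DNA-end positions
#'
#' Per-frame position of the free DNA end, with a quality flag per frame:
#' \code{accepted}, \code{edge_excluded} (detection pinned to the edge
#' exclusion zone) or \code{outlier_rejected} (too far from the
#' Savitzky-Golay smoothed trajectory). Rejected frames keep their raw
#' position but are excluded from downstream fits, never interpolated.
#'
#' @slot frame integer frame indices (0-based times: frame i is time
#'   \code{i * frameInterval})
#' @slot position numeric end positions, pixels (1-based column index)
#' @slot flag character per-frame quality flag
#' @slot nPixels kymogram width used for tracking
#' @slot edgeMargin pixels excluded at either border
#' @export
setClass("EndTrack",
  representation(frame = "integer", position = "numeric", flag = "character",
                 nPixels = "integer", edgeMargin = "integer"))

.endtrack_flags <- c("accepted", "edge_excluded", "outlier_rejected")

setValidity("EndTrack", function(object) {
  n <- length(object@frame)
  if (length(object@position) != n || length(object@flag) != n)
    return("frame, position and flag must have equal length")
  if (!all(object@flag %in% .endtrack_flags))
    return("invalid quality flag")
  ok <- object@flag == "accepted"
  if (length(object@nPixels) == 1L && !is.na(object@nPixels) &&
      length(object@edgeMargin) == 1L && any(ok)) {
    p <- object@position[ok]
    if (any(p < object@edgeMargin | p > object@nPixels - object@edgeMargin))
      return("accepted positions must lie inside the edge margins")
  }
  TRUE
})

#' Construct an EndTrack
#'
#' @param frame integer frame indices
#' @param position end positions in pixels
#' @param flag per-frame quality flags ("accepted", "edge_excluded",
#'   "outlier_rejected")
#' @param nPixels kymogram width
#' @param edgeMargin edge exclusion margin in pixels
#' @return An \linkS4class{EndTrack}.
#' @export
EndTrack <- function(frame, position, flag = rep("accepted", length(frame)),
                     nPixels = NA_integer_, edgeMargin = 0L) {
  new("EndTrack", frame = as.integer(frame), position = as.numeric(position),
      flag = as.character(flag), nPixels = as.integer(nPixels),
      edgeMargin = as.integer(edgeMargin))
}

#' @rdname accessors
#' @export
setMethod("endPositions", "EndTrack", function(object) object@position)
#' @rdname accessors
#' @export
setMethod("qualityFlags", "EndTrack", function(object) object@flag)

setMethod("show", "EndTrack", function(object) {
  tb <- table(factor(object@flag, levels = .endtrack_flags))
  cat(sprintf("EndTrack: %d frames (%d accepted, %d edge, %d outlier)\n",
              length(object@frame), tb[["accepted"]], tb[["edge_excluded"]],
              tb[["outlier_rejected"]]))
})

#' Linear compaction-rate fit
#'
#' Least-squares line through accepted (time, end position) points. The
#' slope is negative during compaction (the end moves toward the tether);
#' its magnitude is the compaction rate v.
#'
#' @slot ratePxPerFrame fitted slope, pixels per frame
#' @slot rateUmPerS slope converted to micrometres per second
#' @slot intercept fitted position at frame 0, pixels
#' @slot fitWindow first and last frame used
#' @slot residualSd residual standard deviation, pixels
#' @slot nAccepted number of points in the fit
#' @export
setClass("CompactionFit",
  representation(ratePxPerFrame = "numeric", rateUmPerS = "numeric",
                 intercept = "numeric", fitWindow = "integer",
                 residualSd = "numeric", nAccepted = "integer"))

setValidity("CompactionFit", function(object) {
  if (length(object@ratePxPerFrame) != 1L || length(object@rateUmPerS) != 1L)
    return("rates must be scalars")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("compactionRate", "CompactionFit", function(object, units = c(
    "px_per_frame", "um_per_s")) {
  units <- match.arg(units)
  if (units == "px_per_frame") object@ratePxPerFrame else object@rateUmPerS
})

setMethod("show", "CompactionFit", function(object) {
  cat(sprintf(
    "CompactionFit: %.4g px/frame (%.4g um/s), n = %d, residual sd %.3g px\n",
    object@ratePxPerFrame, object@rateUmPerS, object@nAccepted,
    object@residualSd))
})

#' Compacted / uncompacted segment intensity traces
#'
#' Per-frame total intensities of the compacted (Ic) and uncompacted (Iu)
#' DNA segments of a kymogram, the mean fluorescence density on the
#' uncompacted segment (rho) and the compacted length (lc), all background
#' subtracted.
#'
#' @slot time seconds
#' @slot frame frame index (0-based)
#' @slot Iu total intensity on the uncompacted segment
#' @slot Ic total intensity on the compacted segment
#' @slot rho mean intensity per pixel on the uncompacted segment
#' @slot lc compacted length, pixels
#' @slot frameInterval seconds per frame
#' @export
setClass("SegmentTrace",
  representation(time = "numeric", frame = "integer", Iu = "numeric",
                 Ic = "numeric", rho = "numeric", lc = "numeric",
                 frameInterval = "numeric"))

setValidity("SegmentTrace", function(object) {
  n <- length(object@time)
  if (!all(c(length(object@Iu), length(object@Ic), length(object@rho),
             length(object@lc), length(object@frame)) == n))
    return("all series must have equal length")
  TRUE
})

#' Construct a SegmentTrace
#'
#' @param time seconds
#' @param Iu,Ic total segment intensities
#' @param rho uncompacted mean density (optional)
#' @param lc compacted length in pixels (optional)
#' @param frameInterval seconds per frame
#' @return A \linkS4class{SegmentTrace}.
#' @export
SegmentTrace <- function(time, Iu, Ic, rho = rep(NA_real_, length(time)),
                         lc = rep(NA_real_, length(time)),
                         frameInterval = if (length(time) > 1)
                           diff(time[1:2]) else 1) {
  new("SegmentTrace", time = as.numeric(time),
      frame = as.integer(round(time / frameInterval)),
      Iu = as.numeric(Iu), Ic = as.numeric(Ic), rho = as.numeric(rho),
      lc = as.numeric(lc), frameInterval = frameInterval)
}

setMethod("show", "SegmentTrace", function(object) {
  cat(sprintf("SegmentTrace: %d frames, max Ic = %.4g, max Iu = %.4g\n",
              length(object@time), suppressWarnings(max(object@Ic, na.rm = TRUE)),
              suppressWarnings(max(object@Iu, na.rm = TRUE))))
})

#' Segmented condensate regions
#'
#' One row per retained condensate: centroid (row/col, pixels), area,
#' equivalent radius (\code{sqrt(area/pi)}) in pixels and micrometres,
#' eccentricity and perimeter. The \code{condition} list carries the
#' experimental condition (protein and DNA concentration, DNA length).
#'
#' @slot regions data.frame of region properties
#' @slot imageId character identifier of the source image
#' @slot condition named list describing the condition
#' @slot pixelSize micrometres per pixel
#' @export
setClass("DropletSet",
  representation(regions = "data.frame", imageId = "character",
                 condition = "list", pixelSize = "numeric"),
  prototype(imageId = "image", condition = list(), pixelSize = 1))

setValidity("DropletSet", function(object) {
  need <- c("centroid_row", "centroid_col", "area_px", "radius_px",
            "radius_um", "eccentricity", "perimeter_px")
  if (nrow(object@regions) > 0 && !all(need %in% names(object@regions)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Construct a DropletSet
#'
#' @param regions region-properties data.frame (see class slots)
#' @param imageId source image label
#' @param condition named list (e.g. protein_conc_uM, dna_conc, dna_length_bp)
#' @param pixelSize micrometres per pixel
#' @return A \linkS4class{DropletSet}.
#' @export
DropletSet <- function(regions = data.frame(), imageId = "image",
                       condition = list(), pixelSize = 1) {
  new("DropletSet", regions = regions, imageId = imageId,
      condition = condition, pixelSize = pixelSize)
}

#' @rdname accessors
#' @export
setMethod("dropletRegions", "DropletSet", function(object) object@regions)
#' @rdname accessors
#' @param units return radii in pixels or micrometres
#' @export
setMethod("radii", "DropletSet", function(object, units = c("um", "px")) {
  units <- match.arg(units)
  if (nrow(object@regions) == 0) return(numeric(0))
  if (units == "um") object@regions$radius_um else object@regions$radius_px
})
setMethod("length", "DropletSet", function(x) nrow(x@regions))

setMethod("show", "DropletSet", function(object) {
  cat(sprintf("DropletSet '%s': %d condensates\n", object@imageId,
              nrow(object@regions)))
})

#' Radius distribution with bootstrap confidence bands
#'
#' Complementary cumulative distribution (CCD) of condensate radii pooled
#' over images, with percentile bootstrap confidence bands and the
#' expectation value of the radius obtained by integrating the CCD.
#'
#' @slot radii pooled radii (micrometres unless stated otherwise)
#' @slot grid radii at which the CCD is evaluated (includes 0)
#' @slot ccd fraction of condensates with radius >= grid value
#' @slot ciLo,ciHi bootstrap confidence band at each grid value
#' @slot expectedRadius integral of the CCD over the observed support
#' @slot expectedRadiusCi bootstrap interval for the expected radius
#' @slot nBoot,ciLevel bootstrap settings
#' @export
setClass("RadiusDistribution",
  representation(radii = "numeric", grid = "numeric", ccd = "numeric",
                 ciLo = "numeric", ciHi = "numeric",
                 expectedRadius = "numeric", expectedRadiusCi = "numeric",
                 nBoot = "integer", ciLevel = "numeric"))

setValidity("RadiusDistribution", function(object) {
  if (length(object@grid) != length(object@ccd))
    return("grid and ccd lengths differ")
  if (any(diff(object@ccd) > 1e-12))
    return("ccd must be non-increasing")
  if (length(object@ccd) && abs(object@ccd[1] - 1) > 1e-12)
    return("ccd must equal 1 at r = 0")
  if (object@expectedRadius < 0)
    return("expectedRadius must be non-negative")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("radii", "RadiusDistribution", function(object, ...) object@radii)
#' @rdname accessors
#' @export
setMethod("expectedRadius", "RadiusDistribution",
          function(object) object@expectedRadius)

setMethod("show", "RadiusDistribution", function(object) {
  cat(sprintf(
    "RadiusDistribution: n = %d, E[R] = %.4g [%.4g, %.4g] (%d bootstrap)\n",
    length(object@radii), object@expectedRadius, object@expectedRadiusCi[1],
    object@expectedRadiusCi[2], object@nBoot))
})

#' Power-law fit of expected radius versus concentration
#'
#' Fit of r = A * c^b on log-log axes by least squares.
#'
#' @slot amplitude A
#' @slot exponent b
#' @slot amplitudeSe,exponentSe standard errors
#' @slot n number of conditions fitted
#' @export
setClass("PowerLawFit",
  representation(amplitude = "numeric", exponent = "numeric",
                 amplitudeSe = "numeric", exponentSe = "numeric",
                 n = "integer"))

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: r = %.4g * c^%.4g (se %.2g, %.2g; n = %d)\n",
              object@amplitude, object@exponent, object@amplitudeSe,
              object@exponentSe, object@n))
})

#' FRAP intensity traces
#'
#' Raw region-mean intensity traces for one FRAP experiment: the bleached
#' ROI, every unbleached reference droplet, and the background.
#'
#' @slot time seconds (0 at the first frame)
#' @slot iFrap bleached-ROI mean intensity per frame
#' @slot iUnbleached frames x droplets matrix of unbleached droplet means
#' @slot iBackground background intensity per frame
#' @slot bleachFrame index of the last pre-bleach frame
#' @slot centroids droplets x 2 matrix of unbleached centroids (x = col,
#'   y = row); may have zero rows
#' @slot bleachCentroid length-2 centroid of the bleached droplet (x, y)
#' @export
setClass("FrapTrace",
  representation(time = "numeric", iFrap = "numeric", iUnbleached = "matrix",
                 iBackground = "numeric", bleachFrame = "integer",
                 centroids = "matrix", bleachCentroid = "numeric"))

setValidity("FrapTrace", function(object) {
  n <- length(object@time)
  if (length(object@iFrap) != n || length(object@iBackground) != n)
    return("traces must share the time axis")
  if (nrow(object@iUnbleached) > 0 && nrow(object@iUnbleached) != n)
    return("iUnbleached must have one row per frame")
  if (object@bleachFrame < 1L || object@bleachFrame >= n)
    return("bleachFrame must leave pre- and post-bleach frames")
  TRUE
})

#' Construct a FrapTrace
#'
#' @param time seconds
#' @param iFrap bleached-ROI intensity trace
#' @param iUnbleached matrix of unbleached droplet traces (frames x droplets)
#' @param iBackground background trace (scalar recycled)
#' @param bleachFrame last pre-bleach frame index
#' @param centroids unbleached centroids, droplets x 2 (x, y)
#' @param bleachCentroid centroid of the bleached droplet (x, y)
#' @return A \linkS4class{FrapTrace}.
#' @export
FrapTrace <- function(time, iFrap, iUnbleached, iBackground = 0,
                      bleachFrame, centroids = matrix(numeric(0), 0, 2),
                      bleachCentroid = c(NA_real_, NA_real_)) {
  if (length(iBackground) == 1L) iBackground <- rep(iBackground, length(time))
  if (is.null(dim(iUnbleached)))
    iUnbleached <- matrix(iUnbleached, ncol = 1L)
  new("FrapTrace", time = as.numeric(time), iFrap = as.numeric(iFrap),
      iUnbleached = iUnbleached, iBackground = as.numeric(iBackground),
      bleachFrame = as.integer(bleachFrame), centroids = centroids,
      bleachCentroid = as.numeric(bleachCentroid))
}

setMethod("show", "FrapTrace", function(object) {
  cat(sprintf("FrapTrace: %d frames, bleach after frame %d, %d unbleached\n",
              length(object@time), object@bleachFrame,
              ncol(object@iUnbleached)))
})

#' Biexponential fit
#'
#' Parameters of a biexponential recovery
#' y(t) = plateau - a exp(-k1 t) - b exp(-k2 t) or decay
#' y(t) = a exp(-k1 t) + b exp(-k2 t), with the recovery half-time solved
#' from the fitted curve.
#'
#' @slot a,b amplitudes (normalized scale)
#' @slot k1,k2 rate constants, 1/s (k1 >= k2 by convention)
#' @slot plateau fitted plateau (recovery form; NA for decay)
#' @slot tHalf time at which the fitted curve crosses halfway between its
#'   post-bleach floor and the plateau; NA if not defined
#' @slot residualSd residual standard deviation
#' @slot converged logical fit-convergence flag
#' @slot form "recovery" or "decay"
#' @export
setClass("BiExpFit",
  representation(a = "numeric", b = "numeric", k1 = "numeric", k2 = "numeric",
                 plateau = "numeric", tHalf = "numeric",
                 residualSd = "numeric", converged = "logical",
                 form = "character"))

setValidity("BiExpFit", function(object) {
  if (isTRUE(object@converged) && (object@k1 <= 0 || object@k2 <= 0))
    return("rate constants must be positive")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("halfTime", "BiExpFit", function(object) object@tHalf)
#' @rdname accessors
#' @export
setMethod("rateConstants", "BiExpFit",
          function(object) c(k1 = object@k1, k2 = object@k2))

setMethod("show", "BiExpFit", function(object) {
  cat(sprintf(
    "BiExpFit (%s): a = %.3g, b = %.3g, k1 = %.3g, k2 = %.3g /s, t1/2 = %.3g s%s\n",
    object@form, object@a, object@b, object@k1, object@k2, object@tHalf,
    if (object@converged) "" else " [not converged]"))
})

#' Spatially varying photobleach decay model
#'
#' Whole-field photobleaching model: droplet fluorescence decays
#' biexponentially with rate constants that vary linearly with position,
#' k1(x, y) = k1_0 + x alpha1 + y beta1 and
#' k2(x, y) = k2_0 + x alpha2 + y beta2, with population-average
#' amplitudes.
#'
#' @slot aMean,bMean average amplitudes across unbleached droplets
#' @slot k10,k20 rate intercepts, 1/s
#' @slot alpha1,beta1,alpha2,beta2 rate gradients, 1/s per pixel
#' @slot perDroplet data.frame of per-droplet fits (x, y, a, b, k1, k2)
#' @export
setClass("SpatialDecayModel",
  representation(aMean = "numeric", bMean = "numeric", k10 = "numeric",
                 k20 = "numeric", alpha1 = "numeric", beta1 = "numeric",
                 alpha2 = "numeric", beta2 = "numeric",
                 perDroplet = "data.frame"))

#' @rdname decayRateAt
#' @export
setMethod("decayRateAt", "SpatialDecayModel", function(object, x, y) {
  list(k1 = object@k10 + x * object@alpha1 + y * object@beta1,
       k2 = object@k20 + x * object@alpha2 + y * object@beta2)
})

setMethod("show", "SpatialDecayModel", function(object) {
  cat(sprintf(
    "SpatialDecayModel: <a> = %.3g, <b> = %.3g\n  k1(x,y) = %.4g + %.3g x + %.3g y\n  k2(x,y) = %.4g + %.3g x + %.3g y  (%d droplets)\n",
    object@aMean, object@bMean, object@k10, object@alpha1, object@beta1,
    object@k20, object@alpha2, object@beta2, nrow(object@perDroplet)))
})

#' Force-extension curve
#'
#' One stretch or relax pass of an optical-trap experiment.
#'
#' @slot extension micrometres, strictly increasing within the pass
#' @slot force piconewtons
#' @slot direction "stretch" or "relax"
#' @slot cycleIndex stretch-relax cycle number
#' @export
setClass("ForceExtensionCurve",
  representation(extension = "numeric", force = "numeric",
                 direction = "character", cycleIndex = "integer"),
  prototype(direction = "stretch", cycleIndex = 1L))

setValidity("ForceExtensionCurve", function(object) {
  if (length(object@extension) != length(object@force))
    return("extension and force must have equal length")
  if (any(diff(object@extension) <= 0))
    return("extension must be strictly increasing within a pass")
  if (!object@direction %in% c("stretch", "relax"))
    return("direction must be 'stretch' or 'relax'")
  TRUE
})

#' Construct a ForceExtensionCurve
#'
#' @param extension micrometres, strictly increasing
#' @param force piconewtons
#' @param direction "stretch" or "relax"
#' @param cycleIndex cycle number
#' @return A \linkS4class{ForceExtensionCurve}.
#' @export
ForceExtensionCurve <- function(extension, force, direction = "stretch",
                                cycleIndex = 1L) {
  new("ForceExtensionCurve", extension = as.numeric(extension),
      force = as.numeric(force), direction = direction,
      cycleIndex = as.integer(cycleIndex))
}

#' @rdname accessors
#' @export
setMethod("extension", "ForceExtensionCurve", function(object) object@extension)
#' @rdname accessors
#' @export
setMethod("force", "ForceExtensionCurve", function(object) object@force)

setMethod("show", "ForceExtensionCurve", function(object) {
  cat(sprintf(
    "ForceExtensionCurve (%s, cycle %d): %d points, %.3g-%.3g um, max %.3g pN\n",
    object@direction, object@cycleIndex, length(object@extension),
    min(object@extension), max(object@extension), max(object@force)))
})

#' Energy barrier between force-extension curves
#'
#' Area between a protein-bound and a bare DNA force-extension curve,
#' expressed as thermal energy per base pair of compacted DNA.
#'
#' @slot area pN um, trapezoid integral of the force difference
#' @slot compactedBp base pairs of compacted DNA
#' @slot energyPerBp kBT per base pair
#' @slot kBT thermal energy used for the conversion, pN nm
#' @export
setClass("EnergyEstimate",
  representation(area = "numeric", compactedBp = "numeric",
                 energyPerBp = "numeric", kBT = "numeric"))

setValidity("EnergyEstimate", function(object) {
  expected <- object@area / (object@kBT * 1e-3) / object@compactedBp
  if (abs(expected - object@energyPerBp) >
      1e-9 * max(1, abs(object@energyPerBp)))
    return("energyPerBp inconsistent with area, kBT and compactedBp")
  TRUE
})

setMethod("show", "EnergyEstimate", function(object) {
  cat(sprintf("EnergyEstimate: %.4g pN um over %g bp = %.4g kBT/bp\n",
              object@area, object@compactedBp, object@energyPerBp))
})
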