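#' Accessor generics
#'
#' Small family of accessor generics shared by the container classes.
#' Accessors are the supported way to reach slot contents.
#'
#' @param object,x an object of one of the package's S4 classes
#' @param ... further arguments for methods
#' @return The slot contents; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object, ...) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("endPositions", function(object) standardGeneric("endPositions"))

#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))

#' @rdname accessors
#' @export
setGeneric("compactionRate",
           function(object, units = c("px_per_frame", "um_per_s"))
             standardGeneric("compactionRate"))

#' @rdname accessors
#' @export
setGeneric("dropletRegions", function(object) standardGeneric("dropletRegions"))

#' @rdname accessors
#' @export
setGeneric("radii", function(object, ...) standardGeneric("radii"))

#' @rdname accessors
#' @export
setGeneric("expectedRadius", function(object) standardGeneric("expectedRadius"))

#' @rdname accessors
#' @export
setGeneric("halfTime", function(object) standardGeneric("halfTime"))

#' @rdname accessors
#' @export
setGeneric("rateConstants", function(object) standardGeneric("rateConstants"))

#' @rdname accessors
#' @export
setGeneric("extension", function(object) standardGeneric("extension"))

#' @rdname accessors
#' @export
setGeneric("force", function(object) standardGeneric("force"))

#' Predicted local decay rates
#'
#' Evaluate a fitted spatially varying photobleach model at image
#' coordinates, returning the two local decay rate constants.
#'
#' @param object a \linkS4class{SpatialDecayModel}
#' @param x,y image coordinates (x = column index, y = row index), in pixels
#' @return A list with numeric vectors \code{k1} and \code{k2} (1/s).
#' @export
setGeneric("decayRateAt", function(object, x, y) standardGeneric("decayRateAt"))
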