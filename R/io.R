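#' Read a multi-frame TIFF as a list of matrices
#'
#' Reads a stack written by \code{\link{writeImageStack}} (applying the
#' intensity-scale sidecar when present) or any other TIFF.
#'
#' @param path TIFF file
#' @return List of numeric matrices, one per frame. Multi-channel frames
#'   are reduced to their first channel.
#' @export
readImageStack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    unclass(f)
  })
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- lapply(frames, function(f) f * sc$scale + sc$offset)
  }
  frames
}

#' Write a list of matrices as a multi-frame float TIFF
#'
#' TIFF storage is unit-range, so the stack is affinely mapped to [0, 1]
#' and the transform recorded in a JSON sidecar
#' (\code{<path>.json}); \code{\link{readImageStack}} undoes it, making
#' intensities round-trip to float precision.
#'
#' @param frames list of numeric matrices (or a single matrix)
#' @param path output file
#' @return Invisibly, the path.
#' @export
writeImageStack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(frames, function(f) (f - lo) / scale), path,
                  bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(offset = lo, scale = scale,
                            n_frames = length(frames)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an end track as CSV
#'
#' Columns: frame, time_s, position_px, flag.
#'
#' @param track an \linkS4class{EndTrack}
#' @param path output CSV
#' @param frameInterval seconds per frame for the time column
#' @return Invisibly, the data.frame written.
#' @export
writeEndTrack <- function(track, path, frameInterval = 1) {
  df <- data.frame(frame = track@frame,
                   time_s = track@frame * frameInterval,
                   position_px = track@position, flag = track@flag)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read/write force-extension curves as CSV
#'
#' CSV schema: extension_um, force_pN, direction, cycle.
#'
#' @param path CSV file
#' @return List of \linkS4class{ForceExtensionCurve}s, one per
#'   (direction, cycle) pass.
#' @export
readForceExtensionCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("extension_um", "force_pN")
  if (!all(need %in% names(df))) stop("missing extension_um/force_pN columns")
  if (is.null(df$direction)) df$direction <- "stretch"
  if (is.null(df$cycle)) df$cycle <- 0L
  parts <- split(df, list(df$direction, df$cycle), drop = TRUE)
  lapply(unname(parts), function(p)
    ForceExtensionCurve(p$extension_um, p$force_pN, p$direction[1],
                        as.integer(p$cycle[1])))
}

#' @rdname readForceExtensionCsv
#' @param curves list of \linkS4class{ForceExtensionCurve}s (or one)
#' @export
writeForceExtensionCsv <- function(curves, path) {
  if (is(curves, "ForceExtensionCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(extension_um = extension(cv), force_pN = force(cv),
               direction = cv@direction, cycle = cv@cycleIndex)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
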