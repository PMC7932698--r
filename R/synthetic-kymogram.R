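#' Specification for a synthetic curtain kymogram
#'
#' Phenomenological model of an HP1-driven DNA compaction kymogram: the
#' free DNA end starts at \code{end_start} and moves linearly toward the
#' tether (column 1) at \code{compaction_rate_v} pixels/frame; protein
#' associates uniformly on uncompacted DNA so the fluorescence density
#' there grows as kappa * t; the compacted punctum at the end position
#' accumulates the swept-up signal. Under \code{binding = "equal"} the
#' punctum also keeps exchanging with solution (intensity
#' kappa * t * lc(t)); under \code{binding = "blocked"} each DNA element
#' keeps the density it had when it was captured, integrating to
#' (1/2) kappa v t^2.
#'
#' @param n_frames,n_pixels kymogram dimensions
#' @param frame_interval seconds per frame
#' @param pixel_size micrometres per pixel
#' @param end_start free-end position at t = 0, pixels (1-based, must be
#'   less than n_pixels)
#' @param compaction_rate_v compaction rate, pixels per frame (>= 0)
#' @param association_rate_kappa protein association rate, intensity per
#'   pixel per frame (>= 0)
#' @param compacted_gain dimensionless >= 1 gain applied to punctum signal
#' @param dna_intensity initial dye signal per uncompacted pixel
#' @param noise_sigma camera noise sd (Gaussian model) in intensity units
#' @param background camera offset
#' @param binding "equal" or "blocked" protein association to compacted DNA
#' @param noise_model "gaussian" (default) or "poisson"
#' @param seed integer seed; all generator randomness flows from it
#' @return A validated list of class \code{"kymogramSpec"}.
#' @examples
#' sp <- kymogramSpec(n_frames = 50, end_start = 100, compaction_rate_v = 2)
#' sim <- genKymogram(sp)
#' sim$kymogram
#' @export
kymogramSpec <- function(n_frames = 100L, n_pixels = 256L,
                         frame_interval = 0.1, pixel_size = 0.16,
                         end_start = 200L, compaction_rate_v = 2,
                         association_rate_kappa = 0.5, compacted_gain = 1,
                         dna_intensity = 50, noise_sigma = 5,
                         background = 100, binding = c("equal", "blocked"),
                         noise_model = c("gaussian", "poisson"), seed = 1L) {
  binding <- match.arg(binding)
  noise_model <- match.arg(noise_model)
  if (n_frames < 1 || n_pixels < 2)
    stop("non-positive kymogram dimensions")
  if (compaction_rate_v < 0 || association_rate_kappa < 0 || noise_sigma < 0)
    stop("rates and noise must be non-negative")
  if (end_start >= n_pixels || end_start < 1)
    stop("end_start must lie inside [1, n_pixels)")
  if (compacted_gain < 1) stop("compacted_gain must be >= 1")
  structure(list(
    n_frames = as.integer(n_frames), n_pixels = as.integer(n_pixels),
    frame_interval = frame_interval, pixel_size = pixel_size,
    end_start = end_start, compaction_rate_v = compaction_rate_v,
    association_rate_kappa = association_rate_kappa,
    compacted_gain = compacted_gain, dna_intensity = dna_intensity,
    noise_sigma = noise_sigma, background = background, binding = binding,
    noise_model = noise_model, seed = as.integer(seed)),
    class = "kymogramSpec")
}

# True end position (pixels) at 0-based frame times; clamped at the tether.
kymogramTrueEnd <- function(spec, t = seq_len(spec$n_frames) - 1) {
  pmax(spec$end_start - spec$compaction_rate_v * t, 1)
}

#' Generate a synthetic kymogram with ground truth
#'
#' Renders the deterministic compaction signal described in
#' \code{\link{kymogramSpec}} and adds i.i.d. camera noise. The true
#' per-frame end positions are returned alongside as an
#' \linkS4class{EndTrack}; no generator output lacks its truth record.
#'
#' @param spec a \code{\link{kymogramSpec}}
#' @return List with elements \code{kymogram} (\linkS4class{Kymogram}),
#'   \code{truth} (list: \code{endTrack}, \code{end_px}, \code{v},
#'   \code{kappa}, \code{lc}, \code{rho}, \code{Ic}, \code{Iu},
#'   \code{t_complete}) and \code{spec}.
#' @export
genKymogram <- function(spec) {
  stopifnot(inherits(spec, "kymogramSpec"))
  nf <- spec$n_frames; np <- spec$n_pixels
  t <- seq_len(nf) - 1
  e <- kymogramTrueEnd(spec, t)
  ei <- as.integer(round(e))
  kappa <- spec$association_rate_kappa
  v <- spec$compaction_rate_v
  lc <- spec$end_start - e
  # time at which the end reaches the tether; blocked-binding punctum
  # intensity freezes there because nothing more is swept up
  t_complete <- if (v > 0) (spec$end_start - 1) / v else Inf
  punctum <- switch(spec$binding,
    equal   = kappa * t * lc,
    blocked = 0.5 * kappa * v * pmin(t, t_complete)^2)
  m <- matrix(spec$background, nf, np)
  for (i in seq_len(nf)) {
    if (ei[i] > 1)
      m[i, seq_len(ei[i] - 1L)] <- spec$background + spec$dna_intensity +
        kappa * t[i]
    m[i, ei[i]] <- spec$background +
      spec$compacted_gain * (spec$dna_intensity * lc[i] + punctum[i])
  }
  if (spec$noise_sigma > 0 || spec$noise_model == "poisson") {
    m <- withSeed(spec$seed, {
      if (spec$noise_model == "gaussian")
        m + matrix(stats::rnorm(nf * np, sd = spec$noise_sigma), nf, np)
      else
        matrix(stats::rpois(nf * np, lambda = pmax(m, 0)), nf, np)
    })
  }
  kym <- Kymogram(m, frameInterval = spec$frame_interval,
                  pixelSize = spec$pixel_size, strandId = "synthetic")
  truth <- list(
    endTrack = EndTrack(frame = t, position = e, nPixels = np,
                        edgeMargin = 0L),
    end_px = e, v = v, kappa = kappa, lc = lc,
    rho = spec$dna_intensity + kappa * t,
    Ic = spec$dna_intensity * lc + punctum,
    Iu = (spec$dna_intensity + kappa * t) * (ei - 1),
    t_complete = t_complete)
  list(kymogram = kym, truth = truth, spec = spec)
}

#' Render a single curtain frame with vertical DNA strands
#'
#' Convenience generator for strand detection: a single image (rows =
#' position along DNA, columns = lateral position) with DNA strands as
#' bright vertical lines of given length.
#'
#' @param n_rows,n_cols image dimensions
#' @param strand_cols column indices of strand centres
#' @param strand_length rows covered by each strand (from row 1)
#' @param dna_intensity intensity above background on the strand
#' @param background camera offset
#' @param noise_sigma Gaussian noise sd
#' @param seed integer seed
#' @return List with \code{frame} (matrix) and \code{truth}
#'   (\code{strand_cols}).
#' @export
genCurtainFrame <- function(n_rows = 128L, n_cols = 64L,
                            strand_cols = integer(0),
                            strand_length = round(0.8 * n_rows),
                            dna_intensity = 50, background = 100,
                            noise_sigma = 0, seed = 1L) {
  if (length(strand_cols) &&
      any(strand_cols < 2 | strand_cols > n_cols - 1))
    stop("strand columns must keep a 1-px border inside the frame")
  m <- matrix(background, n_rows, n_cols)
  for (cc in strand_cols)
    m[seq_len(strand_length), cc] <- background + dna_intensity
  if (noise_sigma > 0)
    m <- withSeed(seed,
      m + matrix(stats::rnorm(n_rows * n_cols, sd = noise_sigma),
                 n_rows, n_cols))
  list(frame = m, truth = list(strand_cols = sort(strand_cols)))
}

#' Render a synthetic curtain movie
#'
#' Stacks per-frame images in which each strand column carries the
#' kymogram profile of a seeded \code{\link{genKymogram}} run, so that
#' \code{\link{extractKymogram}} applied to the movie reproduces the
#' generator's internal kymogram.
#'
#' @param spec a \code{\link{kymogramSpec}} (noise is applied per movie
#'   pixel, not per kymogram pixel)
#' @param strand_cols column indices of strand centres (>= 2 px from edges)
#' @param n_cols lateral movie width
#' @return List with \code{movie} (list of matrices, rows = position,
#'   cols = lateral), \code{truth} and \code{spec}.
#' @export
genCurtainMovie <- function(spec, strand_cols = c(20L, 40L), n_cols = 64L) {
  stopifnot(inherits(spec, "kymogramSpec"))
  if (any(strand_cols < 2 | strand_cols > n_cols - 1))
    stop("strand columns must keep a 1-px border inside the frame")
  clean <- genKymogram(modifyListSpec(spec, noise_sigma = 0,
                                      noise_model = "gaussian"))
  prof <- intensity(clean$kymogram)  # frames x positions, noiseless
  nf <- spec$n_frames
  movie <- withSeed(spec$seed, lapply(seq_len(nf), function(i) {
    f <- matrix(spec$background, spec$n_pixels, n_cols)
    for (cc in strand_cols)
      f[, (cc - 1L):(cc + 1L)] <- prof[i, ]
    if (spec$noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), sd = spec$noise_sigma),
                      nrow(f), ncol(f))
    f
  }))
  list(movie = movie, truth = c(clean$truth,
                                list(strand_cols = sort(strand_cols))),
       spec = spec)
}

# Re-build a spec with some fields replaced (keeps validation).
modifyListSpec <- function(spec, ...) {
  args <- utils::modifyList(unclass(spec), list(...))
  do.call(kymogramSpec, args)
}
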