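#' Specification for synthetic force-extension curves
#'
#' Worm-like-chain (WLC) baseline curve for bare DNA, plus a
#' protein-bound curve built from a WLC of reduced contour length
#' (\code{compacted_bp} base pairs sequestered at 0.34 nm/bp) with an
#' optional additional force offset. The enclosed area between the two
#' noiseless curves over the extension grid is recorded as ground truth.
#'
#' @param contour_length_L0 contour length, micrometres (lambda DNA:
#'   48,502 bp x 0.34 nm/bp = 16.49 um)
#' @param persistence_length_Lp persistence length, nm
#' @param kBT thermal energy, pN nm
#' @param total_bp total base pairs of the construct
#' @param compacted_bp base pairs sequestered by protein (ground truth)
#' @param extra_force_offset list describing the additional force shift:
#'   \code{list(type = "none")}, \code{list(type = "constant", amplitude,
#'   from, to)} (pN over an extension window, um) or \code{list(type =
#'   "gaussian", amplitude, center, width)}
#' @param extension_grid extension values, um, strictly increasing and
#'   strictly below the bare contour length; the protein-bound curve is
#'   evaluated on the subset reaching up to 98 percent of its reduced
#'   contour length (it leaves the grid earlier because compaction
#'   shortens the chain)
#' @param noise_sigma force noise sd, pN
#' @param seed integer seed
#' @return A validated list of class \code{"forceExtensionSpec"}.
#' @export
forceExtensionSpec <- function(contour_length_L0 = 16.49,
                               persistence_length_Lp = 50, kBT = 4.114,
                               total_bp = 48502L, compacted_bp = 5000,
                               extra_force_offset = list(type = "none"),
                               extension_grid = seq(1, 16, by = 0.05),
                               noise_sigma = 0, seed = 1L) {
  if (contour_length_L0 <= 0 || persistence_length_Lp <= 0 || kBT <= 0)
    stop("WLC parameters must be positive")
  if (compacted_bp < 0 || compacted_bp >= total_bp)
    stop("compacted_bp must lie in [0, total_bp)")
  L0hp1 <- contour_length_L0 - compacted_bp * 0.34e-3
  if (any(diff(extension_grid) <= 0))
    stop("extension grid must be strictly increasing")
  if (max(extension_grid) >= contour_length_L0)
    stop("extension must stay below the contour length")
  if (min(extension_grid) >= 0.98 * L0hp1)
    stop("no grid points below the reduced contour length")
  if (min(extension_grid) < 0) stop("forces require non-negative extension")
  structure(list(contour_length_L0 = contour_length_L0,
                 persistence_length_Lp = persistence_length_Lp, kBT = kBT,
                 total_bp = as.integer(total_bp),
                 compacted_bp = compacted_bp,
                 extra_force_offset = extra_force_offset,
                 extension_grid = extension_grid,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "forceExtensionSpec")
}

forceOffsetFun <- function(off, x) {
  switch(off$type,
    none = rep(0, length(x)),
    constant = ifelse(x >= off$from & x <= off$to, off$amplitude, 0),
    gaussian = off$amplitude * exp(-(x - off$center)^2 / (2 * off$width^2)),
    stop("unknown offset type"))
}

#' Generate a pair of synthetic force-extension curves
#'
#' @param spec a \code{\link{forceExtensionSpec}}
#' @return List with \code{bare} and \code{hp1}
#'   (\linkS4class{ForceExtensionCurve}), and \code{truth} (list:
#'   \code{area} pN um between the noiseless curves, \code{compacted_bp},
#'   \code{energy_per_bp} in kBT/bp).
#' @export
genForceExtension <- function(spec) {
  stopifnot(inherits(spec, "forceExtensionSpec"))
  x <- spec$extension_grid
  wlc <- wlcParams(persistenceLength = spec$persistence_length_Lp,
                   contourLength = spec$contour_length_L0, kBT = spec$kBT)
  L0hp1 <- spec$contour_length_L0 - spec$compacted_bp * 0.34e-3
  wlcHp1 <- wlcParams(persistenceLength = spec$persistence_length_Lp,
                      contourLength = L0hp1, kBT = spec$kBT)
  xh <- x[x < 0.98 * L0hp1]
  fBare <- wlcForce(x, wlc)
  fHp1 <- wlcForce(xh, wlcHp1) + forceOffsetFun(spec$extra_force_offset, xh)
  # enclosed area between the noiseless curves over the shared grid
  area <- pracma::trapz(xh, fHp1 - fBare[seq_along(xh)])
  if (spec$noise_sigma > 0) {
    noise <- withSeed(spec$seed,
      stats::rnorm(length(x) + length(xh), sd = spec$noise_sigma))
    fBare <- fBare + noise[seq_along(x)]
    fHp1 <- fHp1 + noise[length(x) + seq_along(xh)]
  }
  list(bare = ForceExtensionCurve(x, fBare, "stretch", 0L),
       hp1 = ForceExtensionCurve(xh, fHp1, "stretch", 1L),
       truth = list(area = area, compacted_bp = spec$compacted_bp,
                    energy_per_bp = if (spec$compacted_bp > 0)
                      kbtFromPnUm(area, spec$kBT) / spec$compacted_bp
                    else NA_real_),
       spec = spec)
}
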