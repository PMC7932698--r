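#' Specification for a synthetic brightfield condensate field
#'
#' Emulates brightfield images of phase-separated droplets: each droplet
#' boundary carries an annular bright/dark rim (a derivative-of-Gaussian
#' radial profile, bright just inside and dark just outside the radius)
#' while the interior contrast against background is near zero, which is
#' what defeats plain threshold segmentation on real images.
#'
#' @param image_shape c(rows, cols) in pixels
#' @param radii ground-truth droplet radii, pixels
#' @param centers optional n x 2 matrix of (row, col) centres; when NULL,
#'   non-overlapping centres are drawn with the spec seed
#' @param edge_ring_contrast rim amplitude (intensity units)
#' @param interior_contrast interior offset relative to background
#'   (near zero by design)
#' @param ring_width radial Gaussian width of the rim, pixels
#' @param background image background level
#' @param noise_sigma Gaussian camera noise sd
#' @param min_gap minimum clearance between droplet rims, pixels
#' @param seed integer seed
#' @return A validated list of class \code{"dropletFieldSpec"}.
#' @examples
#' sp <- dropletFieldSpec(radii = c(4, 8, 12), seed = 7)
#' img <- genDropletImage(sp)
#' img$truth$centers
#' @export
dropletFieldSpec <- function(image_shape = c(256L, 256L), radii = c(5, 10),
                             centers = NULL, edge_ring_contrast = 0.5,
                             interior_contrast = 0.02, ring_width = 1.5,
                             background = 1, noise_sigma = 0, min_gap = 4,
                             seed = 1L) {
  if (any(image_shape < 8)) stop("image too small")
  if (any(radii <= 0)) stop("radii must be positive")
  if (!is.null(centers)) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    if (nrow(centers) != length(radii))
      stop("centers and radii must match")
  } else if (length(radii)) {
    centers <- placeDroplets(image_shape, radii, min_gap, seed)
  } else {
    centers <- matrix(numeric(0), 0, 2)
  }
  if (nrow(centers) > 1) {
    d <- as.matrix(stats::dist(centers))
    sums <- outer(radii, radii, "+")
    if (any(d[upper.tri(d)] <= sums[upper.tri(sums)]))
      stop("droplets must not overlap")
  }
  structure(list(image_shape = as.integer(image_shape), radii = radii,
                 centers = centers, edge_ring_contrast = edge_ring_contrast,
                 interior_contrast = interior_contrast,
                 ring_width = ring_width, background = background,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "dropletFieldSpec")
}

# Seeded rejection sampling of non-overlapping centres kept clear of the
# image border.
placeDroplets <- function(image_shape, radii, min_gap, seed) {
  withSeed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    for (r in radii) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(stats::runif(1, r + min_gap, image_shape[1] - r - min_gap),
                  stats::runif(1, r + min_gap, image_shape[2] - r - min_gap))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >
                radii[seq_len(nrow(centers))] + r + min_gap)) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place droplets without overlap")
    }
    unname(centers)
  })
}

#' Generate a synthetic brightfield droplet image with ground truth
#'
#' @param spec a \code{\link{dropletFieldSpec}}
#' @return List with \code{image} (matrix), \code{truth} (list:
#'   \code{centers} (row, col), \code{radii},
#'   \code{droplets} = \linkS4class{DropletSet}) and \code{spec}.
#' @export
genDropletImage <- function(spec) {
  stopifnot(inherits(spec, "dropletFieldSpec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  img <- matrix(spec$background, nr, nc)
  w <- spec$ring_width
  for (i in seq_along(spec$radii)) {
    R <- spec$radii[i]
    cr <- spec$centers[i, 1]; cc <- spec$centers[i, 2]
    ext <- ceiling(R + 4 * w)
    rows <- max(1, floor(cr - ext)):min(nr, ceiling(cr + ext))
    cols <- max(1, floor(cc - ext)):min(nc, ceiling(cc + ext))
    d <- sqrt(outer((rows - cr)^2, (cols - cc)^2, "+"))
    # derivative-of-Gaussian rim: bright just inside R, dark just outside
    rim <- spec$edge_ring_contrast * (-(d - R) / w) *
      exp(-(d - R)^2 / (2 * w^2))
    interior <- spec$interior_contrast / (1 + exp((d - R + w) / (w / 2)))
    img[rows, cols] <- img[rows, cols] + rim + interior
  }
  if (spec$noise_sigma > 0)
    img <- withSeed(spec$seed,
      img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sigma), nr, nc))
  n <- length(spec$radii)
  regions <- if (n) data.frame(
    centroid_row = spec$centers[, 1], centroid_col = spec$centers[, 2],
    area_px = pi * spec$radii^2, radius_px = spec$radii,
    radius_um = spec$radii, eccentricity = 0,
    perimeter_px = 2 * pi * spec$radii)
  else data.frame()
  truth <- list(centers = spec$centers, radii = spec$radii,
                droplets = DropletSet(regions, imageId = "synthetic"))
  list(image = img, truth = truth, spec = spec)
}
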