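#' Specification for a synthetic FRAP movie
#'
#' Confocal-like movie of fluorescent droplets on a dark background.
#' Droplet fluorescence photobleaches biexponentially with rate constants
#' that vary linearly across the field (non-homogeneous illumination):
#' k1(x, y) = k1_0 + x alpha1 + y beta1 and likewise for k2, evaluated at
#' each droplet centroid (x = column, y = row). At \code{bleach_frame} the
#' pixels inside \code{bleach_roi} drop to the bleach floor
#' 1 - a - b and recover with the ground-truth biexponential
#' 1 - a exp(-k1 tau) - b exp(-k2 tau), multiplied by the local
#' photobleach decay.
#'
#' @param image_shape c(rows, cols)
#' @param n_frames number of frames
#' @param frame_interval seconds per frame
#' @param radii,centers droplet layout as in \code{\link{dropletFieldSpec}};
#'   \code{centers} may be NULL for seeded auto-placement
#' @param droplet_intensity fluorescence above background at t = 0
#' @param background camera offset
#' @param bleach_frame last pre-bleach frame index (1-based)
#' @param bleach_roi c(row1, row2, col1, col2); for line FRAP a 3-px-wide
#'   strip, for whole-droplet FRAP a box around one droplet
#' @param recovery_params named c(a, b, k1, k2); a + b is the bleach depth
#'   (floor = 1 - a - b), k's in 1/s
#' @param decay_params named list(a_mean, b_mean, k1_0, alpha1, beta1,
#'   k2_0, alpha2, beta2); a_mean + b_mean must equal 1
#' @param noise_sigma Gaussian camera noise sd
#' @param seed integer seed
#' @return A validated list of class \code{"frapSpec"}.
#' @export
frapSpec <- function(image_shape = c(144L, 144L), n_frames = 150L,
                     frame_interval = 1, radii = rep(9, 9), centers = NULL,
                     droplet_intensity = 100, background = 10,
                     bleach_frame = 10L,
                     bleach_roi = NULL,
                     recovery_params = c(a = 0.5, b = 0.3, k1 = 0.35,
                                         k2 = 0.04),
                     decay_params = list(a_mean = 0.7, b_mean = 0.3,
                                         k1_0 = 0.10, alpha1 = 1e-3,
                                         beta1 = 2e-3, k2_0 = 0.01,
                                         alpha2 = 2e-5, beta2 = 4e-5),
                     noise_sigma = 0.5, seed = 1L) {
  if (bleach_frame < 1 || bleach_frame >= n_frames)
    stop("bleach_frame must lie before the last frame")
  rp <- recovery_params
  if (any(rp[c("k1", "k2")] <= 0)) stop("recovery rate constants must be positive")
  if (rp[["a"]] < 0 || rp[["b"]] < 0 || rp[["a"]] + rp[["b"]] > 1)
    stop("recovery amplitudes must be non-negative with a + b <= 1")
  if (is.null(centers)) {
    centers <- if (length(radii) == 9 && is.null(centers)) {
      g <- round(seq(0.2, 0.8, length.out = 3) * image_shape[1])
      as.matrix(expand.grid(row = g, col = g))
    } else placeDroplets(image_shape, radii, 4, seed)
  }
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (is.null(bleach_roi)) {
    # default: box around the droplet closest to the field centre
    mid <- image_shape / 2
    i <- which.min(rowSums(sweep(centers, 2, mid)^2))
    r <- ceiling(radii[i]) + 2
    bleach_roi <- c(round(centers[i, 1]) - r, round(centers[i, 1]) + r,
                    round(centers[i, 2]) - r, round(centers[i, 2]) + r)
  }
  if (bleach_roi[1] < 1 || bleach_roi[3] < 1 ||
      bleach_roi[2] > image_shape[1] || bleach_roi[4] > image_shape[2])
    stop("bleach ROI outside image")
  dp <- decay_params
  if (abs(dp$a_mean + dp$b_mean - 1) > 1e-9)
    stop("decay amplitudes must sum to 1")
  # rates must stay positive over the whole field
  corners <- expand.grid(x = c(1, image_shape[2]), y = c(1, image_shape[1]))
  k1c <- dp$k1_0 + corners$x * dp$alpha1 + corners$y * dp$beta1
  k2c <- dp$k2_0 + corners$x * dp$alpha2 + corners$y * dp$beta2
  if (any(k1c <= 0) || any(k2c <= 0))
    stop("decay rates must be positive over the image domain")
  structure(list(image_shape = as.integer(image_shape),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, radii = radii,
                 centers = centers, droplet_intensity = droplet_intensity,
                 background = background,
                 bleach_frame = as.integer(bleach_frame),
                 bleach_roi = as.integer(round(bleach_roi)),
                 recovery_params = rp, decay_params = dp,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "frapSpec")
}

# Ground-truth normalized recovery curve at post-bleach times tau.
frapRecoveryCurve <- function(rp, tau) {
  1 - rp[["a"]] * exp(-rp[["k1"]] * tau) - rp[["b"]] * exp(-rp[["k2"]] * tau)
}

# Closed-form-free ground-truth half-recovery time: first tau where the
# recovery curve crosses halfway between its floor and plateau 1.
frapTrueHalfTime <- function(rp) {
  floorv <- 1 - rp[["a"]] - rp[["b"]]
  target <- floorv + (1 - floorv) / 2
  f <- function(tau) frapRecoveryCurve(rp, tau) - target
  upper <- 10 / min(rp[["k1"]], rp[["k2"]])
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Generate a synthetic FRAP movie with ground truth
#'
#' @param spec a \code{\link{frapSpec}}
#' @return List with \code{movie} (list of matrices), \code{truth} (list:
#'   \code{centers}, \code{radii}, \code{k1}, \code{k2} per droplet,
#'   \code{bleached_index}, \code{recovery_params}, \code{decay_params},
#'   \code{t_half}) and \code{spec}.
#' @export
genFrapMovie <- function(spec) {
  stopifnot(inherits(spec, "frapSpec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  dp <- spec$decay_params; rp <- spec$recovery_params
  nd <- length(spec$radii)
  # x = column, y = row of each droplet centroid
  kx <- spec$centers[, 2]; ky <- spec$centers[, 1]
  k1 <- dp$k1_0 + kx * dp$alpha1 + ky * dp$beta1
  k2 <- dp$k2_0 + kx * dp$alpha2 + ky * dp$beta2
  roi <- spec$bleach_roi
  roiMask <- matrix(FALSE, nr, nc)
  roiMask[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
  masks <- vector("list", nd)
  for (i in seq_len(nd)) {
    d <- sqrt(outer((seq_len(nr) - spec$centers[i, 1])^2,
                    (seq_len(nc) - spec$centers[i, 2])^2, "+"))
    masks[[i]] <- d <= spec$radii[i]
  }
  # droplet hit by the bleach ROI (largest pixel overlap)
  overlap <- vapply(masks, function(m) sum(m & roiMask), numeric(1))
  bleachedIndex <- if (any(overlap > 0)) which.max(overlap) else NA_integer_
  t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  tb <- t[spec$bleach_frame + 1L]  # time of the first post-bleach frame
  movie <- lapply(seq_len(spec$n_frames), function(fi) {
    f <- matrix(spec$background, nr, nc)
    for (i in seq_len(nd)) {
      decay <- dp$a_mean * exp(-k1[i] * t[fi]) +
        dp$b_mean * exp(-k2[i] * t[fi])
      val <- spec$droplet_intensity * decay
      m <- masks[[i]]
      if (!is.na(bleachedIndex) && i == bleachedIndex &&
          fi > spec$bleach_frame) {
        rec <- frapRecoveryCurve(rp, t[fi] - tb)
        f[m & roiMask] <- spec$background + val * rec
        f[m & !roiMask] <- spec$background + val
      } else {
        f[m] <- spec$background + val
      }
    }
    f
  })
  if (spec$noise_sigma > 0)
    movie <- withSeed(spec$seed, lapply(movie, function(f)
      f + matrix(stats::rnorm(length(f), sd = spec$noise_sigma),
                 nrow(f), ncol(f))))
  truth <- list(centers = spec$centers, radii = spec$radii, k1 = k1, k2 = k2,
                bleached_index = bleachedIndex,
                recovery_params = rp, decay_params = dp,
                t_half = frapTrueHalfTime(rp), time = t,
                bleach_time = tb)
  list(movie = movie, truth = truth, spec = spec)
}

#' Generate synthetic FRAP traces without rendering a movie
#'
#' Trace-level counterpart of \code{\link{genFrapMovie}} for fast
#' parameter-recovery studies: returns the bleached-ROI trace and the
#' per-droplet unbleached decay traces directly, with multiplicative
#' structure identical to the movie generator and i.i.d. Gaussian noise.
#'
#' @param spec a \code{\link{frapSpec}}
#' @return List with \code{trace} (\linkS4class{FrapTrace}) and
#'   \code{truth} as in \code{\link{genFrapMovie}}.
#' @export
genFrapTraces <- function(spec) {
  stopifnot(inherits(spec, "frapSpec"))
  dp <- spec$decay_params; rp <- spec$recovery_params
  kx <- spec$centers[, 2]; ky <- spec$centers[, 1]
  k1 <- dp$k1_0 + kx * dp$alpha1 + ky * dp$beta1
  k2 <- dp$k2_0 + kx * dp$alpha2 + ky * dp$beta2
  t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  tb <- t[spec$bleach_frame + 1L]
  nd <- length(spec$radii)
  mid <- spec$image_shape / 2
  bleachedIndex <- which.min(rowSums(sweep(spec$centers, 2, mid)^2))
  decay <- function(i) dp$a_mean * exp(-k1[i] * t) + dp$b_mean * exp(-k2[i] * t)
  unb <- vapply(setdiff(seq_len(nd), bleachedIndex), function(i)
    spec$background + spec$droplet_intensity * decay(i),
    numeric(length(t)))
  rec <- ifelse(t > t[spec$bleach_frame],
                frapRecoveryCurve(rp, pmax(t - tb, 0)), 1)
  ifrap <- spec$background +
    spec$droplet_intensity * decay(bleachedIndex) * rec
  if (spec$noise_sigma > 0) {
    noisy <- withSeed(spec$seed, {
      list(ifrap = ifrap + stats::rnorm(length(t), sd = spec$noise_sigma),
           unb = unb + matrix(stats::rnorm(length(unb),
                                           sd = spec$noise_sigma),
                              nrow(unb), ncol(unb)))
    })
    ifrap <- noisy$ifrap; unb <- noisy$unb
  }
  keep <- setdiff(seq_len(nd), bleachedIndex)
  trace <- FrapTrace(time = t, iFrap = ifrap, iUnbleached = unb,
                     iBackground = spec$background,
                     bleachFrame = spec$bleach_frame,
                     centroids = cbind(x = kx[keep], y = ky[keep]),
                     bleachCentroid = c(kx[bleachedIndex],
                                        ky[bleachedIndex]))
  truth <- list(centers = spec$centers, radii = spec$radii,
                k1 = k1, k2 = k2, bleached_index = bleachedIndex,
                recovery_params = rp, decay_params = dp,
                t_half = frapTrueHalfTime(rp), time = t, bleach_time = tb)
  list(trace = trace, truth = truth, spec = spec)
}
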