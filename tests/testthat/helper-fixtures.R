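# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# Kymogram spec whose compaction finishes exactly at the last frame
# (end_start - 1 divisible by v), which makes the conservation statistic
# match its closed form without a discretisation kink at the clamp.
fullCompactionSpec <- function(..., seed = 1L) {
  kymogramSpec(n_frames = 101L, n_pixels = 256L, end_start = 201L,
               compaction_rate_v = 2, seed = seed, ...)
}

# Two-scale droplet fixture: a small sharp ring plus a large faint broad
# ring in noise, constructed so that Canny at sigma 1 finds only the
# small droplet, sigma 4 only the large one, and their combination both.
twoScaleDropletFixture <- function(seed = 5L) {
  sp1 <- dropletFieldSpec(image_shape = c(128, 128), radii = 3,
                          centers = matrix(c(40, 40), 1),
                          edge_ring_contrast = 1.2, ring_width = 0.7,
                          noise_sigma = 0, seed = seed)
  sp2 <- dropletFieldSpec(image_shape = c(128, 128), radii = 15,
                          centers = matrix(c(85, 85), 1),
                          edge_ring_contrast = 0.12, ring_width = 5,
                          noise_sigma = 0, seed = seed)
  img <- genDropletImage(sp1)$image + genDropletImage(sp2)$image - 1
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(128 * 128, sd = 0.10), 128, 128))
  list(image = img + noise,
       centers = matrix(c(40, 40, 85, 85), 2, byrow = TRUE),
       radii = c(3, 15))
}

# Ideal biexponential recovery series with Gaussian noise.
recoverySeries <- function(time, a, b, k1, k2, noise = 0, seed = 1L) {
  y <- 1 - a * exp(-k1 * time) - b * exp(-k2 * time)
  if (noise > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(time), sd = noise))
  y
}

# Pooled segmentation score of noiseless synthetic fields over seeds.
pooledSegmentationScore <- function(seeds, radii = c(3, 4, 5, 6, 8, 10, 12, 16),
                                    noise_sigma = 0) {
  hits <- 0; nTruth <- 0; nDet <- 0
  for (s in seeds) {
    sp <- dropletFieldSpec(image_shape = c(256, 256), radii = radii,
                           noise_sigma = noise_sigma, seed = s)
    im <- genDropletImage(sp)
    ds <- segmentDroplets(im$image)
    sc <- matchDroplets(im$truth$centers, im$truth$radii, ds)
    hits <- hits + sc$nMatched
    nTruth <- nTruth + length(radii)
    nDet <- nDet + length(ds)
  }
  list(recall = hits / nTruth, precision = hits / nDet)
}
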