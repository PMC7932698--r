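#' Run configuration
#'
#' Flat, JSON-serializable container of acquisition metadata and module
#' parameter blocks. Every pipeline run writes its resolved configuration
#' beside its outputs, which is enough provenance to re-execute the run.
#'
#' @param pixel_size micrometres per pixel
#' @param frame_interval seconds per frame
#' @param seed integer seed forwarded to every stochastic step
#' @param tracking list of \code{\link{trackingParams}} overrides
#' @param segmentation list: sigmas, low, high, cutoff_frac, areaMin,
#'   eccMax
#' @param frap list: excludeFactor, erodePx
#' @param wlc list of \code{\link{wlcParams}} overrides
#' @param ... further fields stored verbatim
#' @return List of class \code{"runConfig"}.
#' @export
runConfig <- function(pixel_size = 0.16, frame_interval = 0.1, seed = 1L,
                      tracking = list(), segmentation = list(),
                      frap = list(), wlc = list(), ...) {
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 seed = as.integer(seed), tracking = tracking,
                 segmentation = segmentation, frap = frap, wlc = wlc, ...),
            class = "runConfig")
}

#' Read or write a run configuration as JSON
#'
#' @param path JSON file
#' @return \code{readRunConfig}: a \code{"runConfig"} list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, cfg)
}

#' @rdname readRunConfig
#' @param config a \code{"runConfig"} list
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

writeProvenance <- function(outdir, stage, config, extra = list()) {
  rec <- c(list(stage = stage,
                package = "CondensateKit",
                version = as.character(utils::packageVersion("CondensateKit")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = unclass(config)), extra)
  jsonlite::write_json(rec, file.path(outdir,
                                      sprintf("%s_provenance.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

writeJsonNum <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Execute one pipeline stage
#'
#' Orchestration entry point behind the command-line interface. Each
#' stage reads its inputs, runs the corresponding module functions with
#' parameters from \code{config}, writes CSV/JSON outputs plus a
#' provenance record into \code{outdir}, and returns its results
#' invisibly.
#'
#' Stages: \code{simulate} (write synthetic fixtures), \code{track}
#' (movie -> kymogram -> end track -> compaction fit), \code{kinetics}
#' (kymogram + track -> segment traces, conservation, kappa),
#' \code{droplets} (images -> segmentation -> CCD -> power law),
#' \code{frap} (movie -> traces -> fits/correction), \code{force}
#' (curves CSV -> energy, deficits, ruptures).
#'
#' @param stage stage name (see Details)
#' @param config a \code{\link{runConfig}}
#' @param inputs named list of input paths/objects; stage-specific
#' @param outdir output directory (created if needed)
#' @return Stage results, invisibly.
#' @export
runStage <- function(stage, config = runConfig(), inputs = list(),
                     outdir = ".") {
  stages <- c("simulate", "track", "kinetics", "droplets", "frap", "force")
  if (!stage %in% stages)
    stop(sprintf("unknown stage '%s'; available: %s", stage,
                 paste(stages, collapse = ", ")))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(outdir, paste0(stage, "_config.json")))
  res <- switch(stage,
    simulate = stageSimulate(config, outdir),
    track = stageTrack(config, inputs, outdir),
    kinetics = stageKinetics(config, inputs, outdir),
    droplets = stageDroplets(config, inputs, outdir),
    frap = stageFrap(config, inputs, outdir),
    force = stageForce(config, inputs, outdir))
  writeProvenance(outdir, stage, config)
  invisible(res)
}

stageSimulate <- function(config, outdir) {
  seed <- config$seed
  kspec <- kymogramSpec(seed = seed, noise_sigma = 5)
  mv <- genCurtainMovie(kspec, strand_cols = c(20L, 40L))
  writeImageStack(mv$movie, file.path(outdir, "curtain_movie.tif"))
  dspec <- dropletFieldSpec(radii = c(4, 6, 8, 10, 14), noise_sigma = 0.01,
                            seed = seed)
  di <- genDropletImage(dspec)
  writeImageStack(di$image, file.path(outdir, "droplet_field.tif"))
  fspec <- frapSpec(seed = seed)
  fm <- genFrapMovie(fspec)
  writeImageStack(fm$movie, file.path(outdir, "frap_movie.tif"))
  fe <- genForceExtension(forceExtensionSpec(
    noise_sigma = 0.1, seed = seed,
    extra_force_offset = list(type = "gaussian", amplitude = 3,
                              center = 8, width = 2)))
  writeForceExtensionCsv(list(fe$bare, fe$hp1),
                         file.path(outdir, "force_extension.csv"))
  truth <- list(
    kymogram = list(v = mv$truth$v, kappa = mv$truth$kappa,
                    strand_cols = mv$truth$strand_cols),
    droplets = list(radii = di$truth$radii,
                    centers = apply(di$truth$centers, 1, paste,
                                    collapse = ",")),
    frap = as.list(fm$truth$recovery_params),
    force = list(area = fe$truth$area,
                 compacted_bp = fe$truth$compacted_bp))
  writeJsonNum(truth, file.path(outdir, "simulate_truth.json"))
  invisible(list(kymogram = mv, droplets = di, frap = fm, force = fe))
}

stageTrack <- function(config, inputs, outdir) {
  movie <- if (!is.null(inputs$movie_path))
    readImageStack(inputs$movie_path) else inputs$movie
  if (is.null(movie)) stop("track stage needs inputs$movie or movie_path")
  cols <- findStrands(movie[[1]])
  if (!length(cols)) stop("no strands detected")
  tp <- do.call(trackingParams, config$tracking)
  out <- lapply(cols, function(cc) {
    kym <- extractKymogram(movie, cc, frameInterval = config$frame_interval,
                           pixelSize = config$pixel_size)
    track <- trackDnaEnd(kym, tp)
    fit <- fitCompactionRate(track, kym)
    writeEndTrack(track, file.path(outdir, sprintf("endtrack_col%d.csv", cc)),
                  frameInterval = config$frame_interval)
    list(column = cc, kymogram = kym, track = track, fit = fit)
  })
  summary <- lapply(out, function(o) list(
    column = o$column,
    rate_px_per_frame = o$fit@ratePxPerFrame,
    rate_um_per_s = o$fit@rateUmPerS,
    n_accepted = o$fit@nAccepted,
    residual_sd_px = o$fit@residualSd))
  writeJsonNum(summary, file.path(outdir, "compaction_fits.json"))
  out
}

stageKinetics <- function(config, inputs, outdir) {
  kym <- inputs$kymogram
  track <- inputs$track
  if (is.null(kym) || is.null(track))
    stop("kinetics stage needs inputs$kymogram and inputs$track")
  # margin covers the tracker's smoothing-induced end offset
  trace <- computeSegmentTrace(kym, track, punctumMargin = 2L)
  cons <- yoyoConservation(trace)
  kap <- fitUncompactedDensityRate(trace)
  norm <- normalizedCompactedIntensity(trace)
  utils::write.csv(data.frame(
    time_s = trace@time, Iu = trace@Iu, Ic = trace@Ic, rho = trace@rho,
    lc_px = trace@lc, conservation = cons, normalized_Ic = norm),
    file.path(outdir, "segment_traces.csv"), row.names = FALSE)
  writeJsonNum(list(kappa_per_frame = kap$kappa,
                    kappa_per_s = kap$kappa_per_s,
                    r_squared = kap$r_squared,
                    mean_normalized_Ic = mean(norm, na.rm = TRUE)),
               file.path(outdir, "kinetics_summary.json"))
  list(trace = trace, conservation = cons, kappa = kap,
       normalized = norm)
}

stageDroplets <- function(config, inputs, outdir) {
  paths <- inputs$image_paths
  images <- if (!is.null(paths)) lapply(paths, function(p)
    readImageStack(p)[[1]]) else inputs$images
  if (is.null(images)) stop("droplets stage needs images")
  sg <- config$segmentation
  getp <- function(name, default) if (is.null(sg[[name]])) default else
    sg[[name]]
  sets <- lapply(seq_along(images), function(i)
    segmentDroplets(images[[i]], pixelSize = config$pixel_size,
                    sigmas = getp("sigmas", c(1, 2, 4, 8)),
                    low = getp("low", 0.08), high = getp("high", 0.2),
                    cutoff_frac = getp("cutoff_frac", 0.02),
                    areaMin = getp("areaMin", 3),
                    eccMax = getp("eccMax", 0.94),
                    imageId = sprintf("image%d", i)))
  pooled <- unlist(lapply(sets, radii))
  regions <- do.call(rbind, lapply(sets, dropletRegions))
  utils::write.csv(regions, file.path(outdir, "droplet_regions.csv"),
                   row.names = FALSE)
  dist <- if (length(pooled)) radiusCcd(pooled, seed = config$seed) else NULL
  if (!is.null(dist))
    utils::write.csv(data.frame(r = dist@grid, ccd = dist@ccd,
                                ci_lo = dist@ciLo, ci_hi = dist@ciHi),
                     file.path(outdir, "radius_ccd.csv"), row.names = FALSE)
  writeJsonNum(list(n_droplets = length(pooled),
                    expected_radius = if (is.null(dist)) NA else
                      dist@expectedRadius),
               file.path(outdir, "droplet_summary.json"))
  list(sets = sets, distribution = dist)
}

stageFrap <- function(config, inputs, outdir) {
  movie <- if (!is.null(inputs$movie_path))
    readImageStack(inputs$movie_path) else inputs$movie
  if (is.null(movie) || is.null(inputs$roi) || is.null(inputs$bleach_frame))
    stop("frap stage needs movie, roi and bleach_frame")
  excl <- if (is.null(config$frap$excludeFactor)) 3 else
    config$frap$excludeFactor
  trace <- extractFrapTraces(movie, inputs$roi, inputs$bleach_frame,
                             frameInterval = config$frame_interval,
                             excludeFactor = excl)
  mode <- if (is.null(inputs$mode)) "whole" else inputs$mode
  if (mode == "line") {
    norm <- normalizeLineFrap(trace)
    fit <- fitBiexponential(norm, trace@time,
                            bleachFrame = trace@bleachFrame)
    utils::write.csv(data.frame(time_s = trace@time, normalized = norm),
                     file.path(outdir, "frap_normalized.csv"),
                     row.names = FALSE)
    res <- list(trace = trace, normalized = norm, fit = fit)
  } else {
    model <- fitSpatialDecay(trace)
    corr <- correctWholeDropFrap(trace, model)
    fit <- fitBiexponential(corr$corrected, trace@time,
                            bleachFrame = trace@bleachFrame)
    utils::write.csv(data.frame(time_s = corr$time,
                                corrected = corr$corrected),
                     file.path(outdir, "frap_corrected.csv"),
                     row.names = FALSE)
    res <- list(trace = trace, model = model, corrected = corr, fit = fit)
  }
  writeJsonNum(list(a = res$fit@a, b = res$fit@b, k1 = res$fit@k1,
                    k2 = res$fit@k2, t_half_s = res$fit@tHalf,
                    converged = res$fit@converged),
               file.path(outdir, "frap_fit.json"))
  res
}

stageForce <- function(config, inputs, outdir) {
  curves <- if (!is.null(inputs$curves_path))
    readForceExtensionCsv(inputs$curves_path) else inputs$curves
  if (is.null(curves) || length(curves) < 2L)
    stop("force stage needs a bare and a protein-bound curve")
  bare <- curves[[1]]; hp1 <- curves[[2]]
  atForce <- if (is.null(inputs$at_force)) 20 else inputs$at_force
  totalBp <- if (is.null(inputs$total_bp)) 48502 else inputs$total_bp
  bp <- tryCatch(compactedLengthFromDeficit(bare, hp1, atForce, totalBp),
                 error = function(e) NA_real_)
  compactedBp <- if (!is.null(inputs$compacted_bp)) inputs$compacted_bp
                 else if (is.finite(bp) && bp > 0) bp else NA_real_
  energy <- if (is.finite(compactedBp))
    energyBetweenCurves(bare, hp1, compactedBp) else NULL
  rupt <- detectRuptures(hp1)
  writeJsonNum(list(
    area_pN_um = if (is.null(energy)) NA else energy@area,
    energy_kBT_per_bp = if (is.null(energy)) NA else energy@energyPerBp,
    compacted_bp = compactedBp,
    deficit_query_force_pN = atForce,
    n_ruptures = nrow(rupt)),
    file.path(outdir, "force_summary.json"))
  list(energy = energy, compacted_bp = compactedBp, ruptures = rupt)
}

#' End-to-end demonstration on synthetic data
#'
#' Generates every synthetic fixture with one seed and runs all pipeline
#' stages on them: strand tracking and compaction-rate fitting, binding
#' kinetics, droplet segmentation with radius statistics, whole-droplet
#' FRAP with photobleach correction, and the force-extension energy
#' analysis. Outputs (CSV/JSON plus provenance) land in \code{outdir}.
#' Re-running with the same seed reproduces every output byte for byte.
#'
#' @param seed integer seed
#' @param outdir output directory
#' @return Named list with each stage's results, invisibly.
#' @export
runDemo <- function(seed = 1L, outdir = tempfile("condensate-demo")) {
  config <- runConfig(seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- runStage("simulate", config, outdir = file.path(outdir, "simulate"))
  trackRes <- runStage("track", config,
                       inputs = list(movie = sim$kymogram$movie),
                       outdir = file.path(outdir, "track"))
  kin <- runStage("kinetics", config,
                  inputs = list(kymogram = trackRes[[1]]$kymogram,
                                track = trackRes[[1]]$track),
                  outdir = file.path(outdir, "kinetics"))
  cfgD <- config; cfgD$pixel_size <- 1
  drop <- runStage("droplets", cfgD,
                   inputs = list(images = list(sim$droplets$image)),
                   outdir = file.path(outdir, "droplets"))
  cfgF <- config; cfgF$frame_interval <- sim$frap$spec$frame_interval
  # synthetic droplets carry no bleach spillover, so only immediate
  # neighbours of the ROI need excluding
  cfgF$frap <- list(excludeFactor = 0.6)
  frap <- runStage("frap", cfgF,
                   inputs = list(movie = sim$frap$movie,
                                 roi = sim$frap$spec$bleach_roi,
                                 bleach_frame = sim$frap$spec$bleach_frame,
                                 mode = "whole"),
                   outdir = file.path(outdir, "frap"))
  forceRes <- runStage("force", config,
                       inputs = list(curves = list(sim$force$bare,
                                                   sim$force$hp1),
                                     compacted_bp = sim$force$truth$compacted_bp),
                       outdir = file.path(outdir, "force"))
  invisible(list(simulate = sim, track = trackRes, kinetics = kin,
                 droplets = drop, frap = frap, force = forceRes,
                 outdir = outdir))
}
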