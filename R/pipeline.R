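.pipelineStages <- c("simulate", "absorbance", "calibrate", "reconstruct",
                     "profile", "wells", "classify")

.need <- function(stage, params, fields) {
  missing <- fields[!fields %in% names(params)]
  if (length(missing))
    stop("stage '", stage, "': missing config field(s): ",
         paste(missing, collapse = ", "))
}

.featureFromList <- function(f) {
  extra <- f[setdiff(names(f), c("kind", "center", "r", "d"))]
  do.call(FeatureSpec, c(list(kind = f$kind,
                              center = unlist(f$center),
                              r = f$r, d = f$d), extra))
}

#' Run the profilometry pipeline from a configuration
#'
#' Executes the configured subset of stages, in order: `simulate`
#' (forward-model a layout into one or more 16-bit scans plus a blank
#' reference), `absorbance` (sample vs blank, one channel, averaging over
#' repeat scans), `calibrate` (fit a calibration series CSV), `reconstruct`
#' (absorbance to depth via an epsilon or a fit file), `profile`
#' (longitudinal cross-sections to CSV), `wells` (segment, measure,
#' CSV report) and `classify` (k-means typing of a wells CSV). Each stage
#' reads its inputs from the paths the config names, so stages can also be
#' run in separate invocations. A manifest JSON recording inputs, outputs,
#' seeds and MD5 checksums of every artifact is written at the end; rerun
#' with the same config and seeds, it is reproduced byte-identically.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Top-level keys are stage names; values are stage parameter lists.
#' @param base_dir directory relative paths resolve against (default: the
#'   config file's directory, or `"."` for a list config).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, the manifest list (also written to
#'   `config$manifest`, default `manifest.json` under `base_dir`).
#' @export
runPipeline <- function(config, base_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c(.pipelineStages, "manifest"))
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  rp <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p
                    else file.path(base_dir, p)
  say <- function(...) if (!quiet) message(...)
  artifacts <- character(0)
  manifest <- list(stages = list())

  if (!is.null(config$simulate)) {
    p <- config$simulate
    .need("simulate", p, c("layout", "extent_um", "out_prefix"))
    say("simulate: rendering ", length(p$layout), " feature(s)")
    cfg <- ScanSimConfig(
      dpi = p$dpi %||% 12800, i0 = p$i0 %||% 60000,
      noise_sd = p$noise_sd %||% 100,
      eps_R = p$eps_R %||% 0, eps_G = p$eps_G %||% 0.00026,
      eps_B = p$eps_B %||% 0.00052, conc = p$conc %||% 6,
      seed = p$seed %||% 1)
    feats <- lapply(p$layout, .featureFromList)
    field <- renderDepthField(feats, unlist(p$extent_um),
                              pitchFromDpi(cfg@dpi))
    n_scans <- p$n_scans %||% 1
    paths <- character(0)
    for (s in seq_len(n_scans)) {
      cfg_s <- cfg
      cfg_s@seed <- as.integer(cfg@seed + s - 1L)
      out <- rp(sprintf("%s_scan%02d.tiff", p$out_prefix, s))
      writeScan(simulateScan(field, cfg_s), out)
      paths <- c(paths, out)
    }
    blank <- renderDepthField(list(), unlist(p$extent_um),
                              pitchFromDpi(cfg@dpi))
    cfg_b <- cfg
    cfg_b@seed <- as.integer(cfg@seed + n_scans)
    blank_path <- rp(sprintf("%s_blank.tiff", p$out_prefix))
    writeScan(simulateScan(blank, cfg_b), blank_path)
    truth_path <- rp(sprintf("%s_truth.json", p$out_prefix))
    jsonlite::write_json(
      list(features = p$layout, seed = cfg@seed,
           conc_mM = cfg@conc, dpi = cfg@dpi, i0 = cfg@i0,
           noise_sd = cfg@noise_sd, eps = as.list(cfg@eps),
           true_volumes_nL = vapply(feats, featureVolume,
                                    numeric(1)) / UM3_PER_NL),
      truth_path, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, paths, blank_path, truth_path,
                   .sidecarPath(paths), .sidecarPath(blank_path))
    manifest$stages$simulate <- list(scans = paths, blank = blank_path,
                                     truth = truth_path, seed = cfg@seed)
  }

  if (!is.null(config$absorbance)) {
    p <- config$absorbance
    .need("absorbance", p, c("sample", "reference", "out"))
    ch <- p$channel %||% "B"
    say("absorbance: ", length(p$sample), " scan(s), channel ", ch)
    ref <- readScan(rp(p$reference))
    maps <- lapply(p$sample, function(s)
      computeAbsorbance(readScan(rp(s)), ref, channel = ch))
    amap <- if (length(maps) > 1L)
      averageScans(maps, align = p$align %||% "none") else maps[[1]]
    out <- rp(p$out)
    writeFloatMap(amap, out)
    artifacts <- c(artifacts, out, .sidecarPath(out))
    manifest$stages$absorbance <- list(out = out, channel = ch,
                                       n_scans = length(maps))
  }

  if (!is.null(config$calibrate)) {
    p <- config$calibrate
    .need("calibrate", p, c("series", "out"))
    say("calibrate: fitting ", p$series)
    fit <- fitSeries(readCalibrationSeries(rp(p$series)),
                     weighted = isTRUE(p$weighted))
    out <- rp(p$out)
    writeCalibrationFit(fit, out)
    artifacts <- c(artifacts, out)
    manifest$stages$calibrate <- list(out = out, epsilon = fit@epsilon,
                                      r_squared = fit@r_squared)
  }

  if (!is.null(config$reconstruct)) {
    p <- config$reconstruct
    .need("reconstruct", p, c("absorbance", "conc", "out"))
    if (is.null(p$epsilon) && is.null(p$fit))
      stop("stage 'reconstruct': supply either 'epsilon' or a 'fit' path ",
           "(no calibration available)")
    say("reconstruct: inverting ", p$absorbance)
    amap <- readAbsorbanceMap(rp(p$absorbance))
    dmap <- if (!is.null(p$fit))
      reconstructDepth(amap, conc = p$conc,
                       fit = readCalibrationFit(rp(p$fit)))
    else reconstructDepth(amap, epsilon = p$epsilon, conc = p$conc)
    out <- rp(p$out)
    writeFloatMap(dmap, out)
    artifacts <- c(artifacts, out, .sidecarPath(out))
    manifest$stages$reconstruct <- list(out = out,
                                        epsilon = dmap@provenance$epsilon,
                                        conc_mM = p$conc)
  }

  if (!is.null(config$profile)) {
    p <- config$profile
    .need("profile", p, c("depth", "axis", "out"))
    say("profile: ", p$n_slices %||% 16, " slices")
    dmap <- readDepthMap(rp(p$depth))
    ax <- unlist(p$axis)
    lp <- longitudinalProfile(dmap, ax[1:2], ax[3:4],
                              n_slices = p$n_slices %||% 16,
                              halfwidth_um = p$halfwidth_um)
    long <- do.call(rbind, lapply(seq_along(lp$slices), function(i)
      cbind(slice_index = i,
            axis_position_um = attr(lp$slices[[i]], "axis_position_um"),
            lp$slices[[i]])))
    out <- rp(p$out)
    utils::write.csv(long, out, row.names = FALSE)
    artifacts <- c(artifacts, out)
    manifest$stages$profile <- list(out = out,
                                    n_slices = length(lp$slices))
  }

  if (!is.null(config$wells)) {
    p <- config$wells
    .need("wells", p, c("depth", "out"))
    say("wells: segmenting ", p$depth)
    dmap <- readDepthMap(rp(p$depth))
    fs <- segmentFeatures(dmap, min_depth = p$min_depth,
                          min_area_px = p$min_area_px %||% 10)
    pop <- measureWells(dmap, fs)
    out <- rp(p$out)
    writeWells(pop, out)
    s <- summarizeWells(pop)
    artifacts <- c(artifacts, out)
    manifest$stages$wells <- list(out = out, n_wells = s$n,
                                  mean_nL = s$mean, sd_nL = s$sd,
                                  cov_pct = s$cov_report)
  }

  if (!is.null(config$classify)) {
    p <- config$classify
    .need("classify", p, c("wells", "k", "out"))
    say("classify: k = ", p$k)
    pop <- readWells(rp(p$wells))
    pop <- kmeansClassify(pop, k = p$k, seed = p$seed %||% 1,
                          n_restarts = p$n_restarts %||% 10)
    out <- rp(p$out)
    writeWells(pop, out)
    manifest$stages$classify <- list(out = out, k = p$k,
                                     seed = p$seed %||% 1)
    artifacts <- c(artifacts, out)
  }

  if (!length(manifest$stages)) stop("config enables no pipeline stage")
  manifest$checksums <- as.list(tools::md5sum(sort(unique(artifacts))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  mpath <- rp(config$manifest %||% "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  say("manifest written to ", mpath)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
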