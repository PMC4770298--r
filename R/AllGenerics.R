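#' Physical pixel pitch in micrometres
#'
#' The centre-to-centre pixel spacing of the object's raster grid, derived
#' from the scan resolution for a [ScanImage-class] (`25400/dpi`) or stored
#' directly for maps and fields.
#'
#' @param x a ScanImage, AbsorbanceMap, DepthField or DepthMap.
#' @return pixel pitch in micrometres.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @describeIn pixelPitch pitch from the scan dpi.
#' @export
setMethod("pixelPitch", "ScanImage", function(x) UM_PER_INCH / x@dpi)

#' @describeIn pixelPitch stored pitch.
#' @export
setMethod("pixelPitch", "AbsorbanceMap", function(x) x@pitch)

#' @describeIn pixelPitch stored pitch.
#' @export
setMethod("pixelPitch", "DepthField", function(x) x@pitch)

#' @describeIn pixelPitch stored pitch.
#' @export
setMethod("pixelPitch", "DepthMap", function(x) x@pitch)

#' Pixel pitch implied by a scan resolution
#'
#' @param dpi scan resolution in dots per inch.
#' @return pitch in micrometres per pixel, `25400/dpi`.
#' @examples
#' pitchFromDpi(12800)  # ~2 um per pixel
#' @export
pitchFromDpi <- function(dpi) {
  stopifnot(is.numeric(dpi), all(dpi > 0))
  UM_PER_INCH / dpi
}

#' Raw count data of a scan
#' @param x a ScanImage.
#' @return numeric rows x cols x 3 array of 16-bit counts.
#' @export
setGeneric("scanData", function(x) standardGeneric("scanData"))

#' @rdname scanData
#' @export
setMethod("scanData", "ScanImage", function(x) x@data)

#' Scan resolution in dpi
#' @param x a ScanImage.
#' @return dots per inch.
#' @export
setGeneric("scanDpi", function(x) standardGeneric("scanDpi"))

#' @rdname scanDpi
#' @export
setMethod("scanDpi", "ScanImage", function(x) x@dpi)

#' Absorbance matrix of an AbsorbanceMap
#' @param x an AbsorbanceMap.
#' @return numeric matrix of log10 absorbance.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname absorbance
#' @export
setMethod("absorbance", "AbsorbanceMap", function(x) x@absorbance)

#' Depth matrix in micrometres
#' @param x a DepthField or DepthMap.
#' @return numeric matrix of depths.
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))

#' @rdname depthMatrix
#' @export
setMethod("depthMatrix", "DepthField", function(x) x@depth)

#' @rdname depthMatrix
#' @export
setMethod("depthMatrix", "DepthMap", function(x) x@depth)

#' Validity mask
#' @param x an AbsorbanceMap or DepthMap.
#' @return logical matrix, TRUE where the value is computable.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname validMask
#' @export
setMethod("validMask", "AbsorbanceMap", function(x) x@mask)

#' @rdname validMask
#' @export
setMethod("validMask", "DepthMap", function(x) x@mask)

#' Per-region morphometrics table
#' @param x a FeatureSet.
#' @return data.frame, one row per segmented region.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname featureTable
#' @export
setMethod("featureTable", "FeatureSet", function(x) x@table)

#' Per-well records of a population
#' @param x a WellPopulation.
#' @return data.frame, one row per well.
#' @export
setGeneric("wellTable", function(x) standardGeneric("wellTable"))

#' @rdname wellTable
#' @export
setMethod("wellTable", "WellPopulation", function(x) x@wells)

setMethod("show", "ScanImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScanImage: %d x %d px, 3 channels, %g dpi (pitch %.3f um)\n",
              d[1], d[2], object@dpi, pixelPitch(object)))
  cat(sprintf("  counts in [%g, %g]\n", min(object@data), max(object@data)))
})

setMethod("show", "AbsorbanceMap", function(object) {
  d <- dim(object@absorbance)
  cat(sprintf(
    "AbsorbanceMap (%s channel): %d x %d px, pitch %.3f um, %d invalid px\n",
    object@channel, d[1], d[2], object@pitch, sum(!object@mask)))
  a <- object@absorbance[object@mask]
  if (length(a))
    cat(sprintf("  A in [%.4f, %.4f]\n", min(a), max(a)))
})

setMethod("show", "DepthField", function(object) {
  d <- dim(object@depth)
  cat(sprintf("DepthField: %d x %d px, pitch %.3f um, depth up to %.2f um\n",
              d[1], d[2], object@pitch, max(object@depth)))
})

setMethod("show", "DepthMap", function(object) {
  d <- dim(object@depth)
  v <- object@depth[object@mask]
  cat(sprintf("DepthMap: %d x %d px, pitch %.3f um, %d invalid px\n",
              d[1], d[2], object@pitch, sum(!object@mask)))
  if (length(v))
    cat(sprintf("  depth in [%.2f, %.2f] um (%d negative px retained)\n",
                min(v), max(v), sum(v < 0)))
  pr <- object@provenance
  if (length(pr))
    cat(sprintf("  provenance: eps=%s, c=%s mM, channel=%s, N=%s scans\n",
                format(pr$epsilon), format(pr$conc_mM),
                format(pr$channel), format(pr$n_scans)))
})

setMethod("show", "FeatureSpec", function(object) {
  cat(sprintf("FeatureSpec: %s at (%.1f, %.1f) um, r=%.1f um, d=%.2f um\n",
              object@kind, object@center[1], object@center[2],
              object@r, object@d))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit (%s): epsilon=%.3g mM^-1 um^-1 (%s), R^2=%.5f\n",
    object@channel, object@epsilon,
    if (object@valid) "valid" else "INVALID", object@r_squared))
  cat(sprintf("  slope=%.4g, intercept=%.4g\n",
              object@slope, object@intercept))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d regions, threshold %.3f um, pitch %.3f um\n",
              nrow(object@table), object@threshold, object@pitch))
})

setMethod("show", "WellPopulation", function(object) {
  s <- summarizeWells(object)
  cat(sprintf("WellPopulation: %d wells\n", s$n))
  cat(sprintf("  volume mean %.4f nL, sd %.4f nL, CoV %s%%\n",
              s$mean, s$sd, format(s$cov_report)))
  if (!is.null(object@wells$cluster))
    cat(sprintf("  clusters: %s\n",
                paste(names(table(object@wells$cluster)),
                      table(object@wells$cluster),
                      sep = ":", collapse = " ")))
})
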