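.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Construct a ScanImage from a count array
#'
#' @param data numeric rows x cols x 3 array of counts in `[0, 65535]`.
#' @param dpi scan resolution, dots per inch.
#' @param metadata optional named list.
#' @return a [ScanImage-class].
#' @export
ScanImage <- function(data, dpi, metadata = list()) {
  new("ScanImage", data = data, dpi = dpi, metadata = metadata)
}

#' Read a 16-bit RGB scanner image
#'
#' Loads a single-page TIFF as written by the scanner (or by
#' [writeScan()]). 16-bit three-channel images are expected; 8-bit images
#' are accepted with a warning and upscaled by 257 so that full scale maps
#' to 65535. The resolution is taken, in order of increasing precedence,
#' from the TIFF resolution tags, from a JSON sidecar written next to the
#' image, and from the explicit `dpi` argument.
#'
#' @param path path to the TIFF file.
#' @param dpi optional explicit resolution override, dots per inch.
#' @return a [ScanImage-class].
#' @export
readScan <- function(path, dpi = NULL) {
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e)
                    stop("not a readable TIFF image: ", path, " (",
                         conditionMessage(e), ")"))
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected a 3-channel RGB image, got ",
         if (length(dim(img)) == 2L) "1" else dim(img)[3], " channel(s)")
  bits <- attr(img, "bits.per.sample")
  counts <- round(img[, , 1:3] * MAX_COUNT)
  if (!is.null(bits) && bits == 8L)
    warning("8-bit image upscaled to 16-bit range (x257)")
  meta <- list()
  file_dpi <- NULL
  xres <- attr(img, "x.resolution")
  runit <- attr(img, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    file_dpi <- if (!is.null(runit) && identical(runit, "cm"))
      xres * 2.54 else xres
  }
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$dpi)) file_dpi <- side$dpi
    meta <- side[setdiff(names(side), "dpi")]
  }
  if (!is.null(dpi)) file_dpi <- dpi
  if (is.null(file_dpi))
    stop("no resolution found in TIFF tags or sidecar; pass dpi explicitly")
  ScanImage(counts, dpi = file_dpi, metadata = as.list(meta))
}

#' Write a ScanImage as a 16-bit RGB TIFF with a JSON sidecar
#'
#' The raster is written as a contiguous single-page 16-bit TIFF; the scan
#' resolution and metadata go to `<path minus extension>.json` so that
#' [readScan()] round-trips losslessly.
#'
#' @param img a [ScanImage-class].
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeScan <- function(img, path, sidecar = TRUE) {
  validObject(img)
  tiff::writeTIFF(img@data / MAX_COUNT, path, bits.per.sample = 16L,
                  reduce = FALSE)
  if (sidecar)
    jsonlite::write_json(c(list(dpi = img@dpi), img@metadata),
                         .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract one colour channel of a scan
#'
#' @param img a [ScanImage-class].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return numeric matrix of counts for that channel.
#' @export
splitChannel <- function(img, channel = c("B", "R", "G")) {
  channel <- match.arg(channel)
  img@data[, , match(channel, c("R", "G", "B"))]
}

#' Compute per-pixel absorbance against a blank reference
#'
#' Absorbance is `A = log10(I0 / It)` with both intensities on the 16-bit
#' grayscale. Two reference modes are supported: a paired blank-solvent
#' scan of the same shape (per-pixel `I0`, the default practice), or a
#' rectangular background region of the sample itself whose mean count
#' serves as a scalar `I0`. Transmitted counts are clamped to at least one
#' count after dark-floor subtraction; pixels that clamp are flagged
#' invalid in the mask rather than dropped, so area statistics remain
#' intact.
#'
#' @param sample a [ScanImage-class] of the dye-filled device.
#' @param reference either a [ScanImage-class] blank scan of the same
#'   shape, or an integer vector `c(row1, row2, col1, col2)` giving a
#'   background region within `sample`.
#' @param channel colour channel to use; blue by default (greatest
#'   extinction for a red dye).
#' @param dark_floor scanner dark offset in counts, subtracted from both
#'   intensities before the ratio (default 0).
#' @return an [AbsorbanceMap-class].
#' @examples
#' fld <- DepthField(matrix(89, 6, 6), pitch = 2)
#' cfg <- ScanSimConfig(noise_sd = 0)
#' a <- computeAbsorbance(simulateScan(fld, cfg),
#'                        simulateScan(DepthField(matrix(0, 6, 6), 2), cfg))
#' absorbance(a)[1, 1]  # ~ 0.00052 * 6 * 89
#' @export
computeAbsorbance <- function(sample, reference, channel = c("B", "R", "G"),
                              dark_floor = 0) {
  channel <- match.arg(channel)
  it <- splitChannel(sample, channel) - dark_floor
  if (is(reference, "ScanImage")) {
    if (!identical(dim(sample@data)[1:2], dim(reference@data)[1:2]))
      stop("sample and reference scans have different shapes")
    i0 <- splitChannel(reference, channel) - dark_floor
    ref_prov <- "paired blank image"
  } else if (is.numeric(reference) && length(reference) == 4L) {
    rr <- reference[1]:reference[2]
    cc <- reference[3]:reference[4]
    if (min(reference) < 1 || reference[2] > nrow(it) ||
        reference[4] > ncol(it))
      stop("background region lies outside the sample image")
    if (!length(rr) || !length(cc))
      stop("background region is empty")
    i0 <- mean(it[rr, cc])
    ref_prov <- sprintf("background region rows %d:%d cols %d:%d",
                        reference[1], reference[2], reference[3],
                        reference[4])
  } else {
    stop("reference must be a ScanImage or c(row1, row2, col1, col2)")
  }
  mask <- it >= 1 & (i0 >= 1)
  it_cl <- pmax(it, 1)
  i0_cl <- pmax(i0, 1)
  a <- log10(i0_cl / it_cl)
  if (!is.matrix(a)) a <- matrix(a, nrow(it), ncol(it))
  if (!is.matrix(mask)) mask <- matrix(mask, nrow(it), ncol(it))
  new("AbsorbanceMap", absorbance = a, channel = channel, mask = mask,
      pitch = pixelPitch(sample),
      metadata = list(reference = ref_prov, dark_floor = dark_floor,
                      n_scans = 1L))
}

## integer shift of b maximizing cross-correlation with a (FFT-based)
.integerShift <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  w <- which.max(cc) - 1L
  nr <- nrow(a)
  dr <- w %% nr
  dc <- w %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > ncol(a) / 2) dc <- dc - ncol(a)
  c(dr, dc)
}

.applyShift <- function(m, shift, fill = NA) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  sr <- shift[1]; sc <- shift[2]
  rs <- max(1, 1 + sr):min(nr, nr + sr)
  cs <- max(1, 1 + sc):min(nc, nc + sc)
  out[rs, cs] <- m[rs - sr, cs - sc]
  out
}

#' Average repeated-scan absorbance maps
#'
#' Pixelwise mean over a set of absorbance maps of the same device,
#' reducing uncorrelated sensor noise by `1/sqrt(N)`. Repeat scans on a
#' flatbed are assumed pixel-aligned by default; `align = "integer"`
#' registers each map to the first by the integer shift maximizing their
#' cross-correlation before averaging. The output mask is the union of
#' per-map validity: a pixel valid in at least one input contributes.
#'
#' @param maps list of [AbsorbanceMap-class] objects, same shape and
#'   channel.
#' @param align `"none"` (default) or `"integer"`.
#' @return an [AbsorbanceMap-class]; metadata records the number of scans
#'   averaged.
#' @export
averageScans <- function(maps, align = c("none", "integer")) {
  align <- match.arg(align)
  stopifnot(length(maps) >= 1L)
  ch <- maps[[1]]@channel
  dm <- dim(maps[[1]]@absorbance)
  for (m in maps) {
    if (!identical(m@channel, ch))
      stop("cannot average maps from different colour channels")
    if (!identical(dim(m@absorbance), dm))
      stop("cannot average maps of different shapes")
  }
  mats <- lapply(maps, function(m) {
    a <- m@absorbance
    a[!m@mask] <- NA
    a
  })
  if (align == "integer" && length(mats) > 1L) {
    ref <- mats[[1]]
    ref0 <- ifelse(is.na(ref), 0, ref)
    for (i in seq_along(mats)[-1]) {
      cur <- ifelse(is.na(mats[[i]]), 0, mats[[i]])
      sh <- .integerShift(ref0, cur)
      if (any(sh != 0)) mats[[i]] <- .applyShift(mats[[i]], sh)
    }
  }
  cnt <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
  tot <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
  avg <- ifelse(cnt > 0, tot / pmax(cnt, 1), 0)
  new("AbsorbanceMap", absorbance = avg, channel = ch, mask = cnt > 0,
      pitch = maps[[1]]@pitch,
      metadata = list(n_scans = length(maps), align = align))
}

#' Write an AbsorbanceMap or DepthMap as 32-bit float TIFF plus sidecar
#'
#' The value matrix is affinely mapped into `[0, 1]` for storage (TIFF
#' float samples outside that range are not portable) and the scale/offset
#' recorded in the JSON sidecar together with channel, pitch, units and
#' provenance; [readAbsorbanceMap()] / [readDepthMap()] undo the mapping
#' exactly to float precision. Invalid pixels are stored as 0 and restored
#' from the mask kept in the sidecar.
#'
#' @param x an [AbsorbanceMap-class] or [DepthMap-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFloatMap <- function(x, path) {
  if (is(x, "AbsorbanceMap")) {
    vals <- x@absorbance
    extra <- list(type = "AbsorbanceMap", channel = x@channel,
                  pitch_um = x@pitch, metadata = x@metadata)
  } else if (is(x, "DepthMap")) {
    vals <- x@depth
    extra <- list(type = "DepthMap", units = "um", pitch_um = x@pitch,
                  provenance = x@provenance)
  } else stop("x must be an AbsorbanceMap or a DepthMap")
  mask <- x@mask
  vals[!mask] <- 0
  lo <- min(vals); hi <- max(vals)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((vals - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- c(extra, list(offset = lo, scale = scale,
                        invalid_px = which(!mask)))
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.readFloatMap <- function(path, expect_type) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for float map: ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(side$type, expect_type))
    stop("file holds a ", side$type, ", expected ", expect_type)
  raw <- tiff::readTIFF(path)
  vals <- raw * side$scale + side$offset
  mask <- matrix(TRUE, nrow(vals), ncol(vals))
  if (length(side$invalid_px)) mask[side$invalid_px] <- FALSE
  list(vals = vals, mask = mask, side = side)
}

#' @rdname writeFloatMap
#' @export
readAbsorbanceMap <- function(path) {
  r <- .readFloatMap(path, "AbsorbanceMap")
  new("AbsorbanceMap", absorbance = r$vals, channel = r$side$channel,
      mask = r$mask, pitch = r$side$pitch_um,
      metadata = as.list(r$side$metadata))
}

#' @rdname writeFloatMap
#' @export
readDepthMap <- function(path) {
  r <- .readFloatMap(path, "DepthMap")
  new("DepthMap", depth = r$vals, pitch = r$side$pitch_um, mask = r$mask,
      provenance = as.list(r$side$provenance))
}
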