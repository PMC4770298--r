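## union-find over integer ids
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## merge 4-connected labels that touch diagonally -> 8-connectivity
.merge8 <- function(lab) {
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  for (i in seq_len(nrow(pairs))) {
    ra <- .ufFind(parent, pairs[i, 1])
    rb <- .ufFind(parent, pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), function(i) .ufFind(parent, i), integer(1))
  lut <- c(0L, as.integer(root))
  matrix(lut[lab + 1L], nr, nc)
}

#' Segment features from a depth map
#'
#' Thresholds the depth map (explicit threshold, or an Otsu split of the
#' depth histogram when `min_depth` is `NULL`), labels connected components
#' under 8-connectivity, discards regions smaller than `min_area_px`
#' pixels, and assigns final labels in deterministic row-major order of the
#' region centroids. Invalid pixels never contribute to a region. Touching
#' (but not overlapping) features merge into one region by construction of
#' connectivity.
#'
#' @param d a [DepthMap-class] or [DepthField-class].
#' @param min_depth depth threshold in micrometres, or `NULL` for Otsu.
#' @param min_area_px minimum region size in pixels (default 10).
#' @return a [FeatureSet-class]; empty table when nothing segments.
#' @export
segmentFeatures <- function(d, min_depth = NULL, min_area_px = 10) {
  stopifnot(min_area_px >= 0)
  depth <- depthMatrix(d)
  mask <- if (is(d, "DepthMap")) d@mask else
    matrix(TRUE, nrow(depth), ncol(depth))
  pitch <- pixelPitch(d)
  if (is.null(min_depth)) {
    pos <- pmax(depth, 0)
    top <- max(pos)
    min_depth <- if (top > 0)
      EBImage::otsu(EBImage::Image(pos / top), range = c(0, 1)) * top
    else Inf
  }
  if (min_depth < 0) stop("min_depth must be non-negative")
  fg <- depth >= min_depth & mask
  empty <- new("FeatureSet", labels = matrix(0L, nrow(depth), ncol(depth)),
               table = data.frame(label = integer(0),
                                  centroid_x_um = numeric(0),
                                  centroid_y_um = numeric(0),
                                  area_um2 = numeric(0),
                                  max_depth_um = numeric(0),
                                  n_pixels = integer(0)),
               pitch = pitch, threshold = min_depth)
  if (!any(fg)) return(empty)
  lab <- .merge8(matrix(as.integer(EBImage::bwlabel(fg)),
                        nrow(depth), ncol(depth)))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  npx <- tabulate(ids)
  keep <- which(npx >= max(min_area_px, 1L))
  if (!length(keep)) return(empty)
  rows <- (idx - 1L) %% nrow(depth) + 1L
  cols <- (idx - 1L) %/% nrow(depth) + 1L
  cx <- tapply((cols - 0.5) * pitch, ids, mean)[as.character(keep)]
  cy <- tapply((rows - 0.5) * pitch, ids, mean)[as.character(keep)]
  dmax <- tapply(depth[idx], ids, max)[as.character(keep)]
  ord <- order(round(cy / pitch), cx)  # row-major by centroid
  keep <- keep[ord]
  relut <- integer(max(lab))
  relut[keep] <- seq_along(keep)
  lab2 <- lab
  lab2[idx] <- relut[ids]
  tab <- data.frame(label = seq_along(keep),
                    centroid_x_um = unname(cx[ord]),
                    centroid_y_um = unname(cy[ord]),
                    area_um2 = npx[keep] * pitch^2,
                    max_depth_um = unname(dmax[ord]),
                    n_pixels = npx[keep])
  new("FeatureSet", labels = lab2, table = tab, pitch = pitch,
      threshold = min_depth)
}

.checkLabels <- function(features, labels) {
  if (is.null(labels)) labels <- features@table$label
  if (!all(labels %in% features@table$label))
    stop("unknown region label(s): ",
         paste(setdiff(labels, features@table$label), collapse = ", "))
  labels
}

#' Integrate region volume from a depth map
#'
#' The volume of a segmented region is the sum of its pixel depths times
#' the pixel area, converted to nanolitres
#' (`V = sum(d) * p^2 / 1e6`, `d` and `p` in micrometres). Only the
#' region's own (thresholded) pixels contribute. Invalid pixels inside a
#' region are excluded; a region with no valid pixels is an error.
#'
#' @param d the [DepthMap-class] or [DepthField-class] the features were
#'   segmented from.
#' @param features a [FeatureSet-class].
#' @param labels region labels to measure (default: all).
#' @return named numeric vector of volumes in nL.
#' @export
integrateVolume <- function(d, features, labels = NULL) {
  labels <- .checkLabels(features, labels)
  depth <- depthMatrix(d)
  if (!identical(dim(depth), dim(features@labels)))
    stop("depth map and feature set have different shapes")
  mask <- if (is(d, "DepthMap")) d@mask else TRUE
  lab <- features@labels
  use <- lab > 0L & mask
  sums <- tapply(depth[use], lab[use], sum)
  out <- sums[as.character(labels)] * features@pitch^2 / UM3_PER_NL
  if (any(is.na(out)))
    stop("region(s) with no valid pixels: ",
         paste(labels[is.na(out)], collapse = ", "))
  names(out) <- labels
  out
}

## 3x3 median smoothing, implemented via EBImage on a [0,1]-normalized copy
.medianSmooth3 <- function(depth) {
  pos <- pmax(depth, 0)
  top <- max(pos)
  if (top <= 0) return(pos)
  as.matrix(EBImage::medianFilter(EBImage::Image(pos / top), size = 1)) *
    top
}

#' Half-depth area of segmented regions
#'
#' The area of the pixels in a region whose depth reaches at least half of
#' the region's maximum depth; a shape descriptor that separates
#' flat-bottomed wells (half-depth area = full area) from cone-shaped pits
#' (a quarter of the mouth area). The reference maximum is taken after 3x3
#' median smoothing, since a raw per-region maximum is biased upward by
#' noise; the pixel count itself uses the unsmoothed depths.
#'
#' @param d the [DepthMap-class] or [DepthField-class] the features were
#'   segmented from.
#' @param features a [FeatureSet-class].
#' @param labels region labels to measure (default: all).
#' @return named numeric vector of areas in um^2.
#' @export
halfDepthArea <- function(d, features, labels = NULL) {
  labels <- .checkLabels(features, labels)
  depth <- depthMatrix(d)
  if (!identical(dim(depth), dim(features@labels)))
    stop("depth map and feature set have different shapes")
  sm <- .medianSmooth3(depth)
  lab <- features@labels
  use <- lab > 0L
  dmax <- tapply(sm[use], lab[use], max)
  if (any(dmax[as.character(labels)] <= 0))
    stop("region(s) with non-positive maximum depth: ",
         paste(labels[dmax[as.character(labels)] <= 0], collapse = ", "))
  half <- dmax[as.character(as.integer(lab[use]))] / 2
  cnt <- tapply(depth[use] >= half, lab[use], sum)
  out <- cnt[as.character(labels)] * features@pitch^2
  names(out) <- labels
  out
}

## bilinear depth sample at physical points (x, y) um; NA outside
.bilinear <- function(depth, pitch, x, y) {
  nr <- nrow(depth); nc <- ncol(depth)
  j <- x / pitch + 0.5
  i <- y / pitch + 0.5
  j <- pmin(pmax(j, 1), nc)
  i <- pmin(pmax(i, 1), nr)
  i0 <- floor(i); j0 <- floor(j)
  i1 <- pmin(i0 + 1, nr); j1 <- pmin(j0 + 1, nc)
  fi <- i - i0; fj <- j - j0
  depth[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    depth[cbind(i1, j0)] * fi * (1 - fj) +
    depth[cbind(i0, j1)] * (1 - fi) * fj +
    depth[cbind(i1, j1)] * fi * fj
}

#' Depth cross-section along a line
#'
#' Samples the depth map by bilinear interpolation along the segment from
#' `p0` to `p1` (micrometre coordinates, pixel-centre convention), at one
#' pixel pitch spacing.
#'
#' @param d a [DepthMap-class] or [DepthField-class].
#' @param p0,p1 segment endpoints `(x, y)` in micrometres; must lie inside
#'   the map and be distinct.
#' @return data.frame with columns `position_um` (distance from `p0`) and
#'   `depth_um`.
#' @export
crossSection <- function(d, p0, p1) {
  depth <- depthMatrix(d)
  pitch <- pixelPitch(d)
  ext <- c(ncol(depth), nrow(depth)) * pitch
  for (p in list(p0, p1))
    if (length(p) != 2L || any(p < 0) || p[1] > ext[1] || p[2] > ext[2])
      stop("cross-section endpoints must lie inside the map")
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("degenerate zero-length cross-section line")
  pos <- seq(0, L, by = pitch)
  if (pos[length(pos)] < L) pos <- c(pos, L)
  u <- (p1 - p0) / L
  data.frame(position_um = pos,
             depth_um = .bilinear(depth, pitch,
                                  p0[1] + pos * u[1], p0[2] + pos * u[2]))
}

#' Longitudinal profile: repeated cross-sections along a channel axis
#'
#' Takes `n_slices` cross-sections perpendicular to the channel axis,
#' evenly spaced along it, each extending `halfwidth_um` to both sides of
#' the axis, and reports the pointwise mean profile and its +/- 1 sd
#' envelope across slices. A translationally uniform channel yields a zero
#' sd envelope; fabrication jitter shows up as sd concentrated where the
#' profile varies (typically the sidewalls).
#'
#' @param d a [DepthMap-class] or [DepthField-class].
#' @param p0,p1 axis endpoints `(x, y)` in micrometres.
#' @param n_slices number of cross-sections (>= 2, default 16).
#' @param halfwidth_um half-width of each cross-section, micrometres.
#' @return list with `slices` (list of cross-section data.frames, each with
#'   an `axis_position_um` attribute), `offset_um` (transverse sample
#'   offsets), `mean_depth_um`, `sd_depth_um`.
#' @export
longitudinalProfile <- function(d, p0, p1, n_slices = 16,
                                halfwidth_um = NULL) {
  if (n_slices < 2) stop("n_slices must be at least 2")
  depth <- depthMatrix(d)
  pitch <- pixelPitch(d)
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("degenerate zero-length axis")
  u <- (p1 - p0) / L
  v <- c(-u[2], u[1])  # perpendicular
  if (is.null(halfwidth_um)) halfwidth_um <- L / 4
  offs <- seq(-halfwidth_um, halfwidth_um, by = pitch)
  tpos <- (seq_len(n_slices) - 0.5) / n_slices * L
  ext <- c(ncol(depth), nrow(depth)) * pitch
  prof <- matrix(NA_real_, length(offs), n_slices)
  slices <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    ctr <- p0 + tpos[s] * u
    xs <- ctr[1] + offs * v[1]
    ys <- ctr[2] + offs * v[2]
    if (min(xs) < 0 || max(xs) > ext[1] || min(ys) < 0 || max(ys) > ext[2])
      stop("cross-section slice extends outside the map; shorten ",
           "halfwidth_um or move the axis")
    prof[, s] <- .bilinear(depth, pitch, xs, ys)
    sl <- data.frame(position_um = offs - offs[1], depth_um = prof[, s])
    attr(sl, "axis_position_um") <- tpos[s]
    slices[[s]] <- sl
  }
  list(slices = slices, offset_um = offs,
       mean_depth_um = rowMeans(prof),
       sd_depth_um = apply(prof, 1, stats::sd))
}

#' Measure segmented wells into a WellPopulation
#'
#' Convenience wrapper: volume, half-depth area and centroid for every
#' region of a [FeatureSet-class], assembled into a
#' [WellPopulation-class].
#'
#' @param d the [DepthMap-class] or [DepthField-class] the features were
#'   segmented from.
#' @param features a [FeatureSet-class] with at least one region.
#' @return a [WellPopulation-class].
#' @export
measureWells <- function(d, features) {
  tab <- features@table
  if (!nrow(tab)) stop("feature set contains no regions to measure")
  vols <- integrateVolume(d, features)
  hda <- halfDepthArea(d, features)
  new("WellPopulation",
      wells = data.frame(label = tab$label, volume_nL = unname(vols),
                         half_depth_area_um2 = unname(hda),
                         centroid_x_um = tab$centroid_x_um,
                         centroid_y_um = tab$centroid_y_um,
                         area_um2 = tab$area_um2,
                         max_depth_um = tab$max_depth_um),
      metadata = list(threshold_um = features@threshold,
                      pitch_um = features@pitch))
}
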