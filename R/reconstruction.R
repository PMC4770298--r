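#' Reconstruct a depth map from an absorbance map
#'
#' Beer-Lambert inversion: with the dye's extinction coefficient `epsilon`
#' (`mM^-1 um^-1`) and its concentration `c` (mM), the optical path length
#' at each pixel is `d = A / (epsilon * c)` micrometres. When one bounding
#' surface of the structure is flat this equals the local structure depth;
#' for doubly-deformed laminated chambers it is the summed deformation of
#' both surfaces, which still integrates to the correct volume. Negative
#' depths from noise are retained, not clipped. The validity mask is
#' propagated from the absorbance map.
#'
#' @param A an [AbsorbanceMap-class] (or a [CalibrationFit-class] can
#'   supply `epsilon` via the `fit` argument).
#' @param epsilon extinction coefficient, `mM^-1 um^-1` (> 0); ignored if
#'   `fit` is given.
#' @param conc dye concentration, mM (> 0).
#' @param fit optional [CalibrationFit-class]; its epsilon is used and must
#'   be valid.
#' @return a [DepthMap-class] with provenance recording epsilon,
#'   concentration, channel and the number of averaged scans.
#' @examples
#' m <- new("AbsorbanceMap", absorbance = matrix(0.4992, 2, 2),
#'          channel = "B", mask = matrix(TRUE, 2, 2), pitch = 2,
#'          metadata = list())
#' depthMatrix(reconstructDepth(m, epsilon = 0.00052, conc = 6))[1, 1]
#' # 160 um
#' @export
reconstructDepth <- function(A, epsilon = NULL, conc, fit = NULL) {
  stopifnot(is(A, "AbsorbanceMap"))
  if (!is.null(fit)) {
    if (!isTRUE(fit@valid)) stop("calibration fit is flagged invalid")
    epsilon <- fit@epsilon
  }
  if (is.null(epsilon) || epsilon <= 0 || conc <= 0 ||
      !is.finite(epsilon * conc) || epsilon * conc == 0)
    stop("epsilon and conc must be positive (epsilon * conc > 0)")
  d <- A@absorbance / (epsilon * conc)
  n_scans <- if (is.null(A@metadata$n_scans)) 1L else A@metadata$n_scans
  new("DepthMap", depth = d, pitch = A@pitch, mask = A@mask,
      provenance = list(epsilon = epsilon, conc_mM = conc,
                        channel = A@channel, n_scans = n_scans))
}

#' Estimate depth noise over a known-flat region
#'
#' Quantifies reconstruction noise in micrometres. With several repeat
#' depth maps, the estimate is the mean over the region of the pixelwise
#' standard deviation across maps (pure sensor noise, insensitive to any
#' real surface texture). With a single map it falls back to the spatial
#' standard deviation within the region, which assumes the region is truly
#' flat.
#'
#' @param maps a [DepthMap-class] or list of them (same shape).
#' @param region integer vector `c(row1, row2, col1, col2)` delimiting a
#'   flat region, or `NULL` for the whole map.
#' @return noise standard deviation in micrometres.
#' @export
depthNoiseEstimate <- function(maps, region = NULL) {
  if (is(maps, "DepthMap")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  dm <- dim(maps[[1]]@depth)
  if (is.null(region)) region <- c(1L, dm[1], 1L, dm[2])
  if (region[1] < 1 || region[2] > dm[1] || region[3] < 1 ||
      region[4] > dm[2] || region[1] > region[2] || region[3] > region[4])
    stop("region lies outside the depth map")
  rr <- region[1]:region[2]
  cc <- region[3]:region[4]
  sub <- lapply(maps, function(m) {
    if (!identical(dim(m@depth), dm)) stop("maps must share one shape")
    d <- m@depth
    d[!m@mask] <- NA
    d[rr, cc]
  })
  if (length(sub) == 1L)
    return(stats::sd(sub[[1]][is.finite(sub[[1]])]))
  stack <- array(unlist(sub), dim = c(length(rr), length(cc), length(sub)))
  px_sd <- apply(stack, c(1, 2), stats::sd, na.rm = TRUE)
  mean(px_sd[is.finite(px_sd)])
}
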