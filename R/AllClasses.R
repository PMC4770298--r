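#' @import methods
NULL

MAX_COUNT <- 65535          # 16-bit grayscale ceiling
UM_PER_INCH <- 25400        # micrometres per inch, fixes pitch = 25400/dpi
UM3_PER_NL <- 1e6           # 1 nL = 1e6 um^3

FEATURE_KINDS <- c("cylinder_chamber", "basin_well", "cone_well",
                   "ablated_channel", "sagging_chamber")

#' ScanImage: a raw 16-bit RGB transmission scan
#'
#' Holds the three-channel raster a flatbed scanner produces in film-scan
#' (transmission) mode, with counts on the 16-bit grayscale `[0, 65535]`,
#' the scan resolution in dots per inch, and free-form acquisition metadata
#' (scan index, mode tag, simulation provenance). The physical pixel pitch
#' is derived, `25400/dpi` micrometres.
#'
#' @slot data numeric array, rows x cols x 3 (R, G, B), counts in
#'   `[0, 65535]`.
#' @slot dpi scan resolution, dots per inch (> 0).
#' @slot metadata named list of acquisition metadata.
#' @export
setClass("ScanImage",
  representation(data = "array", dpi = "numeric", metadata = "list"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      return("data must be a rows x cols x 3 array")
    if (!all(is.finite(d)))
      return("counts must be finite")
    if (min(d) < 0 || max(d) > MAX_COUNT)
      return(sprintf("counts must lie in [0, %d]", MAX_COUNT))
    if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
      return("dpi must be a single positive number")
    TRUE
  })

#' AbsorbanceMap: per-pixel absorbance in one colour channel
#'
#' Per-pixel absorbance `A = log10(I0/It)` computed from a sample scan and a
#' blank-solvent reference in a single RGB channel. The validity mask flags
#' pixels where `A` could not be computed (zero transmitted counts after
#' dark-floor subtraction); noise may legitimately drive `A` slightly
#' negative on valid pixels, so no positivity is enforced.
#'
#' @slot absorbance numeric matrix of absorbance values (log10 units).
#' @slot channel one of `"R"`, `"G"`, `"B"`.
#' @slot mask logical matrix, `TRUE` where absorbance is computable.
#' @slot pitch physical pixel pitch, micrometres.
#' @slot metadata named list (reference provenance, scans averaged, ...).
#' @export
setClass("AbsorbanceMap",
  representation(absorbance = "matrix", channel = "character",
                 mask = "matrix", pitch = "numeric", metadata = "list"),
  validity = function(object) {
    if (!identical(dim(object@absorbance), dim(object@mask)))
      return("absorbance and mask must have the same shape")
    if (!is.logical(object@mask))
      return("mask must be logical")
    if (!(object@channel %in% c("R", "G", "B")))
      return("channel must be one of R, G, B")
    if (any(!is.finite(object@absorbance[object@mask])))
      return("absorbance must be finite wherever the mask is TRUE")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
        object@pitch <= 0)
      return("pitch must be a single positive number")
    TRUE
  })

#' DepthField: a ground-truth depth grid
#'
#' A rendered (known) depth field on a regular physical grid: depth in
#' micrometres per cell, pixel pitch in micrometres. The origin is the
#' top-left corner; physical coordinates are taken at pixel centres, x to
#' the right and y downward. All depths are non-negative and finite.
#'
#' @slot depth numeric matrix, depth in micrometres.
#' @slot pitch pixel pitch, micrometres.
#' @export
setClass("DepthField",
  representation(depth = "matrix", pitch = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@depth)))
      return("depths must be finite")
    if (min(object@depth) < 0)
      return("depths must be non-negative")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
        object@pitch <= 0)
      return("pitch must be a single positive number")
    TRUE
  })

#' DepthMap: a reconstructed per-pixel depth map
#'
#' Depth reconstructed from an [AbsorbanceMap-class] by Beer-Lambert
#' inversion, `d = A/(epsilon * c)`. Negative depths (noise on blank
#' regions) are retained, not clipped, so population statistics on blank
#' areas stay unbiased; the mask flags only non-computable pixels.
#' Provenance records the extinction coefficient, dye concentration,
#' channel and number of averaged scans used.
#'
#' @slot depth numeric matrix, micrometres (may contain negatives).
#' @slot pitch pixel pitch, micrometres.
#' @slot mask logical matrix, `TRUE` where the depth is computable.
#' @slot provenance named list: `epsilon`, `conc_mM`, `channel`, `n_scans`.
#' @export
setClass("DepthMap",
  representation(depth = "matrix", pitch = "numeric", mask = "matrix",
                 provenance = "list"),
  validity = function(object) {
    if (!identical(dim(object@depth), dim(object@mask)))
      return("depth and mask must have the same shape")
    if (!is.logical(object@mask))
      return("mask must be logical")
    if (any(!is.finite(object@depth[object@mask])))
      return("valid depths must be finite")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
        object@pitch <= 0)
      return("pitch must be a single positive number")
    TRUE
  })

#' FeatureSpec: parametric description of one microfluidic feature
#'
#' One feature to be rendered into a [DepthField-class]. Supported kinds:
#' \describe{
#'   \item{`cylinder_chamber`}{flat-bottomed cylinder: radius `r`, depth `d`.}
#'   \item{`basin_well`}{isotropic-etch profile: flat bottom of mask radius
#'     `r`, quarter-circle sidewall of radius `d` (mouth radius `r + d`).}
#'   \item{`cone_well`}{cone pit from a single focused laser pulse: mouth
#'     radius `r`, apex depth `d`.}
#'   \item{`ablated_channel`}{straight channel with a Gaussian transverse
#'     profile (laser single-stroke ablation): peak depth `d`, params
#'     `length` (um), `width` (Gaussian sd, um), `angle_deg` (axis
#'     orientation, default 0 = along x), optional `width_jitter_sd` and
#'     `jitter_seed` for per-slice sidewall jitter.}
#'   \item{`sagging_chamber`}{cylinder of depth `d` minus a spherical-cap
#'     sag whose volume is `k_sag * r^3` (param `k_sag`, the laminated-film
#'     sagging coefficient).}
#' }
#'
#' @slot kind feature kind, one of the five above.
#' @slot center feature centre `(x, y)` in micrometres.
#' @slot r characteristic radius, micrometres (> 0).
#' @slot d characteristic depth, micrometres (>= 0).
#' @slot params named list of kind-specific shape parameters.
#' @export
setClass("FeatureSpec",
  representation(kind = "character", center = "numeric", r = "numeric",
                 d = "numeric", params = "list"),
  validity = function(object) {
    if (!(object@kind %in% FEATURE_KINDS))
      return(sprintf("kind must be one of: %s",
                     paste(FEATURE_KINDS, collapse = ", ")))
    if (length(object@center) != 2L || !all(is.finite(object@center)))
      return("center must be a finite (x, y) pair")
    if (length(object@r) != 1L || !is.finite(object@r) || object@r <= 0)
      return("r must be a single positive number")
    if (length(object@d) != 1L || !is.finite(object@d) || object@d < 0)
      return("d must be a single non-negative number")
    if (object@kind == "ablated_channel") {
      for (p in c("length", "width"))
        if (is.null(object@params[[p]]) || object@params[[p]] <= 0)
          return(sprintf("ablated_channel requires positive param '%s'", p))
    }
    if (object@kind == "sagging_chamber") {
      k <- object@params$k_sag
      if (is.null(k) || !is.finite(k) || k < 0)
        return("sagging_chamber requires non-negative param 'k_sag'")
    }
    TRUE
  })

#' ScanSimConfig: forward-model scanner configuration
#'
#' Parameters of the simulated scanner: resolution, incident intensity,
#' additive Gaussian sensor noise on transmitted counts, per-channel
#' extinction coefficients of the dye (for an Allura-Red-like red dye the
#' blue channel absorbs most: `eps_B >= eps_G >= eps_R >= 0`), dye
#' concentration and the random seed. Bit depth is fixed at 16. An optional
#' Poisson shot-noise flag and a gamma transfer exponent are available for
#' realism studies; the defaults model a linear film-scan response.
#'
#' @slot dpi scan resolution, dots per inch.
#' @slot i0 incident intensity, counts in `[1, 65535]`.
#' @slot noise_sd additive Gaussian noise sd, counts.
#' @slot eps named numeric `(R, G, B)` extinction coefficients,
#'   `mM^-1 um^-1`.
#' @slot conc dye concentration, mM.
#' @slot gamma transfer-curve exponent (1 = linear, the default).
#' @slot poisson logical; add Poisson shot noise before Gaussian noise.
#' @slot seed integer random seed (`NA` = use current RNG state).
#' @export
setClass("ScanSimConfig",
  representation(dpi = "numeric", i0 = "numeric", noise_sd = "numeric",
                 eps = "numeric", conc = "numeric", gamma = "numeric",
                 poisson = "logical", seed = "integer"),
  validity = function(object) {
    if (object@dpi <= 0) return("dpi must be positive")
    if (!is.finite(object@i0) || object@i0 <= 0 || object@i0 > MAX_COUNT)
      return(sprintf("i0 must lie in (0, %d]", MAX_COUNT))
    if (object@noise_sd < 0) return("noise_sd must be non-negative")
    if (length(object@eps) != 3L ||
        !identical(names(object@eps), c("R", "G", "B")))
      return("eps must be a named numeric of length 3: R, G, B")
    if (any(object@eps < 0))
      return("extinction coefficients must be non-negative")
    if (!(object@eps["B"] >= object@eps["G"] &&
          object@eps["G"] >= object@eps["R"]))
      return("expected eps_B >= eps_G >= eps_R for a red dye")
    if (object@conc < 0) return("conc must be non-negative")
    if (object@gamma <= 0) return("gamma must be positive")
    TRUE
  })

#' CalibrationSeries: absorbance standards at varied depth or concentration
#'
#' A calibration series measured on standard chambers: either absorbance at
#' several known depths with the dye concentration fixed (`depth_series`),
#' or at several known concentrations with the depth fixed
#' (`concentration_series`). Each point carries the mean absorbance over
#' replicates, its sd and the replicate count.
#'
#' @slot mode `"depth_series"` or `"concentration_series"`.
#' @slot fixed the fixed quantity: concentration in mM (depth series) or
#'   depth in um (concentration series).
#' @slot points data.frame with columns `independent_value`, `A_mean`,
#'   `A_sd`, `n`.
#' @slot channel colour channel the series was measured in.
#' @export
setClass("CalibrationSeries",
  representation(mode = "character", fixed = "numeric",
                 points = "data.frame", channel = "character"),
  validity = function(object) {
    if (!(object@mode %in% c("depth_series", "concentration_series")))
      return("mode must be depth_series or concentration_series")
    if (!is.finite(object@fixed) || object@fixed <= 0)
      return("fixed quantity must be positive")
    need <- c("independent_value", "A_mean", "A_sd", "n")
    if (!all(need %in% names(object@points)))
      return(sprintf("points must have columns: %s",
                     paste(need, collapse = ", ")))
    iv <- object@points$independent_value
    if (nrow(object@points) < 3L)
      return("a calibration series needs at least 3 points")
    if (any(iv <= 0) || anyDuplicated(iv))
      return("independent values must be positive and distinct")
    TRUE
  })

#' CalibrationFit: fitted extinction coefficient with diagnostics
#'
#' Ordinary least-squares line of absorbance on depth or concentration,
#' and the extinction coefficient derived from its slope (`slope/c` for a
#' depth series, `slope/d` for a concentration series), in `mM^-1 um^-1`.
#' A non-positive slope leaves `epsilon` flagged invalid. The intercept is
#' retained as a QC diagnostic (a well-behaved series has intercept near
#' zero).
#'
#' @slot slope fitted slope (absorbance per um or per mM).
#' @slot intercept fitted intercept (absorbance units).
#' @slot r_squared coefficient of determination of the line.
#' @slot epsilon extinction coefficient, `mM^-1 um^-1`.
#' @slot epsilon_se standard error of `epsilon` (NA when not estimable).
#' @slot channel colour channel of the underlying series.
#' @slot valid logical: `TRUE` when the fit yields a usable epsilon.
#' @slot diagnostics named list (mode, fixed value, n points, residuals).
#' @export
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 r_squared = "numeric", epsilon = "numeric",
                 epsilon_se = "numeric", channel = "character",
                 valid = "logical", diagnostics = "list"))

#' FeatureSet: labelled segmentation of a depth map
#'
#' Connected regions (8-connectivity) of above-threshold pixels in a
#' [DepthMap-class], with per-region morphometrics. Labels are assigned in
#' deterministic row-major order of region centroids. The table holds one
#' row per region: `label`, `centroid_x_um`, `centroid_y_um`, `area_um2`
#' (pixel count times pitch squared), `max_depth_um`, `n_pixels`, and the
#' pixel bounding box.
#'
#' @slot labels integer matrix; 0 = background, k = region k.
#' @slot table data.frame of per-region properties.
#' @slot pitch pixel pitch, micrometres.
#' @slot threshold the depth threshold used, micrometres.
#' @export
setClass("FeatureSet",
  representation(labels = "matrix", table = "data.frame", pitch = "numeric",
                 threshold = "numeric"))

#' WellPopulation: per-well measurements with population statistics
#'
#' One row per well: volume in nL, half-depth area in um^2, centroid, and
#' optionally a designed (true) type label and a cluster label from k-means
#' typing. Summary statistics (mean, sd, coefficient of variation) are
#' computed by [summarizeWells()].
#'
#' @slot wells data.frame; must contain `volume_nL`, may contain
#'   `half_depth_area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `true_label`, `cluster`.
#' @slot metadata named list (seeds, provenance, rejected-draw counts).
#' @export
setClass("WellPopulation",
  representation(wells = "data.frame", metadata = "list"),
  validity = function(object) {
    if (!("volume_nL" %in% names(object@wells)))
      return("wells must contain a volume_nL column")
    if (nrow(object@wells) < 1L)
      return("a population needs at least one well")
    TRUE
  })
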