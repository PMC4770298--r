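#' Construct a FeatureSpec
#'
#' @param kind one of `"cylinder_chamber"`, `"basin_well"`, `"cone_well"`,
#'   `"ablated_channel"`, `"sagging_chamber"`.
#' @param center feature centre `(x, y)` in micrometres.
#' @param r characteristic radius in micrometres (mask radius for a basin
#'   well, mouth radius for a cone, chamber radius otherwise; for a channel
#'   it is unused by the profile and conventionally set to the half-width).
#' @param d characteristic depth in micrometres.
#' @param ... kind-specific parameters: `length`, `width`, `angle_deg`,
#'   `width_jitter_sd`, `jitter_seed` (ablated_channel); `k_sag`
#'   (sagging_chamber).
#' @return a [FeatureSpec-class].
#' @examples
#' FeatureSpec("basin_well", center = c(100, 100), r = 40, d = 10.9)
#' @export
FeatureSpec <- function(kind, center, r, d, ...) {
  new("FeatureSpec", kind = kind, center = as.numeric(center),
      r = as.numeric(r), d = as.numeric(d), params = list(...))
}

#' Construct a ScanSimConfig
#'
#' Defaults model an Allura-Red-like dye (strongest absorption in blue,
#' essentially transparent in red) scanned in linear film-scan mode with
#' moderate additive sensor noise.
#'
#' @param dpi scan resolution, dots per inch.
#' @param i0 incident intensity in counts (blank-field level).
#' @param noise_sd additive Gaussian noise sd on transmitted counts.
#' @param eps_R,eps_G,eps_B per-channel extinction coefficients,
#'   `mM^-1 um^-1`.
#' @param conc dye concentration, mM.
#' @param gamma transfer exponent; 1 (default) is a linear response.
#' @param poisson add Poisson shot noise before the Gaussian term.
#' @param seed integer seed for reproducible noise, or `NA`.
#' @return a [ScanSimConfig-class].
#' @export
ScanSimConfig <- function(dpi = 12800, i0 = 60000, noise_sd = 100,
                          eps_R = 0, eps_G = 0.00026, eps_B = 0.00052,
                          conc = 6, gamma = 1, poisson = FALSE, seed = NA) {
  new("ScanSimConfig", dpi = dpi, i0 = i0, noise_sd = noise_sd,
      eps = c(R = eps_R, G = eps_G, B = eps_B), conc = conc, gamma = gamma,
      poisson = poisson, seed = as.integer(seed))
}

#' Construct a DepthField from a depth matrix
#'
#' @param depth numeric matrix of non-negative depths, micrometres.
#' @param pitch pixel pitch, micrometres.
#' @return a [DepthField-class].
#' @export
DepthField <- function(depth, pitch) {
  new("DepthField", depth = depth, pitch = pitch)
}

## spherical-cap height h with volume V and base radius r:
## V = pi*h*(3 r^2 + h^2)/6, monotone in h -> bisection-free uniroot
.capHeightForVolume <- function(V, r) {
  if (V <= 0) return(0)
  f <- function(h) pi * h * (3 * r^2 + h^2) / 6 - V
  upper <- max(2 * V / (pi * r^2) * 3, r)  # f(upper) > 0 guaranteed below
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

## depth profile of one feature at points (x, y), vectorized
.featureDepthAt <- function(spec, x, y) {
  dx <- x - spec@center[1]
  dy <- y - spec@center[2]
  r <- spec@r; d <- spec@d
  switch(spec@kind,
    cylinder_chamber = {
      ifelse(dx^2 + dy^2 <= r^2, d, 0)
    },
    basin_well = {
      rho <- sqrt(dx^2 + dy^2)
      out <- numeric(length(rho))
      out[rho <= r] <- d
      side <- rho > r & rho <= r + d
      out[side] <- sqrt(pmax(d^2 - (rho[side] - r)^2, 0))
      out
    },
    cone_well = {
      rho <- sqrt(dx^2 + dy^2)
      pmax(d * (1 - rho / r), 0)
    },
    ablated_channel = {
      p <- spec@params
      th <- (if (is.null(p$angle_deg)) 0 else p$angle_deg) * pi / 180
      s <- dx * cos(th) + dy * sin(th)    # along axis
      t <- -dx * sin(th) + dy * cos(th)   # across axis
      w <- p$width
      jit <- p$width_jitter_sd
      if (!is.null(jit) && jit > 0) {
        # smooth per-slice width jitter: slice index along the axis at one
        # width granularity, reproducible from the feature's own seed
        bins <- floor(s / w)
        ubin <- sort(unique(bins))
        seed <- if (is.null(p$jitter_seed)) 0L else as.integer(p$jitter_seed)
        offs <- withr::with_seed(seed, stats::rnorm(length(ubin), 0, jit))
        w <- pmax(w + offs[match(bins, ubin)], w * 0.1)
      }
      depth <- d * exp(-t^2 / (2 * w^2))
      depth[abs(s) > p$length / 2 | abs(t) > 4 * max(w)] <- 0
      depth
    },
    sagging_chamber = {
      k <- spec@params$k_sag
      h <- .capHeightForVolume(k * r^3, r)
      R <- (r^2 + h^2) / (2 * h)
      rho2 <- dx^2 + dy^2
      inside <- rho2 <= r^2
      sag <- numeric(length(rho2))
      sag[inside] <- sqrt(pmax(R^2 - rho2[inside], 0)) - (R - h)
      out <- numeric(length(rho2))
      out[inside] <- pmax(d - sag[inside], 0)
      out
    })
}

## axis-aligned half-extents (hx, hy) of the feature footprint
.featureBBox <- function(spec) {
  switch(spec@kind,
    cylinder_chamber = rep(spec@r, 2),
    basin_well = rep(spec@r + spec@d, 2),
    cone_well = rep(spec@r, 2),
    sagging_chamber = rep(spec@r, 2),
    ablated_channel = {
      p <- spec@params
      jit <- if (is.null(p$width_jitter_sd)) 0 else p$width_jitter_sd
      th <- (if (is.null(p$angle_deg)) 0 else p$angle_deg) * pi / 180
      half_l <- p$length / 2
      half_w <- 4 * (p$width + 4 * jit)
      c(abs(cos(th)) * half_l + abs(sin(th)) * half_w,
        abs(sin(th)) * half_l + abs(cos(th)) * half_w)
    })
}

## circumscribed footprint radius, used for grid-spacing checks
.featureFootprint <- function(spec) {
  if (spec@kind == "ablated_channel") sqrt(sum(.featureBBox(spec)^2))
  else .featureBBox(spec)[1]
}

#' Analytic volume of a feature, in cubic micrometres
#'
#' Closed-form volumes of the supported feature shapes: cylinder
#' `pi r^2 d`; isotropic-etch basin
#' `pi (r^2 d + (pi/2) r d^2 + (2/3) d^3)`; cone `pi r^2 d / 3`; Gaussian
#' channel `d * width * sqrt(2 pi) * length`; sagging chamber
#' `pi r^2 d - k_sag r^3` (design volume minus the sagging volume).
#'
#' @param spec a [FeatureSpec-class].
#' @return volume in um^3.
#' @export
featureVolume <- function(spec) {
  r <- spec@r; d <- spec@d
  switch(spec@kind,
    cylinder_chamber = pi * r^2 * d,
    basin_well = pi * (r^2 * d + (pi / 2) * r * d^2 + (2 / 3) * d^3),
    cone_well = pi * r^2 * d / 3,
    ablated_channel = d * spec@params$width * sqrt(2 * pi) *
      spec@params$length,
    sagging_chamber = pi * r^2 * d - spec@params$k_sag * r^3)
}

#' Render a ground-truth depth field from feature specs
#'
#' Rasterizes a layout of microfluidic features onto a regular grid. Each
#' pixel takes the depth of the feature covering its centre (no
#' anti-aliasing at edges); features must not overlap and must lie inside
#' the extent.
#'
#' @param features list of [FeatureSpec-class] objects (may be empty).
#' @param extent_um field extent `(width_x, height_y)` in micrometres.
#' @param pitch_um pixel pitch in micrometres.
#' @return a [DepthField-class].
#' @examples
#' f <- FeatureSpec("cylinder_chamber", center = c(600, 600), r = 500,
#'                  d = 100)
#' fld <- renderDepthField(list(f), extent_um = c(1200, 1200),
#'                         pitch_um = pitchFromDpi(1200))
#' sum(depthMatrix(fld)) * pixelPitch(fld)^2 / 1e6  # ~ pi*500^2*100/1e6 nL
#' @export
renderDepthField <- function(features, extent_um, pitch_um) {
  stopifnot(pitch_um > 0, length(extent_um) == 2L, all(extent_um > 0))
  if (is(features, "FeatureSpec")) features <- list(features)
  nc <- max(1L, round(extent_um[1] / pitch_um))
  nr <- max(1L, round(extent_um[2] / pitch_um))
  depth <- matrix(0, nr, nc)
  occ <- matrix(0L, nr, nc)
  xs <- (seq_len(nc) - 0.5) * pitch_um
  ys <- (seq_len(nr) - 0.5) * pitch_um
  for (spec in features) {
    validObject(spec)
    bb <- .featureBBox(spec)
    if (spec@center[1] - bb[1] < 0 || spec@center[1] + bb[1] > extent_um[1] ||
        spec@center[2] - bb[2] < 0 || spec@center[2] + bb[2] > extent_um[2])
      stop("feature footprint extends outside the field extent")
    jc <- which(xs >= spec@center[1] - bb[1] & xs <= spec@center[1] + bb[1])
    ir <- which(ys >= spec@center[2] - bb[2] & ys <= spec@center[2] + bb[2])
    if (!length(jc) || !length(ir)) next
    g <- expand.grid(y = ys[ir], x = xs[jc])
    dsub <- matrix(.featureDepthAt(spec, g$x, g$y), length(ir), length(jc))
    hit <- dsub > 1e-9
    occ[ir, jc] <- occ[ir, jc] + hit
    depth[ir, jc] <- pmax(depth[ir, jc], dsub)
  }
  if (any(occ > 1L))
    stop("features overlap: ", sum(occ > 1L), " pixels claimed twice")
  DepthField(depth, pitch_um)
}

#' Simulate a 16-bit transmission scan of a depth field
#'
#' Forward Beer-Lambert model of a flatbed scanner in film-scan mode: for
#' each colour channel `x`, the transmitted count is
#' `It = I0 * 10^(-eps_x * c * d)` at every pixel, optionally passed
#' through a gamma transfer curve, degraded by Poisson shot noise and/or
#' additive Gaussian sensor noise, then quantized to integer counts and
#' clipped to `[0, 65535]`. Repeated calls with distinct seeds model
#' repeated scans of the same device.
#'
#' @param field a [DepthField-class] (ground truth).
#' @param config a [ScanSimConfig-class].
#' @return a [ScanImage-class] with metadata recording the configuration.
#' @examples
#' fld <- DepthField(matrix(160, 8, 8), pitch = 2)
#' img <- simulateScan(fld, ScanSimConfig(noise_sd = 0))
#' scanData(img)[1, 1, 3]  # blue count, 60000 * 10^-0.4992
#' @export
simulateScan <- function(field, config) {
  validObject(field); validObject(config)
  if (config@i0 <= 0) stop("incident intensity must be positive")
  d <- field@depth
  dims <- dim(d)
  run <- function() {
    out <- array(0, dim = c(dims, 3L))
    for (ch in 1:3) {
      it <- config@i0 * 10^(-config@eps[ch] * config@conc * d)
      if (config@gamma != 1)
        it <- MAX_COUNT * (it / MAX_COUNT)^(1 / config@gamma)
      if (config@poisson)
        it <- stats::rpois(length(it), lambda = it)
      if (config@noise_sd > 0)
        it <- it + stats::rnorm(length(it), 0, config@noise_sd)
      out[, , ch] <- matrix(pmin(pmax(round(it), 0), MAX_COUNT), dims[1])
    }
    out
  }
  data <- if (!is.na(config@seed)) withr::with_seed(config@seed, run())
          else run()
  # the simulated raster IS the field's grid: the image resolution follows
  # the field pitch, not the nominal config dpi (which sizes the render)
  new("ScanImage", data = data, dpi = UM_PER_INCH / field@pitch,
      metadata = list(simulated = TRUE, i0 = config@i0,
                      noise_sd = config@noise_sd, eps = as.list(config@eps),
                      conc_mM = config@conc, seed = config@seed,
                      mode = "film-scan"))
}

#' Generate a labelled micro-well array with parameter jitter
#'
#' Places wells of several designed types on a regular grid, jitters each
#' well's radius and depth independently (Gaussian, sd per parameter), and
#' renders the ground-truth depth field. Well types are shuffled over grid
#' positions so type is not confounded with location. Ground-truth labels
#' and analytic per-well volumes are returned alongside the field.
#'
#' @param n_per_type integer counts of wells per type.
#' @param type_specs list of [FeatureSpec-class] templates, one per type
#'   (centres are ignored; the grid supplies positions).
#' @param jitter_sd named list with elements `r` and `d`: Gaussian sd of the
#'   per-well radius and depth jitter, micrometres (0 = no jitter).
#' @param seed integer seed for placement shuffling and jitter.
#' @param pitch_um render pitch, micrometres.
#' @param spacing_um grid spacing (centre to centre); must be at least one
#'   feature diameter.
#' @return list with elements `field` (a [DepthField-class]) and `wells`
#'   (data.frame: `id`, `type`, `center_x_um`, `center_y_um`, `r_um`,
#'   `d_um`, `true_volume_nL`).
#' @export
generateWellArray <- function(n_per_type, type_specs,
                              jitter_sd = list(r = 0, d = 0), seed = 1,
                              pitch_um = 2, spacing_um = 150) {
  stopifnot(length(n_per_type) == length(type_specs), all(n_per_type >= 1))
  n <- sum(n_per_type)
  maxfp <- max(vapply(type_specs, .featureFootprint, numeric(1)))
  if (spacing_um < 2 * maxfp)
    stop("grid spacing smaller than the largest feature diameter")
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  withr::with_seed(as.integer(seed), {
    types <- sample(rep(seq_along(type_specs), n_per_type))
    pos <- seq_len(n) - 1L
    gx <- (pos %% ncols) * spacing_um + spacing_um / 2
    gy <- (pos %/% ncols) * spacing_um + spacing_um / 2
    jr <- stats::rnorm(n, 0, jitter_sd$r)
    jd <- stats::rnorm(n, 0, jitter_sd$d)
  })
  feats <- vector("list", n)
  vols <- numeric(n)
  for (i in seq_len(n)) {
    tmpl <- type_specs[[types[i]]]
    r <- max(tmpl@r + jr[i], tmpl@r * 0.1)
    d <- max(tmpl@d + jd[i], 0)
    sp <- new("FeatureSpec", kind = tmpl@kind, center = c(gx[i], gy[i]),
              r = r, d = d, params = tmpl@params)
    feats[[i]] <- sp
    vols[i] <- featureVolume(sp) / UM3_PER_NL
  }
  extent <- c(ncols, nrows) * spacing_um
  field <- renderDepthField(feats, extent, pitch_um)
  wells <- data.frame(id = seq_len(n), type = types, center_x_um = gx,
                      center_y_um = gy,
                      r_um = vapply(feats, function(f) f@r, numeric(1)),
                      d_um = vapply(feats, function(f) f@d, numeric(1)),
                      true_volume_nL = vols)
  list(field = field, wells = wells)
}

#' Draw per-group well volumes from Gaussian populations
#'
#' Fast statistical surrogate for full-image simulation of a multi-type
#' well array: volumes are drawn per group from `N(mean, sd^2)`; negative
#' draws are rejected and redrawn (the count of rejections is recorded in
#' the population metadata). Half-depth areas proportional to `volume^(2/3)`
#' (with matching relative spread) are attached so the two-feature typing
#' workflow can run on the surrogate.
#'
#' @param means group mean volumes, nL.
#' @param sds group volume standard deviations, nL (>= 0).
#' @param counts wells per group (>= 1).
#' @param seed integer seed.
#' @return a [WellPopulation-class] with columns `volume_nL`,
#'   `half_depth_area_um2`, `true_label`; metadata records `n_rejected`.
#' @examples
#' pop <- sampleWellVolumes(c(0.065, 0.080, 0.095), rep(0.0013, 3),
#'                          c(1000, 8000, 1000), seed = 7)
#' summarizeWells(wellTable(pop)$volume_nL[wellTable(pop)$true_label == 2])
#' @export
sampleWellVolumes <- function(means, sds, counts, seed = 1) {
  stopifnot(length(means) == length(sds), length(means) == length(counts),
            all(sds >= 0), all(counts >= 1))
  n_rejected <- 0L
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_along(means), function(g) {
      v <- stats::rnorm(counts[g], means[g], sds[g])
      while (any(bad <- v <= 0)) {
        n_rejected <<- n_rejected + sum(bad)
        v[bad] <- stats::rnorm(sum(bad), means[g], sds[g])
      }
      v
    })
  })
  vol <- unlist(draws)
  lab <- rep(seq_along(means), counts)
  # surrogate half-depth area: scales as V^(2/3) for geometrically similar
  # wells; 1 nL ~ 1e6 um^3 sets the um^2 magnitude
  area <- (vol * UM3_PER_NL)^(2 / 3)
  if (n_rejected > 0)
    message(n_rejected, " negative volume draw(s) rejected and redrawn")
  new("WellPopulation",
      wells = data.frame(volume_nL = vol, half_depth_area_um2 = area,
                         true_label = lab),
      metadata = list(seed = as.integer(seed), n_rejected = n_rejected,
                      means_nL = means, sds_nL = sds, counts = counts))
}
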