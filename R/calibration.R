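#' Construct a CalibrationSeries
#'
#' @param mode `"depth_series"` (absorbance at several known depths, dye
#'   concentration fixed) or `"concentration_series"` (several known
#'   concentrations, depth fixed).
#' @param fixed the fixed quantity: concentration in mM for a depth series,
#'   depth in um for a concentration series.
#' @param independent_value vector of depths (um) or concentrations (mM).
#' @param A_mean mean absorbance at each point.
#' @param A_sd absorbance sd over replicates (default 0).
#' @param n replicate count per point (default 1).
#' @param channel colour channel the series was measured in.
#' @return a [CalibrationSeries-class].
#' @export
CalibrationSeries <- function(mode, fixed, independent_value, A_mean,
                              A_sd = 0, n = 1L, channel = "B") {
  pts <- data.frame(independent_value = independent_value, A_mean = A_mean,
                    A_sd = A_sd, n = as.integer(n))
  new("CalibrationSeries", mode = mode, fixed = fixed, points = pts,
      channel = channel)
}

#' Read/write a calibration series as CSV
#'
#' CSV columns: `independent_value`, `A_mean`, `A_sd`, `n`. Mode, fixed
#' value and channel travel as commented header lines
#' (`# mode: ...`, `# fixed: ...`, `# channel: ...`).
#'
#' @param path CSV path.
#' @param series a [CalibrationSeries-class] (write).
#' @return the series (read), or `path` invisibly (write).
#' @export
readCalibrationSeries <- function(path) {
  hdr <- readLines(path, n = 10L)
  get <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("CSV header missing '# ", key, ":' line")
    trimws(sub(sprintf("^#\\s*%s:", key), "", ln[1]))
  }
  pts <- utils::read.csv(path, comment.char = "#")
  CalibrationSeries(mode = get("mode"), fixed = as.numeric(get("fixed")),
                    independent_value = pts$independent_value,
                    A_mean = pts$A_mean, A_sd = pts$A_sd, n = pts$n,
                    channel = get("channel"))
}

#' @rdname readCalibrationSeries
#' @export
writeCalibrationSeries <- function(series, path) {
  validObject(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mode: %s", series@mode),
               sprintf("# fixed: %.10g", series@fixed),
               sprintf("# channel: %s", series@channel)), con)
  utils::write.csv(series@points, con, row.names = FALSE)
  invisible(path)
}

#' Fit a calibration series and derive the extinction coefficient
#'
#' Ordinary least-squares line of mean absorbance on the independent
#' variable (free intercept; the intercept magnitude is a QC diagnostic).
#' The extinction coefficient follows from the Beer-Lambert bilinearity:
#' `epsilon = slope / c` for a depth series at fixed concentration `c`, and
#' `epsilon = slope / d` for a concentration series at fixed depth `d`. A
#' non-positive slope produces a warning and an epsilon flagged invalid.
#' Points are the per-point replicate means; a weighted fit using the
#' replicate sds is available via `weighted = TRUE`.
#'
#' @param series a [CalibrationSeries-class] (at least 3 points).
#' @param weighted use inverse-variance weights from `A_sd`/`n` (only when
#'   all sds are positive); default unweighted.
#' @return a [CalibrationFit-class].
#' @examples
#' s <- CalibrationSeries("depth_series", fixed = 6,
#'        independent_value = c(7.9, 15.7, 26.9, 49.4, 89, 160),
#'        A_mean = 0.00052 * 6 * c(7.9, 15.7, 26.9, 49.4, 89, 160))
#' fitSeries(s)  # recovers epsilon = 0.00052 mM^-1 um^-1
#' @export
fitSeries <- function(series, weighted = FALSE) {
  validObject(series)
  pts <- series@points
  if (nrow(pts) < 3L)
    stop("calibration requires at least 3 points")
  w <- NULL
  if (weighted && all(pts$A_sd > 0))
    w <- pts$n / pts$A_sd^2
  fit <- stats::lm(A_mean ~ independent_value, data = pts, weights = w)
  co <- stats::coef(fit)
  slope <- unname(co["independent_value"])
  intercept <- unname(co["(Intercept)"])
  r2 <- summary(fit)$r.squared
  slope_se <- summary(fit)$coefficients["independent_value", "Std. Error"]
  eps <- slope / series@fixed
  eps_se <- slope_se / series@fixed
  valid <- is.finite(eps) && eps > 0
  if (!valid)
    warning("non-positive calibration slope; extinction coefficient ",
            "flagged invalid")
  new("CalibrationFit", slope = slope, intercept = intercept,
      r_squared = r2, epsilon = eps, epsilon_se = eps_se,
      channel = series@channel, valid = valid,
      diagnostics = list(mode = series@mode, fixed = series@fixed,
                         n_points = nrow(pts),
                         residuals = unname(stats::residuals(fit)),
                         weighted = weighted))
}

#' Combine extinction-coefficient fits from several series
#'
#' Inverse-variance-weighted mean of the per-fit extinction coefficients
#' (equal weights when any standard error is zero or missing, as for
#' noiseless series). Invalid fits are excluded with a warning. All fits
#' must come from the same colour channel.
#'
#' @param fits list of [CalibrationFit-class] objects.
#' @return a [CalibrationFit-class] whose diagnostics list the per-fit
#'   epsilons and weights; slope/intercept/R-squared are taken from the
#'   highest-weight contributing fit.
#' @export
combineFits <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ch <- fits[[1]]@channel
  if (!all(vapply(fits, function(f) identical(f@channel, ch), logical(1))))
    stop("cannot combine fits from different colour channels")
  ok <- vapply(fits, function(f) isTRUE(f@valid), logical(1))
  if (!any(ok)) stop("no valid fits to combine")
  if (!all(ok)) warning(sum(!ok), " invalid fit(s) excluded")
  fits <- fits[ok]
  eps <- vapply(fits, function(f) f@epsilon, numeric(1))
  se <- vapply(fits, function(f) f@epsilon_se, numeric(1))
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2
       else rep(1, length(eps))
  w <- w / sum(w)
  eps_c <- sum(w * eps)
  se_c <- if (all(is.finite(se)) && all(se > 0))
    sqrt(1 / sum(1 / se^2)) else NA_real_
  lead <- fits[[which.max(w)]]
  new("CalibrationFit", slope = lead@slope, intercept = lead@intercept,
      r_squared = lead@r_squared, epsilon = eps_c, epsilon_se = se_c,
      channel = ch, valid = TRUE,
      diagnostics = list(combined_from = length(eps), epsilons = eps,
                         weights = w))
}

#' Recommend a dye concentration for a target structure depth
#'
#' For calibration linearity the design rule keeps peak absorbance below
#' `A_max` (default 0.6): the recommended concentration is
#' `c = A_max / (epsilon * d_max)`, so the deepest point of the structure
#' reaches exactly the absorbance ceiling.
#'
#' @param d_max maximum structure depth, micrometres (> 0).
#' @param epsilon extinction coefficient, `mM^-1 um^-1` (> 0).
#' @param A_max absorbance ceiling (default 0.6).
#' @return recommended concentration in mM.
#' @examples
#' recommendConcentration(160, 0.00052)  # ~7.2 mM; 6 mM satisfies A < 0.6
#' recommendConcentration(10, 0.00052)   # shallow wells want ~115 mM
#' @export
recommendConcentration <- function(d_max, epsilon, A_max = 0.6) {
  if (d_max <= 0 || epsilon <= 0)
    stop("d_max and epsilon must be positive")
  if (A_max <= 0)
    warning("A_max <= 0 gives a degenerate zero concentration")
  A_max / (epsilon * d_max)
}

#' Write/read a CalibrationFit as JSON
#' @param fit a [CalibrationFit-class].
#' @param path JSON path.
#' @return the fit (read), or `path` invisibly (write).
#' @export
writeCalibrationFit <- function(fit, path) {
  jsonlite::write_json(
    list(slope = fit@slope, intercept = fit@intercept,
         r_squared = fit@r_squared, epsilon = fit@epsilon,
         epsilon_se = fit@epsilon_se, channel = fit@channel,
         valid = fit@valid, diagnostics = fit@diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationFit
#' @export
readCalibrationFit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationFit", slope = j$slope, intercept = j$intercept,
      r_squared = j$r_squared, epsilon = j$epsilon,
      epsilon_se = if (is.null(j$epsilon_se)) NA_real_ else j$epsilon_se,
      channel = j$channel, valid = j$valid,
      diagnostics = as.list(j$diagnostics))
}
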