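# shared fixtures: noiseless scanner config and standard feature layouts

noiselessConfig <- function(...) {
  ScanSimConfig(noise_sd = 0, ...)
}

# render -> scan -> absorbance -> depth, against a blank of the same shape
roundTrip <- function(field, config) {
  img <- simulateScan(field, config)
  blank <- simulateScan(DepthField(depthMatrix(field) * 0,
                                   pixelPitch(field)), config)
  a <- computeAbsorbance(img, blank, channel = "B")
  reconstructDepth(a, epsilon = config@eps[["B"]], conc = config@conc)
}

# independent volume oracle: numeric solid-of-revolution integral of the
# radial profile rho -> depth(rho)
revolutionVolume <- function(profile, r_max) {
  stats::integrate(function(rho) 2 * pi * rho * profile(rho), 0, r_max,
                   rel.tol = 1e-10)$value
}

basinProfile <- function(r0, d) {
  function(rho) ifelse(rho <= r0, d,
                       ifelse(rho <= r0 + d,
                              sqrt(pmax(d^2 - (rho - r0)^2, 0)), 0))
}

# brute-force misclassification oracle: try every bijection of cluster
# levels onto true levels, count disagreements directly on the label
# vectors
bruteForceMisclass <- function(labels, true_labels) {
  lu <- sort(unique(labels))
  tu <- sort(unique(true_labels))
  stopifnot(length(lu) == length(tu))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(tu)) {
    mapped <- p[match(labels, lu)]
    best <- min(best, sum(mapped != true_labels))
  }
  best
}

# wrap a ground-truth DepthField as an all-valid DepthMap
asMap <- function(field) {
  d <- depthMatrix(field)
  new("DepthMap", depth = d, pitch = pixelPitch(field),
      mask = matrix(TRUE, nrow(d), ncol(d)), provenance = list())
}

# a sample with exactly the requested mean and sd (n-1 denominator)
sampleWithMoments <- function(mean, sd, n = 50) {
  x <- seq_len(n)
  z <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * z
}
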