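test_that("rendered cylinder volume matches pi r^2 d", {
  f <- FeatureSpec("cylinder_chamber", center = c(600, 600), r = 500,
                   d = 100)
  fld <- renderDepthField(list(f), c(1200, 1200), pitchFromDpi(1200))
  v <- sum(depthMatrix(fld)) * pixelPitch(fld)^2
  expect_equal(v, pi * 500^2 * 100, tolerance = 0.01)
})

test_that("rendered basin well matches the solid-of-revolution integral", {
  r0 <- 40; d <- 10.9
  f <- FeatureSpec("basin_well", center = c(100, 100), r = r0, d = d)
  fld <- renderDepthField(list(f), c(200, 200), 2)
  v <- sum(depthMatrix(fld)) * 4
  v_oracle <- revolutionVolume(basinProfile(r0, d), r0 + d)
  expect_equal(v, v_oracle, tolerance = 0.02)
  # and the closed form agrees with the independent integral
  expect_equal(featureVolume(f), v_oracle, tolerance = 1e-8)
})

test_that("cone and channel analytic volumes match numeric integration", {
  cone <- FeatureSpec("cone_well", center = c(0, 0), r = 40, d = 12)
  v_cone <- revolutionVolume(function(rho) pmax(12 * (1 - rho / 40), 0),
                             40)
  expect_equal(featureVolume(cone), v_cone, tolerance = 1e-8)
  ch <- FeatureSpec("ablated_channel", center = c(0, 0), r = 80, d = 30,
                    length = 500, width = 20)
  # transverse Gaussian integral times length
  v_ch <- stats::integrate(function(t) 30 * exp(-t^2 / (2 * 20^2)),
                           -Inf, Inf)$value * 500
  expect_equal(featureVolume(ch), v_ch, tolerance = 1e-8)
})

test_that("sagging chamber removes exactly the k_sag r^3 cap volume", {
  r <- 1250; d <- 400; k <- 0.12
  f <- FeatureSpec("sagging_chamber", center = c(1350, 1350), r = r, d = d,
                   k_sag = k)
  fld <- renderDepthField(list(f), c(2700, 2700), 10)
  v <- sum(depthMatrix(fld)) * 100
  expect_equal(v, pi * r^2 * d - k * r^3, tolerance = 0.01)
})

test_that("empty layouts, overlaps and out-of-bounds features are handled", {
  fld <- renderDepthField(list(), c(100, 100), 2)
  expect_true(all(depthMatrix(fld) == 0))
  f1 <- FeatureSpec("cylinder_chamber", center = c(50, 50), r = 20, d = 5)
  f2 <- FeatureSpec("cylinder_chamber", center = c(70, 50), r = 20, d = 5)
  expect_error(renderDepthField(list(f1, f2), c(100, 100), 2), "overlap")
  f3 <- FeatureSpec("cylinder_chamber", center = c(5, 50), r = 20, d = 5)
  expect_error(renderDepthField(list(f3), c(100, 100), 2), "outside")
})

test_that("noiseless transmitted counts follow the Beer-Lambert law", {
  cfg <- noiselessConfig()
  flat0 <- DepthField(matrix(0, 5, 5), 2)
  img0 <- simulateScan(flat0, cfg)
  expect_true(all(scanData(img0) == 60000))  # zero depth: It = I0 exactly
  fld <- DepthField(matrix(160, 5, 5), 2)
  img <- simulateScan(fld, cfg)
  # hand-evaluated: round(60000 * 10^(-0.00052 * 6 * 160)) = 19009
  expect_true(all(scanData(img)[, , 3] == 19009))
  # zero red extinction: red channel stays at the background level
  expect_true(all(scanData(img)[, , 1] == 60000))
})

test_that("scan simulation is bit-deterministic under a fixed seed", {
  fld <- DepthField(matrix(runif(400, 0, 100), 20, 20), 2)
  cfg <- ScanSimConfig(noise_sd = 100, seed = 42)
  expect_identical(scanData(simulateScan(fld, cfg)),
                   scanData(simulateScan(fld, cfg)))
  cfg2 <- ScanSimConfig(noise_sd = 100, seed = 43)
  expect_false(identical(scanData(simulateScan(fld, cfg)),
                         scanData(simulateScan(fld, cfg2))))
})

test_that("noiseless forward/inverse round trip recovers depths to 0.5%", {
  feats <- list(
    FeatureSpec("basin_well", center = c(120, 120), r = 40, d = 10.9),
    FeatureSpec("cone_well", center = c(320, 120), r = 40, d = 12),
    FeatureSpec("cylinder_chamber", center = c(220, 320), r = 60, d = 80))
  fld <- renderDepthField(feats, c(440, 440), 2)
  cfg <- noiselessConfig(conc = 6)
  dm <- roundTrip(fld, cfg)
  truth <- depthMatrix(fld)
  rec <- depthMatrix(dm)
  counts <- 60000 * 10^(-0.00052 * 6 * truth)
  # sub-micrometre rim pixels are quantization-limited (one count of
  # rounding outweighs their tiny absorbance), so the per-pixel check
  # applies from 1 um up
  sel <- truth > 1 & counts >= 10
  expect_lt(max(abs(rec[sel] - truth[sel]) / truth[sel]), 0.005)
  expect_lt(max(abs(rec[truth == 0])), 0.01)  # quantization floor on blanks
})

test_that("well arrays carry correct counts, labels and determinism", {
  specs <- list(
    FeatureSpec("basin_well", center = c(0, 0), r = 30, d = 8),
    FeatureSpec("basin_well", center = c(0, 0), r = 35, d = 10),
    FeatureSpec("cone_well", center = c(0, 0), r = 35, d = 12))
  arr <- generateWellArray(c(5, 10, 5), specs,
                           jitter_sd = list(r = 0.5, d = 0.2), seed = 3,
                           pitch_um = 2, spacing_um = 120)
  expect_equal(nrow(arr$wells), 20)
  expect_equal(as.vector(table(arr$wells$type)), c(5, 10, 5))
  arr2 <- generateWellArray(c(5, 10, 5), specs,
                            jitter_sd = list(r = 0.5, d = 0.2), seed = 3,
                            pitch_um = 2, spacing_um = 120)
  expect_identical(depthMatrix(arr$field), depthMatrix(arr2$field))
  # zero jitter: every well of a type has the same analytic volume
  arr0 <- generateWellArray(c(4, 4), specs[1:2],
                            jitter_sd = list(r = 0, d = 0), seed = 1,
                            pitch_um = 2, spacing_um = 120)
  vols <- split(arr0$wells$true_volume_nL, arr0$wells$type)
  for (v in vols) expect_equal(diff(range(v)), 0)
  expect_error(
    generateWellArray(c(4, 4), specs[1:2], seed = 1, spacing_um = 50),
    "spacing")
})

test_that("volume surrogate draws reproduce the group statistics", {
  means <- c(0.065, 0.080, 0.095)
  counts <- c(1000, 8000, 1000)
  pop <- sampleWellVolumes(means, rep(0.0013, 3), counts, seed = 7)
  w <- wellTable(pop)
  expect_equal(nrow(w), 10000)
  expect_equal(as.vector(table(w$true_label)), counts)
  # group CoV of draws matches sd/mean within 3 standard errors
  for (g in 1:3) {
    v <- w$volume_nL[w$true_label == g]
    cov_hat <- stats::sd(v) / mean(v)
    cov_true <- 0.0013 / means[g]
    se <- cov_true / sqrt(2 * counts[g])
    expect_lt(abs(cov_hat - cov_true), 3 * se)
  }
  # zero spread: sample mean equals the group mean exactly
  pop0 <- sampleWellVolumes(0.08, 0, 50, seed = 1)
  expect_equal(mean(wellTable(pop0)$volume_nL), 0.08)
  # reproducible under seed
  pop2 <- sampleWellVolumes(means, rep(0.0013, 3), counts, seed = 7)
  expect_identical(wellTable(pop)$volume_nL, wellTable(pop2)$volume_nL)
})
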