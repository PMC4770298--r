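test_that("segmentation finds every well of a regular grid exactly once", {
  arr <- generateWellArray(c(50, 50),
    list(FeatureSpec("basin_well", center = c(0, 0), r = 30, d = 10),
         FeatureSpec("cone_well", center = c(0, 0), r = 35, d = 12)),
    jitter_sd = list(r = 0.5, d = 0.3), seed = 2, pitch_um = 2,
    spacing_um = 110)
  fs <- segmentFeatures(asMap(arr$field), min_depth = 1)
  expect_equal(nrow(featureTable(fs)), 100)
  # labels are row-major by centroid: y blocks ascending, x ascending within
  tab <- featureTable(fs)
  expect_true(all(diff(round(tab$centroid_y_um / 110)) >= 0))
  # total segmented volume covers >= 99% of ground truth (noiseless)
  v <- sum(integrateVolume(asMap(arr$field), fs))
  expect_gt(v / sum(arr$wells$true_volume_nL), 0.99)
  expect_lt(v / sum(arr$wells$true_volume_nL), 1.01)
})

test_that("touching features merge into one 8-connected region", {
  # two cylinders whose rims touch on the diagonal but never overlap
  d <- matrix(0, 20, 20)
  d[5:10, 5:10] <- 10
  d[11:16, 11:16] <- 10  # corner-touching blocks: 8-connectivity merges
  fs <- segmentFeatures(new("DepthMap", depth = d, pitch = 2,
                            mask = matrix(TRUE, 20, 20),
                            provenance = list()), min_depth = 1,
                        min_area_px = 5)
  expect_equal(nrow(featureTable(fs)), 1)
})

test_that("Otsu default threshold and empty maps behave", {
  f <- FeatureSpec("cylinder_chamber", center = c(60, 60), r = 30, d = 50)
  fld <- renderDepthField(list(f), c(120, 120), 2)
  fs <- segmentFeatures(asMap(fld))  # threshold picked from the histogram
  expect_equal(nrow(featureTable(fs)), 1)
  expect_gt(fs@threshold, 0)
  empty <- segmentFeatures(asMap(renderDepthField(list(), c(50, 50), 2)))
  expect_equal(nrow(featureTable(empty)), 0)
})

test_that("volume integration is the depth sum times pixel area", {
  d <- matrix(0, 110, 110)
  d[6:105, 6:105] <- 100   # 1e4 px of 100 um at 10 um pitch
  dm <- new("DepthMap", depth = d, pitch = 10,
            mask = matrix(TRUE, 110, 110), provenance = list())
  fs <- segmentFeatures(dm, min_depth = 1, min_area_px = 1)
  expect_equal(unname(integrateVolume(dm, fs)[1]), 100)  # nL
  # basin well against the closed-form solid of revolution
  f <- FeatureSpec("basin_well", center = c(100, 100), r = 40, d = 10.9)
  fld <- renderDepthField(list(f), c(200, 200), 2)
  fsb <- segmentFeatures(asMap(fld), min_depth = 0.05, min_area_px = 1)
  vb <- unname(integrateVolume(asMap(fld), fsb)[1])
  closed <- pi * (40^2 * 10.9 + (pi / 2) * 40 * 10.9^2 +
                  (2 / 3) * 10.9^3) / 1e6
  expect_equal(vb, closed, tolerance = 0.02)
})

test_that("sagging volume deficit grows with chamber radius", {
  deficit <- function(r) {
    f <- FeatureSpec("sagging_chamber", center = c(r + 60, r + 60), r = r,
                     d = 400, k_sag = 0.12)
    fld <- renderDepthField(list(f), c(2 * r + 120, 2 * r + 120),
                            pitchFromDpi(1200))
    m <- asMap(fld)
    fs <- segmentFeatures(m, min_depth = 1, min_area_px = 1)
    1 - sum(integrateVolume(m, fs)) / (pi * r^2 * 400 / 1e6)
  }
  d_small <- deficit(1250)
  d_large <- deficit(6500 / 2)  # keep the raster modest
  expect_gt(d_small, 0)
  expect_gt(d_large, d_small)
  # deficit scales like k r^3 / (pi r^2 d) = k r / (pi d)
  expect_equal(d_small, 0.12 * 1250 / (pi * 400), tolerance = 0.05)
})

test_that("half-depth area separates flat-bottomed from conical wells", {
  pitch <- 1
  cyl <- FeatureSpec("cylinder_chamber", center = c(60, 60), r = 40, d = 20)
  cone <- FeatureSpec("cone_well", center = c(180, 60), r = 40, d = 20)
  cone2 <- FeatureSpec("cone_well", center = c(300, 60), r = 40, d = 40)
  fld <- renderDepthField(list(cyl, cone, cone2), c(360, 120), pitch)
  m <- asMap(fld)
  fs <- segmentFeatures(m, min_depth = 0.2, min_area_px = 1)
  tab <- featureTable(fs)
  expect_equal(nrow(tab), 3)
  hda <- halfDepthArea(m, fs)
  # flat bottom: half-depth area equals the full region area
  expect_equal(unname(hda[1]) / tab$area_um2[1], 1, tolerance = 0.02)
  # cone: the half-depth contour is at half the mouth radius -> 1/4 area
  # (the median-smoothed reference maximum sits slightly below the apex,
  # admitting a thin extra annulus, so the check is one-sided-biased)
  mouth <- pi * 40^2
  expect_equal(unname(hda[2]) / mouth, 0.25, tolerance = 0.1)
  # scale invariance: a deeper cone with the same mouth keeps the ratio
  expect_equal(unname(hda[3]), unname(hda[2]), tolerance = 0.02)
  # all-zero region is rejected
  expect_error(halfDepthArea(m, fs, labels = 99), "unknown")
})

test_that("cross-sections sample the expected analytic profiles", {
  pitch <- 2
  f <- FeatureSpec("cylinder_chamber", center = c(150, 150), r = 60, d = 80)
  fld <- renderDepthField(list(f), c(300, 300), pitch)
  # flat blank region: constant (zero) profile
  flat <- crossSection(fld, c(10, 10), c(290, 10))
  expect_true(all(flat$depth_um == 0))
  # through the cylinder centre: a top-hat of width 2r within one pitch
  cs <- crossSection(fld, c(10, 150), c(290, 150))
  width <- diff(range(cs$position_um[cs$depth_um > 40]))
  expect_lte(abs(width - 120), 2 * pitch)
  # Gaussian channel: fitted transverse width within 5% of truth
  ch <- FeatureSpec("ablated_channel", center = c(150, 150), r = 80, d = 30,
                    length = 260, width = 20)
  fldc <- renderDepthField(list(ch), c(300, 300), pitch)
  csg <- crossSection(fldc, c(150, 30), c(150, 270))
  fit <- stats::nls(depth_um ~ a * exp(-(position_um - m)^2 / (2 * s^2)),
                    data = csg, start = list(a = 25, m = 110, s = 15))
  expect_equal(abs(unname(stats::coef(fit)["s"])), 20, tolerance = 0.05)
  expect_error(crossSection(fld, c(10, 10), c(10, 10)), "degenerate")
  expect_error(crossSection(fld, c(-5, 10), c(50, 10)), "inside")
})

test_that("longitudinal profiles expose sidewall variability", {
  pitch <- 2
  uniform <- FeatureSpec("ablated_channel", center = c(400, 150), r = 80,
                         d = 30, length = 760, width = 20)
  fld <- renderDepthField(list(uniform), c(800, 300), pitch)
  lp <- longitudinalProfile(fld, c(100, 150), c(700, 150), n_slices = 16,
                            halfwidth_um = 90)
  expect_length(lp$slices, 16)
  # translationally uniform channel: zero sd envelope
  expect_lt(max(lp$sd_depth_um), 1e-9)
  # sidewall jitter only: sd concentrated at the walls, ~0 at the floor
  jit <- FeatureSpec("ablated_channel", center = c(400, 150), r = 80,
                     d = 30, length = 760, width = 20,
                     width_jitter_sd = 3, jitter_seed = 4)
  fldj <- renderDepthField(list(jit), c(800, 300), pitch)
  lpj <- longitudinalProfile(fldj, c(100, 150), c(700, 150), n_slices = 16,
                             halfwidth_um = 90)
  centre <- which.min(abs(lpj$offset_um))
  expect_lt(lpj$sd_depth_um[centre], 0.1)
  expect_gt(max(lpj$sd_depth_um), 10 * max(lpj$sd_depth_um[centre], 0.01))
  expect_error(longitudinalProfile(fld, c(100, 150), c(700, 150),
                                   n_slices = 1), "at least 2")
  expect_error(longitudinalProfile(fld, c(100, 150), c(700, 150),
                                   halfwidth_um = 500), "outside")
})

test_that("volume is additive over regions and invariant to rotation", {
  arr <- generateWellArray(c(6, 6),
    list(FeatureSpec("basin_well", center = c(0, 0), r = 25, d = 8),
         FeatureSpec("cone_well", center = c(0, 0), r = 30, d = 10)),
    jitter_sd = list(r = 1, d = 0.5), seed = 5, pitch_um = 2,
    spacing_um = 100)
  m <- asMap(arr$field)
  fs <- segmentFeatures(m, min_depth = 0.5, min_area_px = 1)
  vols <- integrateVolume(m, fs)
  expect_equal(sum(vols),
               sum(depthMatrix(m)[fs@labels > 0]) * 4 / 1e6)
  # 90 degree rotation permutes pixels: total volume is exactly conserved
  td <- t(depthMatrix(m))
  rot <- td[nrow(td):1, , drop = FALSE]
  mrot <- new("DepthMap", depth = rot, pitch = 2,
              mask = matrix(TRUE, nrow(rot), ncol(rot)),
              provenance = list())
  fsr <- segmentFeatures(mrot, min_depth = 0.5, min_area_px = 1)
  expect_equal(sum(integrateVolume(mrot, fsr)), sum(vols))
})

test_that("volumes converge under pitch refinement", {
  f <- FeatureSpec("basin_well", center = c(100, 100), r = 40, d = 10.9)
  vol_at <- function(p) {
    fld <- renderDepthField(list(f), c(200, 200), p)
    m <- asMap(fld)
    sum(integrateVolume(m, segmentFeatures(m, min_depth = 0.05,
                                           min_area_px = 1)))
  }
  v4 <- vol_at(4); v2 <- vol_at(2)
  expect_lt(abs(v2 - v4) / v2, 0.01)
})
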