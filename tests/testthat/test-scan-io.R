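test_that("scan TIFF round trip is lossless and carries the resolution", {
  fld <- DepthField(matrix(runif(100, 0, 150), 10, 10), 2)
  img <- simulateScan(fld, ScanSimConfig(noise_sd = 50, seed = 1))
  path <- withr::local_tempfile(fileext = ".tiff")
  writeScan(img, path)
  back <- readScan(path)
  expect_identical(scanData(back), scanData(img))
  # resolution follows the rendered field pitch (2 um -> 12700 dpi)
  expect_equal(scanDpi(back), 12700)
  expect_equal(pixelPitch(back), 2)
  # explicit override beats the sidecar
  expect_equal(scanDpi(readScan(path, dpi = 1200)), 1200)
})

test_that("8-bit input is accepted with a warning and upscaled by 257", {
  path <- withr::local_tempfile(fileext = ".tiff")
  a <- array(rep(c(0, 128, 255) / 255, each = 16), dim = c(4, 4, 3))
  tiff::writeTIFF(a, path, bits.per.sample = 8L, reduce = FALSE)
  expect_warning(img <- readScan(path, dpi = 1200), "8-bit")
  expect_true(all(scanData(img) %in% (c(0, 128, 255) * 257)))
})

test_that("dpi to pitch arithmetic follows 25400/dpi", {
  expect_equal(pitchFromDpi(12800), 1.984375)
  expect_equal(round(pitchFromDpi(12800)), 2)
  expect_equal(pitchFromDpi(1200), 25400 / 1200)
  expect_equal(round(pitchFromDpi(1200), 2), 21.17)
})

test_that("channel splitting isolates the dye's spectral signature", {
  f <- FeatureSpec("cylinder_chamber", center = c(60, 60), r = 30, d = 80)
  fld <- renderDepthField(list(f), c(120, 120), 2)
  img <- simulateScan(fld, ScanSimConfig(noise_sd = 30, seed = 5))
  red <- splitChannel(img, "R")
  blue <- splitChannel(img, "B")
  inside <- depthMatrix(fld) > 0
  # red extinction is zero: structure indistinguishable from background
  expect_lt(abs(mean(red[inside]) - mean(red[!inside])), 5)
  # blue absorbs: counts over the structure strictly below background
  expect_lt(mean(blue[inside]), mean(blue[!inside]) - 1000)
  # a gray scan splits into three identical channels
  gray <- ScanImage(array(rep(matrix(30000, 4, 4), 3), c(4, 4, 3)),
                    dpi = 1200)
  expect_identical(splitChannel(gray, "R"), splitChannel(gray, "B"))
})

test_that("absorbance follows A = log10(I0/It) with masking and modes", {
  mk <- function(count) ScanImage(array(count, c(3, 3, 3)), dpi = 12800)
  blank <- mk(60000)
  expect_true(all(absorbance(computeAbsorbance(blank, blank)) == 0))
  # hand-checked instance of the defining formula
  a <- computeAbsorbance(mk(18985), blank)
  expect_equal(absorbance(a)[1, 1], log10(60000 / 18985), tolerance = 1e-12)
  expect_equal(round(absorbance(a)[1, 1], 4), 0.4997)
  # noiseless chamber at the calibrated product epsilon*c*d
  fld <- DepthField(matrix(89, 4, 4), 2)
  cfg <- noiselessConfig()
  am <- computeAbsorbance(simulateScan(fld, cfg),
                          simulateScan(DepthField(matrix(0, 4, 4), 2), cfg))
  expect_equal(mean(absorbance(am)), 0.00052 * 6 * 89, tolerance = 1e-3)
  # zero transmitted counts are clamped and masked invalid
  az <- computeAbsorbance(mk(0), blank)
  expect_true(all(!validMask(az)))
  expect_true(all(is.finite(absorbance(az))))
  # region mode: scalar I0 from a background patch of the sample itself
  samp <- mk(30000)
  samp@data[1, 1, ] <- 60000
  ar <- computeAbsorbance(samp, c(1, 1, 1, 1))
  expect_equal(absorbance(ar)[2, 2], log10(2), tolerance = 1e-12)
  expect_error(computeAbsorbance(samp, c(1, 5, 1, 1)), "outside")
  expect_error(
    computeAbsorbance(mk(100), ScanImage(array(2, c(4, 4, 3)), 12800)),
    "shapes")
})

test_that("absorbance increases strictly as transmission drops", {
  blank <- ScanImage(array(60000, c(2, 2, 3)), dpi = 12800)
  counts <- seq(50000, 5000, by = -5000)
  a <- vapply(counts, function(ct)
    absorbance(computeAbsorbance(
      ScanImage(array(ct, c(2, 2, 3)), 12800), blank))[1, 1],
    numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("N-scan averaging reduces absorbance noise like 1/sqrt(N)", {
  fld <- DepthField(matrix(60, 80, 80), 2)
  cfg0 <- noiselessConfig()
  blank0 <- simulateScan(DepthField(matrix(0, 80, 80), 2), cfg0)
  truth <- absorbance(computeAbsorbance(simulateScan(fld, cfg0), blank0))
  mkmap <- function(seed)
    computeAbsorbance(
      simulateScan(fld, ScanSimConfig(noise_sd = 150, seed = seed)),
      blank0)
  maps <- lapply(1:9, mkmap)
  rms <- function(m) sqrt(mean((absorbance(m) - truth)^2))
  r1 <- rms(maps[[1]])
  r4 <- rms(averageScans(maps[1:4]))
  r9 <- rms(averageScans(maps))
  expect_equal(r4 / r1, 1 / 2, tolerance = 0.2)
  expect_equal(r9 / r1, 1 / 3, tolerance = 0.2)
  # averaging identical maps is the identity
  same <- averageScans(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_equal(absorbance(same), absorbance(maps[[1]]))
  bad <- maps[[1]]; bad@channel <- "G"
  expect_error(averageScans(list(maps[[1]], bad)), "channel")
})

test_that("integer-shift registration re-aligns displaced repeat scans", {
  f <- FeatureSpec("cylinder_chamber", center = c(80, 80), r = 30, d = 80)
  fld <- renderDepthField(list(f), c(160, 160), 2)
  cfg <- noiselessConfig()
  blank <- simulateScan(DepthField(matrix(0, 80, 80), 2), cfg)
  ref <- computeAbsorbance(simulateScan(fld, cfg), blank)
  shifted <- ref
  shifted@absorbance <- rbind(matrix(0, 3, 80),
                              ref@absorbance[1:77, ])
  avg <- averageScans(list(ref, shifted), align = "integer")
  # after registration the shifted copy coincides with the reference
  core <- 10:70
  expect_equal(absorbance(avg)[core, core], absorbance(ref)[core, core],
               tolerance = 1e-10)
})

test_that("float map persistence round-trips values, mask and metadata", {
  fld <- DepthField(matrix(runif(64, 0, 120), 8, 8), 2)
  dm <- roundTrip(fld, noiselessConfig())
  dm@mask[2, 3] <- FALSE
  p1 <- withr::local_tempfile(fileext = ".tiff")
  writeFloatMap(dm, p1)
  back <- readDepthMap(p1)
  expect_equal(depthMatrix(back)[validMask(dm)],
               depthMatrix(dm)[validMask(dm)], tolerance = 1e-5)
  expect_identical(validMask(back), validMask(dm))
  expect_equal(back@provenance$epsilon, 0.00052)
  am <- computeAbsorbance(simulateScan(fld, noiselessConfig()),
                          simulateScan(DepthField(matrix(0, 8, 8), 2),
                                       noiselessConfig()))
  p2 <- withr::local_tempfile(fileext = ".tiff")
  writeFloatMap(am, p2)
  am2 <- readAbsorbanceMap(p2)
  expect_equal(absorbance(am2), absorbance(am), tolerance = 1e-6)
  expect_identical(am2@channel, "B")
  expect_error(readDepthMap(p2), "expected")
})
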