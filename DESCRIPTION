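Package: scanprof
Title: Flatbed-Scanner Absorbance Profilometry of Microfluidic Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts transmission scans of dye-filled transparent
    microfluidic structures into calibrated three-dimensional depth maps by
    Beer-Lambert absorbance inversion. Provides extinction-coefficient
    calibration from depth and concentration series, per-pixel depth
    reconstruction, multi-scan averaging, channel cross-section and
    longitudinal profiling, chamber and micro-well volume integration,
    population statistics with coefficient-of-variation reporting, and
    k-means typing of well sub-groups. A forward-model simulator renders
    ground-truth depth fields (cylindrical chambers, isotropically etched
    basin wells, laser-ablated cone wells and channels, sagging laminated
    chambers) and synthesizes 16-bit scanner images with sensor noise, so
    the full inverse pipeline can be exercised without scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-scan.R'
    'scan-io.R'
    'calibration.R'
    'reconstruction.R'
    'morphometry.R'
    'population.R'
    'pipeline.R'
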