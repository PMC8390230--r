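Package: rootvec
Title: Vectorization and Trait Quantification of Monocot Root System
    Architecture from Segmented 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless toolkit for vectorizing monocot root system
    architecture (RSA) from segmented X-ray CT style volumes. Loads a
    directory of 8-bit grayscale slice images as a 3D volume, represents
    the RSA as a depth-2 tree (base node, single roots, relay nodes)
    persisted as "rinfo" JSON, converts operator-registered nodes into
    dense polylines by straight, spline, or center-of-gravity (COG)
    tracking interpolation, and computes single-root traits (growth
    angle, length) and RSA-level traits (mean angle, total length, root
    distribution index) with CSV export. Includes a synthetic phantom
    generator producing tubular root volumes with known ground-truth
    geometry, and a command-line interface for the full
    import-vectorize-calculate-export pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
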