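Package: uwmosaic
Title: Underwater Image Enhancement and Seam-Optimized Mosaicking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building large-field-of-view photomosaics of shallow
    seabed (coral and benthic survey) imagery from a downward-facing
    underwater camera. Implements attenuation-aware dark-channel image
    restoration driven by the wavelength dependence of optical attenuation
    in water, feature-based registration with similarity or projective
    warps, optimal seam-line search by dynamic programming restricted to
    dilated superpixel boundaries, and Laplacian-pyramid blending confined
    to a stripe around the seam. A synthetic survey generator produces
    ground-truthed seabed scenes, per-channel Beer-Lambert degradation and
    overlapping camera views with known warps for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
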