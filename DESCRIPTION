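Package: chromaxial
Title: Post Hoc Chromatic Aberration Correction for Multi-Channel
    Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures and corrects depth-dependent axial chromatic
    aberration in multi-channel volumetric confocal images. Inter-channel
    shifts are measured as intensity-weighted centroid displacements of
    fluorescent calibration beads or in-sample "guide stars", a linear
    axial-shift-versus-depth regression is fitted per channel pair,
    sample sufficiency is assessed by a noncentral-F power analysis
    (Cohen's f-squared), and non-reference channels are realigned by
    nearest-frame z reassignment. Includes a synthetic bead/guide-star
    phantom generator with exact ground truth, TIFF stack and ImageJ ROI
    input/output, and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
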