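Package: dimorphbone
Title: Cortical Bone Porosity, Geometry and Raman Mineral Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sexually dimorphic cortical bone phenotypes
    from micro-computed tomography and Raman spectroscopy. Implements 3D
    intracortical porosity extraction as the negative imprint of calcified
    tissue (threshold, keep-largest-region, morphological closing, mask
    intersection), per-pore morphometry with animal-specific separation of
    osteocyte lacunae from vascular canals, kernel-density analysis of
    lacunar-volume distributions with bimodal split detection, whole-bone
    cross-sectional geometry (CSA, principal second moments of area, polar
    moment, cortical thickness, ellipticity, calibrated BMD), Raman
    preprocessing and pseudo-Voigt deconvolution of the phosphate envelope
    into ACP/OCP/CAP species, and the study statistics (two-way ANOVA,
    paired one-tailed littermate t tests, delta-delta-Ct, significance
    heat-map binning). Ships ground-truthed synthetic phantom generators so
    every stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    minpack.lm,
    car,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
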