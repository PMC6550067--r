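Package: myelometry
Title: Synthetic Correlative Light-Electron Microscopy Morphometry of
    Myelinated Axons
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ground-truthed morphometry of myelinated nerve
    fibres imaged by correlative light microscopy (LM) and serial
    block-face scanning electron microscopy (SBF-SEM).  Provides a 3D
    phantom generator (fibres, nodes of Ranvier with paranodal lamellae,
    somatic fiducials) rendered as EM-like and LM-like stacks with a
    configurable inter-modality misregistration; a contrast-gradient
    bounded region-growing ("blow") segmenter with serial-section
    propagation; digital re-sectioning (multiplanar reslicing,
    centerline-orthogonal cross sections, thickness-matched projections);
    line-scan extraction of axon (d) and fibre (D) diameters with
    diameter-, area- and volume-based g-ratio estimators, paranodal
    lamella counting and one-way ANOVA group comparison; and a landmark
    shift analysis quantifying LM/EM registration accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
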