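Package: hri
Title: Hemodynamic Response Imaging from Dual Gas-Challenge BOLD MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hemodynamic response imaging (HRI): analysis of paired
    BOLD fMRI acquisitions under hyperoxic (carbogen, 95% O2 + 5% CO2) and
    hypercapnic (95% air + 5% CO2) gas challenges. Estimates voxelwise percent
    signal change (dS) maps with block-design significance masking, z-normalizes
    them against a reference region, computes vascular reactivity mismatch (VRM)
    maps that highlight voxels responding to oxygenation but not to vasodilation
    (a signature of immature, angiogenic vessels), and summarizes lesion and
    contralateral volumes of interest with a vascular reactivity index. Includes
    healthy-cohort reference aggregation and a synthetic dual-challenge BOLD
    phantom generator with known ground truth so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
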