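Package: fibcount
Title: Absolute Nanoparticle Dose Quantification from FIB/SEM Slice-and-View Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the absolute number of metallic nanoparticles inside a
    single cell from a focused ion beam / scanning electron microscope (FIB/SEM)
    slice-and-view image stack. Provides drift registration, tilted-view
    correction and denoising; trench-anchored cell segmentation; edge-based
    nanoparticle cluster detection with per-cluster multilevel Otsu refinement;
    calibration of the secondary-electron escape depth and single-particle
    reference volumes from isolated particles; and per-cluster particle counts
    via a shading-corrected volume formula, aggregated into a whole-cell dose
    report with a cluster-size distribution. A physically motivated synthetic
    phantom generator renders ground-truthed stacks (subsurface exponential
    glow, anterior occlusion, per-slice drift, noise) so that every stage is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
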