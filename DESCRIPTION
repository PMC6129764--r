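Package: restbold
Title: Resting-State fMRI Post-Processing: Denoising, Voxel-Wise
    Metrics, Connectivity and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for resting-state functional MRI
    post-processing. Reads and writes NIfTI-1 volumes (gzip-transparent),
    builds nuisance-regression designs (tissue means, Friston 24-parameter
    motion model, trends), censors high-motion frames by framewise
    displacement, and applies an ideal band-pass filter with mirrored
    extension. Computes voxel-wise spontaneous-activity metrics (amplitude
    of time series, ALFF/fALFF, regional homogeneity via Kendall's W,
    functional connectivity density with bit-packed adjacency and region
    growing, functional connectivity strength), ROI functional
    connectivity (Pearson, partial, Fisher-z), complex-network metrics
    with degree-preserving null models, head-motion and temporal-SNR
    quality control, voxel-wise group t-tests, image-based meta-analysis
    combiners, and multiple-comparison corrections. A synthetic phantom
    module generates band-limited signals, motion traces and labelled
    atlases with known ground truth, and a config-driven batch runner
    processes whole studies with one command.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
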