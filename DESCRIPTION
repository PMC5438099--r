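Package: mesoconn
Title: Headless Processing Pipeline for Widefield Mesoscale Brain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An ordered, manifest-tracked processing pipeline that turns raw
    widefield calcium-imaging stacks into seed-pixel correlation maps and
    cross-trial region-of-interest correlation matrices. Provides stack I/O
    (headerless RAW, multipage TIFF, NPY persistence), a JSON-backed project
    manifest with per-file manipulation history, FFT-based rigid registration
    (translation, rotation, scale) against a blood-vessel-emphasising
    reference frame, a bregma-anchored coordinate system with CSV RoI import
    and polygon masking, temporal operations (frame trimming, zero-phase
    Chebyshev type-I bandpass, dF/F0, global signal regression, concatenation,
    division, evoked averaging, standard-deviation maps), zero-lag Pearson
    connectivity (seed-pixel correlation maps, RoI correlation matrices with
    cross-trial dispersion), and a ground-truth synthetic-stack generator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
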