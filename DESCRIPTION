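Package: magicquant
Title: Quantification of Mitochondrial Import Reporters from Yeast Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipelines for quantifying mitochondrial import of
    misfolded proteins (the MAGIC pathway) in budding yeast: per-cell split-GFP
    intensity scoring from two-channel confocal z-stacks (z-sum projection,
    random-walker background segmentation, marker-based watershed separation of
    adjoining cells, organelle masking by per-cell fractional thresholding,
    median reporter intensity within mitochondria), nuclear-cytoplasmic ratio
    scoring from an RFP nuclear marker, per-cell aggregate (punctum) detection,
    cycloheximide-chase degradation kinetics with background subtraction and
    exponential-decay fitting, and Kyte-Doolittle hydropathy profiling. A
    synthetic-scene generator renders yeast-like two-channel stacks and chase
    time courses with known ground truth, so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
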