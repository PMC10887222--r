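Package: matbeeg
Title: Synthetic MATB-II EEG Workload Studies and End-to-End Convolutional Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying EEG-based mental-workload classification in
    multitasking. Generates complete synthetic MATB-II studies (block
    protocols, subtask event schedules, simulated operator behavior, NASA-TLX
    ratings, and forward-modeled 24-channel EEG with workload-dependent
    frontal-theta/parietal-alpha structure and subtask-specific signatures),
    and runs the full analysis pipeline on them: band-pass filtering, average
    re-referencing, channel standardization and downsampling; fixed-length
    segmentation with task-load and multi-label subtask labeling;
    session-exclusive train/test splitting; a 1-D temporal convolutional
    encoder-decoder with task-load (4-class) and subtask-detection
    (3-label) heads trained with AdamW under a warmup/constant/cosine
    learning-rate schedule; and evaluation (confusion matrices,
    precision/recall/F1, ROC AUC, operator error rates) with one-way
    ANOVA and Tukey HSD analysis of the subjective workload ratings.
    EEG is read and written as EDF; logs and ratings as TSV/CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
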