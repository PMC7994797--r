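Package: anatomaly
Title: Weakly Supervised Anatomically-Resolved Abnormality Detection for
    Whole-Body PET/CT
Version: 0.1.0
Authors@R:
    person("anatomaly", "developers", email = "anatomaly@example.org",
           role = c("aut", "cre"))
Description: Extracts per-region abnormality probabilities from free-text
    FDG-PET/CT radiology reports using an anatomical-region ontology, a
    wordpiece token classifier and noisy-OR label propagation, then trains a
    multi-task 3D scan classifier with per-region soft spatial attention
    against those probabilistic weak labels. Includes guided-backpropagation
    saliency and attention-map interpretation, the evaluation statistics used
    for this class of model (AUROC, worklist sensitivity curves, bootstrap
    confidence intervals, paired permutation tests, median-of-seeds
    ensembling), and a synthetic report/volume generator with token-level and
    voxel-level ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
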