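Package: trandaug
Title: Temporally Consistent Random Augmentation and Activity Recognition for Long Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements TRandAugment, a three-parameter (M, N, T) random data
    augmentation policy for long videos that splits each video into temporal
    segments and applies randomly sampled image transformations consistently
    within each segment, together with its per-frame (RandAugment) and
    per-video (UniformRandAugment) special cases. Also provides a causal
    single-stage temporal convolutional network for frame-wise activity
    recognition trained with a class-weighted cross-entropy loss, the
    per-video macro-averaged evaluation protocol used in surgical workflow
    analysis, frame-sequence input/output utilities, and a synthetic
    surgical-like video generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jpeg
Config/testthat/edition: 3
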