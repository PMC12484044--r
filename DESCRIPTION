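Package: anaa
Title: Adaptive Noise-Augmented Attention for Transformer Fine-Tuning on
    Longitudinal Medical Code Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements adaptive noise-augmented attention (ANAA), a
    fine-tuning augmentation for Transformer encoders that injects
    Gaussian noise with matrix-adaptive mean and standard deviation into
    post-softmax self-attention score matrices and smooths the result
    with a discrete 2D Gaussian kernel. Ships a compact multi-head
    Transformer encoder with masked-language-model pre-training and a
    [CLS] classification head, a tokenization pipeline for longitudinal
    visit sequences of ICD/ATC-style medical codes, a seeded synthetic
    cohort generator with planted outcome motifs, baseline augmentations
    (raw noise, naive attention masking, DropAttention, embedding and
    feed-forward noise), cross-validated evaluation with rank-based AUC,
    and attention-distribution diagnostics (scaled histograms,
    polarization index, receptive-field curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
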