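Package: setfuse
Title: Permutation-Invariant Fusion of Image Sets with Continual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses an arbitrary number (N >= 2) of co-registered source images
    (multi-modal medical, infrared/visible, bracketed-exposure, multi-focus
    stacks) into one composite image with a single arity-agnostic convolutional
    network. Every input stream is processed by shared convolutional weights and
    collapsed only by element-wise max pooling, so the fused result is exactly
    invariant to the order and multiplicity of the inputs. Training combines a
    reference mean-absolute-error loss with the no-reference MEF-SSIM structural
    loss, and multiple fusion tasks are learned sequentially with Elastic Weight
    Consolidation to avoid catastrophic forgetting. Includes a synthetic
    multi-focus training-data simulator (basal/shape partition masks plus
    Gaussian defocus blending), a procedural exposure-stack generator, luminance
    /chrominance handling with a weighted chroma fusion rule, and evaluation
    metrics (entropy, mutual information, MEF-SSIM). The network, its gradients
    (reverse-mode tape) and the Adam optimizer are implemented in base R matrix
    algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
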