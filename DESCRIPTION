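Package: proj2proj
Title: Self-Supervised Low-Dose CT Reconstruction via Projection-Domain Masking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sparse-view, low-dose computed tomography reconstruction
    built around a self-supervised training scheme in which noisy projections
    serve as their own training targets. A J-invariant perturbation replaces a
    cycling subset of sinogram pixels by their neighbour means; a convolutional
    encoder-decoder denoises the filtered back projection of the perturbed
    sinogram, its output is re-projected with a differentiable parallel-beam
    Radon operator, and the loss is evaluated only on the perturbed subset
    against the unperturbed measurements. Includes phantom generators
    (Shepp-Logan, random ellipses), a sinogram noise model, filtered back
    projection, SART and total-variation baselines, PSNR/SSIM metrics, and
    benchmark orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
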