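Package: popkernel
Title: Inductive Bias of Neural Population Codes via Kernel Learning Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring the inductive bias of neural population
    codes. Builds inner-product (representational similarity) kernels from
    response matrices, eigendecomposes them under an arbitrary stimulus
    measure, and predicts the generalization error of a linear delta-rule
    readout as a function of sample size from the kernel spectrum and the
    target's eigenmode decomposition. Includes synthetic code generators
    (von Mises tuning-curve populations, kernel-matched spectral codes, a
    Gabor simple/complex-cell model of primary visual cortex, and
    rate-based recurrent-network temporal codes), empirical learning-curve
    simulation with a biologically plausible delta rule, code-task
    alignment via cumulative power distributions, and a metabolic
    efficiency analysis based on kernel-preserving random rotations with
    optimal nonnegativity shifts (RROS), including gradient descent over
    the orthogonal manifold and lifetime/population sparseness statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
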