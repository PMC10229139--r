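Package: sccausal
Title: Constraint-Based Causal Discovery for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A workflow for inferring causal gene-gene interaction networks
    from single-cell RNA-seq expression matrices. Provides expression loading
    and filtering, HSIC-based (BAHSIC) and ensemble-tree feature selection,
    seven pluggable conditional-independence tests (partial-correlation
    Fisher-z, HSIC and distance-covariance statistics with gamma or
    permutation nulls, and random-Fourier-feature approximations RCIT/RCoT),
    the order-independent PC algorithm with Meek-rule orientation to a CPDAG,
    consensus-network and reliability scoring (structural Hamming distance,
    similarity clustering, TPR against a consensus, run stability, spike-in
    separation QC), and a synthetic DAG/structural-equation generator with
    scRNA-seq-style dropout for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
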