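Package: LiquidEngine
Title: Adaptive Self-Benchmarking Implementation Selection for Bioimage Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An adaptive run-time engine for bioimage analysis methods that ship
    several interchangeable implementations of the same algorithm. The engine
    records wall-clock run times per implementation, device and input signature
    in an append-only local store, summarizes them into fast/slow split
    statistics, detects transient delays and estimates their probability of
    recurrence, and selects the implementation to execute either
    deterministically (no delay) or stochastically by inverse-square weighting
    of adjusted expected run times. Ships three multi-implementation kernels
    (2D convolution, Catmull-Rom upsampling, nonlocal-means denoising), a
    manual benchmarking module with packaged factory-default benchmark tables,
    a synthetic image generator, and a delay-injection harness for studying
    adaptive backend switching under induced slowdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    Rcpp,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
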