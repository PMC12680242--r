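Package: attribench
Title: Benchmarking Feature Attribution for Deep Genotype-to-Phenotype Models
Version: 0.1.0
Authors@R: person("Avery", "Quinn", email = "avery.quinn@example.org",
    role = c("aut", "cre"))
Description: Quantifies the interpretability of feed-forward neural networks
    trained to predict quantitative traits from SNP dosages, along three axes:
    attribution recall against spiked-in causal variants with known additive,
    dominant, recessive, and epistatic architectures; attribution precision
    against permutation decoy features; and attribution stability across an
    ensemble of independently trained models. The three axes are combined into
    a composite score by a half-life transform and a geometric mean. Includes
    the synthetic machinery (Hardy-Weinberg cohort generator, spike-in SNP
    simulator, and deterministic decoy permutations) that makes the benchmark
    self-contained, a native implementation of Saliency, Integrated Gradients,
    DeepLIFT (rescale rule), Gradient SHAP and SmoothGrad with exact gradient
    access, a per-SNP linear association baseline, and PLINK 1 binary I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
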