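Package: famkernel
Title: Region-Based Kernel Association Tests for Quantitative Traits in
    Related Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kernel-machine (SKAT-type) region-based association testing of
    quantitative traits in samples of related individuals.  Fits the null
    polygenic mixed model y = X alpha + u + e with cov(u) = sigma2_g R by
    REML over an eigendecomposition of the relationship matrix R, and applies
    the GRAMMAR+ phenotype transformation so that simple-regression score
    statistics on the transformed trait approximate the exact mixed-model
    score statistics, letting kernel machinery built for unrelated samples be
    used on family data.  Region statistics are weighted sums of per-marker
    scores with beta(MAF)-density weights; P values come from the
    chi-square-mixture null via Imhof characteristic-function inversion with
    a moment-matched fallback, or from residual permutation.  Includes
    pedigree and genomic relationship matrices, kinship principal components,
    VCF/pedigree/phenotype/GRM readers, a gene-dropping simulator, and a
    calibration and power evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
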