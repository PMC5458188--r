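Package: snpgxe
Title: Case-Control SNP Association and Gene-Environment Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-SNP case-control studies: Pearson chi-square
    tests of covariate and genotype distributions, Hardy-Weinberg equilibrium
    testing, crude odds ratios with Woolf confidence intervals, maximum
    likelihood logistic regression under codominant/dominant/recessive/additive
    genetic codings, label-permutation empirical p-values for multiple-testing
    correction, stratified analysis with multiplicative (product-term) and
    additive (RERI, bootstrap) gene-environment interaction tests, EM
    estimation of multi-locus haplotype frequencies with pairwise linkage
    disequilibrium, and a synthetic case-control cohort generator with
    simulation-based power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
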