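Package: hapimpute
Title: Genotype Imputation from Large Reference Panels with
    Surrogate-Family Template Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype imputation for association studies under the Li and
    Stephens haplotype-copying hidden Markov model.  An MCMC algorithm
    alternates haplotype-phase sampling at SNPs typed in the study with
    analytic haploid imputation of untyped SNPs, where each study haplotype
    is imputed from a custom reference panel of its Hamming-nearest
    reference haplotypes ("surrogate family members").  Includes readers
    and writers for hap/legend/gen/sample and genetic-map text files, a
    cross-validation harness (leave-one-out and every-Nth-SNP masking,
    dosage R-squared, minor-allele-frequency binning, Hudson F_ST panel
    ordering), and a seedable simulator of structured multi-population
    haplotype panels with SNP-array and low-coverage discovery
    ascertainment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
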