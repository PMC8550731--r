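Package: sexqtl
Title: Sex Chromosome Identification in F2 Interspecific Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sex-determining chromosomes in F2 interspecific
    crosses genotyped at SNP markers (RAD-seq style VCFs). Implements
    diagnostic-site ascertainment between grandparental species, the site and
    individual filter cascade used for reduced-representation data,
    sex-contrasted genotype-frequency statistics with a sex-permutation test
    that distinguishes XY from ZW heterogamety, single-marker ANOVA and
    hidden-Markov interval scans with LOD and percent-variance-explained,
    tracing of Y- and W-linked alleles back to the grandparental species, and
    windowed heterozygosity and d_xy on candidate sex chromosomes. A forward
    simulator of F0 x F0 -> F1 -> F2 crosses with configurable
    sex-determination architectures, recombination map functions and
    sequencing noise makes every stage verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
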