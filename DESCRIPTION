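Package: onsetmod
Title: Genetic Modifiers of Huntington's Disease Age at Onset in Family Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modifier studies of Huntington's disease age at onset in
    family-structured cohorts. Simulates pedigree-structured cohorts with CAG
    repeat transmission and planted modifier variants; fits the log-linear
    CAG-to-onset model with population-specific intercepts and derives the
    residual age-at-onset phenotype; estimates pairwise identity-by-descent by
    the method of moments, reconstructs families by exhaustive relatedness
    merging and builds the kinship matrix; runs kinship-corrected mixed-model
    genome-wide association with conditional, extreme-dichotomous, stratified
    and meta-analyses and polygenic modification scoring; reconstructs a
    consensus disease haplotype from independently phased trios with
    Mendelian-error screening; and scans haplotype pairs for allele-specific
    CRISPR PAM sites.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
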