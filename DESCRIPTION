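Package: otsneo
Title: Off-the-Shelf Shared Neoantigen Panel Construction and Cohort Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building shared ("off-the-shelf") neoantigen panels
    from recurrent somatic mutations and validating them against patient
    cohorts. Includes readers for MAF-style mutation tables, HLA class I
    allele-frequency tables and NetMHCpan-style binding predictions; a
    recurrent-mutation catalog with cumulative patient-coverage curves; a
    pairwise co-occurrence/mutual-exclusivity screen with exact tests and
    false-discovery-rate control; HLA allele-set selection for target
    population coverage under allelic and Hardy-Weinberg genotypic models;
    mutant/wild-type epitope enumeration; percentile-rank binder
    classification; population neoantigen-frequency estimation; patient-level
    mutation-HLA coverage accounting; microsatellite-instability
    classification; ELISpot reactivity calls; and a fully seeded synthetic
    cohort simulator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
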