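Package: honeyGBS
Title: Colony-Level SNP Genotyping of Honey Bees from Honey Environmental DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for targeted amplicon genotyping-by-sequencing
    of honey bee (Apis mellifera) colonies from environmental DNA extracted
    from honey. Estimates whole-colony SNP allele frequencies from per-marker
    REF/ALT read depths, computes sample and marker call-rate quality control,
    quantifies duplicate-aliquot concordance with the two-way absolute-agreement
    intraclass correlation coefficient, assigns samples to the A/C/M/O
    evolutionary lineages by classical multidimensional scaling against
    reference genotype panels, and reports trait-associated marker allele
    frequencies and fixation. Includes a haplodiploid colony and pooled-
    sequencing simulator (Balding-Nichols lineage differentiation, queen/drone/
    worker genetics, matrix-quality-dependent depth tiers and marker dropout)
    that emits VCFs, sample sheets and truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
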