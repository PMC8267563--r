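Package: dtcqc
Title: Quality Control for Direct-to-Consumer Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses raw genotype downloads from direct-to-consumer (DTC)
    genotyping providers (23andMe, AncestryDNA, FamilyTreeDNA, MyHeritage,
    deCODEme) and single-sample VCFs, optionally inside zip/gzip/bzip2
    containers, into a normalized genome representation. Performs file-level
    sanity checks (genome build detection, reference-genome similarity,
    reverse-strand detection and repair, NGS versus array-derived VCF triage),
    per-SNP filtering, fingerprint clustering of genotyping-array designs by
    the number of positions two files do not share, per-cluster blacklisting
    of SNPs whose cohort allele frequencies are implausible against a
    reference panel, and pairwise genotype concordance for duplicate and
    close-relative detection. Includes a seeded synthetic-data generator so
    the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
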