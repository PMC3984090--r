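Package: haploviz
Title: Region-Based SNP Haplotype Clustering, Haplogroup Partitioning and
    Pictorial Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters reference-anchored SNP matrices into haplotypes using
    an identity distance (proportion of mismatched genotype calls, missing
    data excluded) and UPGMA, partitions samples into reference-like and
    divergent haplogroups by cutting the tree at a chosen branching tier,
    merges several reference-aligned datasets with reference fill-in,
    calls functional alleles of candidate genes at registered causative
    SNPs, scans for deletion signatures as runs of missing calls, and
    renders deterministic pictorial SNP maps with tree and gene-annotation
    tracks. Ships a seeded synthetic-fixture generator with planted
    haplogroup structure so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    png,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape,
    jpeg,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
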