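Package: varguide
Title: Variant-Aware CRISPR-Cas9 Guide RNA Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Designs CRISPR-Cas9 single guide RNAs (sgRNAs) against genomes
    carrying SNPs and small insertions or deletions. Given a reference genome
    (FASTA) and a variant set (VCF or CSV), the package reconstructs
    variant-applied template sequences, enumerates candidate 20-nt
    protospacer + PAM designs on both strands that cover each variant, filters
    poly-T stretches that terminate RNA polymerase III transcription, and
    reports side-by-side wild-type and variant-allele designs with
    position-weight-matrix efficiency scores and specificity scores derived
    from an exact, mismatch-tolerant genome-wide off-target search. A seeded
    fixture generator produces synthetic genomes and variant sets for fully
    offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    parallel,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
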