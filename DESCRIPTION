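Package: nomeseqr
Title: Joint Chromatin Accessibility and DNA Methylation Analysis for
    NOMe-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of nucleosome occupancy and methylome
    sequencing (NOMe-seq) data. Classifies reference cytosines into the
    informative trinucleotide contexts (WCG for endogenous CpG
    methylation, GCH for M.CviPI accessibility, GCG/CCG excluded),
    reads bismark-style per-cytosine call tables, estimates enzyme
    efficiency and bisulfite conversion from a lambda phage spike-in,
    calls nucleosome-depleted regions and positioned nucleosomes by a
    sliding-window chi-squared test against the genome background,
    builds TSS metaprofiles and promoter accessibility-expression
    correlations, identifies cell-type-specific proximal NDRs through a
    rank-correlation filter, summarises accessibility over annotated
    elements and repeat subfamilies, and ships a fully parameterised
    synthetic-data generator with a machine-readable truth set for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
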