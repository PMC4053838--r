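Package: wseq
Title: Sexually Dimorphic Expression and W-Chromosome Transcriptome Analysis for ZW Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sexually dimorphic gene expression in
    species with ZW sex chromosomes (female heterogamety), built around
    early avian embryo transcriptomes. Provides negative-binomial GLM
    likelihood-ratio tests for sex-biased expression within and between
    tissues with empirical-Bayes dispersion moderation, TMM library-size
    normalisation, FPKM and Z-dosage-compensation estimation,
    chromosome-class tallies and gene-set enrichment; discovery filters for
    W-linked transcripts (female-specific expression screen, retroviral ORF
    and pseudogene removal); gametologue-guided scaffolding that
    reconstructs full-length W transcripts from fragmented multi-source
    assemblies using the Z gametologue cDNA as an ordering scaffold;
    Nei-Gojobori dN/dS with sliding windows and combined W+Z versus ZZ
    expression comparison; and a synthetic ZW mini-genome generator that
    emulates the statistical structure of such experiments for validation
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
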