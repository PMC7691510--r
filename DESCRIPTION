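Package: nmdscan
Title: Premature Termination Codon Localization and Nonsense-Mediated
    Decay Escape Prediction
Version: 1.0.0
Authors@R:
    person("A.", "Delcourt", email = "a.delcourt@example.org",
           role = c("aut", "cre"))
Description: Locates premature termination codons (PTCs) arising from
    coding variants in a protein-coding transcript, classifies them
    against the four positional rules of nonsense-mediated mRNA decay
    (NMD) surveillance (last exon, exon-junction proximity, long exon,
    start proximity), delineates the transcript region in which a PTC is
    expected to trigger decay, and weighs exome-versus-transcriptome
    allele fractions as evidence of mutant-transcript degradation.
    Includes a parser for cDNA-level HGVS variant descriptions, protein
    consequence (p.) nomenclature generation from mutant translation, a
    seeded simulator producing transcripts, PTC-introducing variants with
    ground truth and DNA/RNA read counts, a command-line interface, and a
    bundled SOD1 (NM_000454.4) transcript model with the catalogue of
    ALS-associated truncating variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
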