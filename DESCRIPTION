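Package: sspsearch
Title: Sample-Specific Proteogenomic Search Databases and Target-Decoy
    Peptide-Spectrum Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-sample protein search databases from RNA-Seq
    evidence -- single-nucleotide variant calls (VCF), splice-junction
    alignments (BED12) and transcript abundances (TPM) -- and searches
    MS/MS spectra against them with a Morpheus-style target-decoy engine
    at 1% FDR. Nonsynonymous variants become single amino acid variant
    (SAV) protein records, unannotated splice junctions are translated
    in three frames into junction-spanning polypeptides, and reference
    records for transcripts below 1 TPM are removed. Peptides identified
    only by the sample-specific database are classified as novel splice
    junction, SAV, or recovered reference peptides. Includes a seeded
    synthetic-data generator (toy genome, planted variants and
    exon-skipping junctions, simulated spectra) with a ground-truth
    manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
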