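---
title: "Sample-specific proteogenomic search databases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific proteogenomic search databases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspsearch)
```

## The problem

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
protein sequence database, so a peptide that is not in the database cannot
be identified. For organisms with incompletely annotated genomes, the
reference proteome misses real gene products: unannotated splice forms and
individual coding variants. RNA-Seq from the same tissue sample observes
exactly the transcripts that are present, including their variants and
splice junctions, and can therefore be converted into a *sample-specific
search database* (SSdb) that (i) adds protein records the reference lacks
and (ii) removes records whose transcripts are not expressed. This package
implements that conversion, a Morpheus-style target-decoy search engine to
consume the resulting FASTA, and the downstream comparison that classifies
peptides found only by the SSdb.

## The three database workflows

**Single amino acid variants (SAV).** Exonic single-nucleotide variants
from a VCF are located in each overlapping transcript's CDS. The codon
substitution is performed strand-aware (the alternate allele is
complemented for minus-strand transcripts) and classified as synonymous,
nonsynonymous, stop-gain or stop-loss. Each nonsynonymous variant yields
one full-length variant protein -- the reference protein with the single
substitution applied -- tagged `p.<Ref><Pos><Alt>`. Full-length records
(rather than peptide windows) let the ordinary digestion code generate
missed-cleavage peptides spanning the variant; whether a matched peptide
actually covers the substituted residue is enforced later, at
classification time. One substitution per record: when a transcript
carries several variants we do not enumerate haplotype combinations, which
mirrors the one-record-per-SNV structure of the upstream variant stream
and avoids exponential blowup. Genotypes are ignored (any called alternate
allele produces a record) and stop-loss variants are skipped, because the
extension past the annotated stop is undefined without a 3' readthrough
policy.

**Splice junctions (SJ).** Observed junctions arrive as two-block BED12
records; the intron is the gap between the blocks. A junction is *novel*
iff its exact intron coordinates (plus strand, when both strands are
known) are absent from the gene model's intron set -- flank lengths and
read counts play no role in identity, and no read-count threshold is
applied. For each novel junction, up to 66 nt of flanking sequence per
side (capped by the aligned block lengths) is spliced and translated in
all three frames -- six when the strand is unknown -- with each
translation split at stop codons. A segment is kept only if it spans the
junction with at least one residue contributed by each side and reaches
the search engine's minimum peptide length; its provenance records the
junction key, orientation, frame and the junction-spanning residue pair.
The 66 nt default (22 residues per side) accommodates fully tryptic
peptides with two missed cleavages on either side of the junction.

**Abundance reduction.** Transcript abundances (RSEM-style TPM) reduce the
*reference* stream only: a reference record is kept iff its transcript is
at or above 1 TPM. The boundary is literal -- records *below* one TPM are
excluded, 1.0 is retained. Transcripts absent from the table are treated
as unquantified and excluded (with a count in the reduction report). SAV
and SJ records are not reduced; they exist only because RNA-Seq evidence
produced them.

The three streams are concatenated (REF, SAV, SJ) into one database.
Exact duplicate sequences within a stream are merged with combined
provenance; a SAV or SJ record whose sequence is identical to a reference
record carries no new information and is dropped with a flag. The
reference database (REFdb) is the degenerate assembly: all reference
proteins, no evidence streams, no reduction.

## The search engine

The engine reproduces the behaviour implied by the Morpheus parameter
block used for all searches:

| parameter | value |
|---|---|
| assumed precursor charge | 2--4 (when unannotated) |
| MS/MS peak filtering | 400 most intense peaks |
| protease | trypsin, no proline rule |
| max missed cleavages | 2 |
| initiator methionine | variable |
| fixed modification | carbamidomethyl C, +57.02146 Da |
| variable modification | oxidation M, +15.99491 Da |
| max modification isoforms | 1024 per peptide |
| precursor tolerance | +/- 2.1 Da, monoisotopic, no isotope correction |
| product tolerance | +/- 0.025 Da, monoisotopic |
| max FDR | 1% |

Digestion cleaves after every K and R, *including* before proline, emits
all products with up to two missed cleavages, and for protein-N-terminal
peptides starting with M also emits the Met-trimmed form. Peptide length
bounds default to 6--50 residues; they are configuration, not a quantity
the upstream settings fix. Peptides containing `X` (from ambiguous
codons) are dropped -- their mass is undefined.

Scoring is the Morpheus score: the number of theoretical singly-charged
b/y fragments with an observed peak within +/-0.025 Da, plus the summed
intensity of matched peaks as a fraction of the spectrum's total ion
current. Each observed peak credits at most one fragment (nearest in m/z,
equidistant ties to the lower-m/z fragment), which makes the score
deterministic. Product peaks are treated as singly charged; true charge
deconvolution of fragments is a known limitation. The best PSM per
spectrum is kept, with ties resolved target-over-decoy, then by the
lexicographically smaller peptide -- a reproducibility choice that also
avoids inflating the decoy count through arbitrary tie resolution.

Decoys are whole-entry sequence reversals (one per target,
`DECOY_`-prefixed), which preserve the length distribution and amino-acid
composition of the target set exactly. The FDR estimate at a score
threshold is `decoys / targets` at or above the threshold (ties counted
together, 0 when no targets); the q-value of a PSM is the minimum FDR
over thresholds at or below its score. Targets with q <= 0.01 are
accepted. Accepted peptides map to all target proteins containing them;
proteins with identical peptide sets merge into one group and groups
whose peptide set is a proper subset of another's are discarded
(parsimony).

## Comparison and classification

Accepted peptides are compared between the SSdb and REFdb searches per
sample, with peptide identity taken as the bare sequence: modification
states are collapsed, and I/L are kept distinct (the databases distinguish
them even though their masses do not). Peptides found only under the SSdb
are classified in a fixed order:

1. **reference-recovered** -- the peptide is a substring of some reference
   protein. It was identifiable in principle under the REFdb and crossed
   the FDR line only under the smaller database.
2. **SAV** -- the peptide maps to a SAV record *and* covers the
   substituted residue.
3. **novel-SJ** -- the peptide maps to an SJ record *and* spans the
   junction residue pair.

Evaluating the reference rule first makes novelty calling conservative:
nothing explainable by the reference is ever called novel. A peptide that
maps to a SAV or SJ record without meeting its coverage condition (for
example a tryptic sub-peptide of an off-frame junction polypeptide that
stays on one side of the splice point) is not a reference substring
either; it falls back to the category of the only record type that
contains it. A peptide matching no database record at all indicates index
corruption and is a hard error. The three categories partition the
SSdb-only set by construction.

## The synthetic-data generator

Real inputs at this scale (a mammalian genome, tens of millions of reads,
Orbitrap raw files) are neither practical nor necessary to validate the
machinery, so the package ships a generator that emulates the statistical
structure the analysis assumes, with a complete ground-truth manifest.

*Genome.* `simulate_genome_and_truth()` builds one chromosome with
multi-exon genes on both strands; CDS are ATG-initiated, stop-terminated,
free of internal stops, and exons include the stop codon while CDS
records exclude it (the Ensembl GTF convention). Exon boundaries sit on
codon boundaries, so skipping any internal exon preserves the reading
frame. That is a deliberate simplification: frame-preserving exon
skipping is the mechanism that produces a verifiable expected junction
peptide, at the cost of not exercising phase-shifted junctions (which
real data contain and which the three-frame translation handles anyway).

*Evidence.* `simulate_sample_evidence()` plants nonsynonymous and
synonymous SNVs at sampled CDS positions, verifying the intended codon
effect at generation time; novel junctions are exon skips joining
annotated donor and acceptor sites, emitted as two-block BED12 alongside
all annotated junctions so novelty detection is non-trivial. Abundances
are log-normal (default meanlog `log(20)`, sdlog 1.5 -- a right-skewed
distribution spanning roughly 1--400 TPM, the shape RSEM output has on
liver RNA-Seq) with an exact requested fraction forced below 1 TPM and
one transcript pinned at exactly 1.0 to exercise the retention boundary.

*Spectra.* `simulate_spectra()` samples tryptic peptides from the
database (stratified so variant-covering SAV and junction-spanning SJ
peptides are represented), builds b/y peaks with Gaussian m/z jitter
(default sd 0.005 Da, under a fifth of the product tolerance), drops 20%
of fragment peaks, adds 30 uniform noise peaks, and sets the precursor
m/z exactly at charge 2 or 3. Foreign ("noise") spectra come from tryptic
peptides of a *shuffled target protein*, verified absent from every
database sequence. The protein-level shuffle matters: shuffling a peptide
in place preserves its residue composition, so its fragment peaks
systematically share prefix/suffix sums with its one source candidate --
a correlated false-match mode that reversed-protein decoys cannot model
and that no plausible contaminant exhibits. Shuffling at the protein
level mirrors the protein-level decoy transformation and keeps the
foreign precursor-mass distribution decoy-like.

What the generator does *not* emulate: isotope envelopes, fragment charge
states >1, retention time, chimeric spectra, intensity structure beyond
uniform draws, UTRs and non-coding transcripts, sequencing errors in the
evidence files. Passing tests therefore demonstrate the correctness of
the database construction, search arithmetic, FDR machinery and
classification logic on in-model data -- not robustness to every
pathology of real instrument output.

## Numerical and design choices

* Coordinates are 0-based half-open internally, converted at the I/O
  boundary (GTF/GFF 1-based inclusive; BED 0-based half-open).
* Minus-strand CDS is reverse-complemented after concatenation, never
  per-exon, so codons crossing exon boundaries are handled correctly.
* Monoisotopic residue masses follow the standard IUPAC/Unimod tables;
  water 18.010565 Da, proton 1.007276 Da. Tests cross-check every mass
  against an elemental-composition oracle to 1e-4 Da.
* Modification isoforms enumerate M-oxidation subsets in binary-counting
  order over ascending site positions; the 1024-isoform cap truncates
  deterministically.
* The candidate index is a mass-sorted table with binary search over the
  +/-2.1 Da window; a peptide shared by several proteins is indexed once
  and is a decoy only if *all* its parents are decoys.
* Degenerate inputs: empty spectra are an error at scoring; spectra with
  no in-window candidate yield no PSM and are counted; an empty database
  union is an error; palindromic decoys are allowed and flagged.

## Validation scale

The test suite validates digestion, masses, fragments and translation
against independent oracles (brute-force enumeration, elemental
composition, the Biostrings codon table) on hundreds to a thousand random
cases, and runs the full pipeline on a 20-gene genome with 10 planted
nonsynonymous SNVs, 5 synonymous SNVs, 5 exon-skipping junctions, 30% of
transcripts below 1 TPM, and 200 true + 100 foreign spectra -- sizes at
which every stage's output is exactly checkable against the manifest
within seconds. FDR calibration averages the empirical false-discovery
proportion over 10 generator seeds. The database-reduction experiment
uses a 60-gene genome with 90% of transcripts unexpressed, making the
reference database more than five times the sample-specific one, and
degraded spectra (45% of fragment peaks dropped, 0.008 Da jitter) so that
weak-but-true identifications sit near the 1% FDR line, where the
database-size effect on q-values is visible: every shared PSM has a
q-value under the smaller database no larger than under the full one, and
some peptides are recovered only under the smaller database -- the
qualitative effect the reduction workflow exists to produce.

## Known limitations

Indels, multi-nucleotide variants and splice-site-disrupting variants are
out of scope, as are gene fusions, semi-tryptic search, isotope-error
correction, PTM open search and fragment charge deconvolution. The
comparator's I/L distinction means mass spectrometry alone could not have
distinguished some "novel" peptides from their I/L twins; with a
reference proteome containing both forms, rule 1 absorbs them.
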