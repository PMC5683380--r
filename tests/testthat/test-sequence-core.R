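test_that("genome FASTA reading normalizes and validates records", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  expect_equal(read_genome_fasta(f), c(chr1 = "ACGT"))

  writeLines(c(">c1 some description", "acgt", "ACG"), f)
  expect_equal(read_genome_fasta(f), c(c1 = "ACGTACG"))

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), f)
  expect_error(read_genome_fasta(f), "c1")

  writeLines(character(), f)
  expect_error(read_genome_fasta(f), "empty")
})

test_that("GTF coordinates convert to 0-based half-open and introns derive", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", ".", "exon", 31, 40, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", ".", "exon", 11, 20, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", ".", "CDS", 11, 20, ".", "+", 0,
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", ".", "CDS", 31, 40, ".", "+", 2,
          'gene_id "g"; transcript_id "t";', sep = "\t")
  ), f)
  genes <- read_gene_models(f, "gtf")
  tx <- genes[[1]]$transcripts[["t"]]
  # exons sorted by start despite out-of-order input
  expect_equal(unname(tx$exons), rbind(c(10, 20), c(30, 40)))
  ann <- genome_annotation(NULL, genes)
  introns <- annotation_introns(ann)
  expect_equal(introns$start, 20)
  expect_equal(introns$end, 30)
})

test_that("mixed-strand transcripts and stray CDS are rejected", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", ".", "exon", 11, 20, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", ".", "exon", 31, 40, ".", "-", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")
  ), f)
  expect_error(read_gene_models(f, "gtf"), "mixed strands")

  writeLines(c(
    paste("c1", ".", "exon", 11, 20, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", ".", "CDS", 25, 28, ".", "+", 0,
          'gene_id "g"; transcript_id "t";', sep = "\t")
  ), f)
  expect_error(read_gene_models(f, "gtf"), "outside its exon")
})

test_that("spliced CDS concatenates in transcription order", {
  mk_ann <- function(chrom, strand, cds) {
    tx <- list(id = "t", gene_id = "g", chrom = "c1", strand = strand,
               exons = cds, cds = cds, frame = 0L, complete = TRUE)
    genome_annotation(c(c1 = chrom),
                      list(list(id = "g", strand = strand,
                                transcripts = list(t = tx))))
  }
  a <- mk_ann("ATGCCCAAA", "+", rbind(c(0L, 3L), c(6L, 9L)))
  expect_equal(spliced_cds_sequence(a, "t"), "ATGAAA")
  a <- mk_ann("ATGCAT", "-", rbind(c(0L, 6L)))
  expect_equal(spliced_cds_sequence(a, "t"), "ATGCAT")  # palindromic
  expect_error(spliced_cds_sequence(a, "nope"), "unknown transcript")

  # random two-exon minus-strand transcripts vs an independent route:
  # reverse-complement of the concatenation
  set.seed(7)
  for (i in 1:25) {
    chrom <- random_nt(60)
    cds <- rbind(c(5L, 20L), c(30L, 48L))
    a <- mk_ann(chrom, "-", cds)
    concat <- paste0(substr(chrom, 6, 20), substr(chrom, 31, 48))
    expect_equal(spliced_cds_sequence(a, "t"), oracle_revcomp(concat))
  }
})

test_that("protein FASTA round trip is the identity on all fields", {
  e <- protein_entries(
    accession = c("T123", "R1"),
    sequence = c("MKIAYIAK", "MKTAYIAK"),
    origin = c("SAV", "REF"),
    provenance = c("T123;p.K45R", "R1"))
  f <- tempfile(fileext = ".fasta")
  write_protein_fasta(e, f)
  hdr <- readLines(f)[1]
  expect_equal(hdr, ">sav|T123|T123;p.K45R")
  back <- read_protein_fasta(f)
  expect_equal(as.data.frame(back), as.data.frame(e))

  # decoys keep the DECOY_ prefix on the full header
  db <- add_decoys(assemble_database(protein_entries("P1", "MKR", "REF", "P1")))
  write_protein_fasta(db$entries, f)
  expect_true(any(startsWith(readLines(f), ">DECOY_ref|P1|")))
  expect_equal(as.data.frame(read_protein_fasta(f)),
               as.data.frame(db$entries))
})

test_that("protein FASTA round trip holds on random entries", {
  set.seed(11)
  n <- 120
  origin <- sample(c("REF", "SAV", "SJ"), n, replace = TRUE)
  prov <- ifelse(origin == "SAV", sprintf("T%d;p.K%dR", 1:n, 1:n),
          ifelse(origin == "SJ",
                 sprintf("c1:%d-%d(+);ori=+;frame=0;span=3-4", 1:n, 101:(100 + n)),
                 sprintf("T%d", 1:n)))
  e <- protein_entries(sprintf("ACC%04d", 1:n),
                       vapply(sample(8:40, n, TRUE), random_protein, ""),
                       origin, prov)
  f <- tempfile(fileext = ".fasta")
  write_protein_fasta(e, f)
  expect_equal(as.data.frame(read_protein_fasta(f)), as.data.frame(e))
})

test_that("entry validation enforces the invariants", {
  expect_error(protein_entries(c("A", "A"), c("MK", "MR")), "duplicate")
  expect_error(protein_entries("A", "MX"), "invalid sequence")
  expect_error(protein_entries("A", "MK*"), "invalid sequence")
  expect_error(protein_entries("A", "MKR", origin = "SAV",
                               provenance = "T1"), "exactly one")
  expect_silent(protein_entries("A", "MKR", origin = "SAV",
                                provenance = "T1;p.K45R"))
})
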