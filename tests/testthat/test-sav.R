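# tiny_annotation() CDS reads ATG AAA CCC GGG TTT AGA -> "MKPGFR"

test_that("variant effects match the codon-table oracle on both strands", {
  for (strand in c("+", "-")) {
    ann <- tiny_annotation(strand)
    cds <- spliced_cds_sequence(ann, "TX1")
    expect_equal(cds, "ATGAAACCCGGGTTTAGA")
    # map every CDS offset back to genome, mutate, verify codon arithmetic
    for (off in c(3L, 5L, 8L, 12L)) {
      tx <- ann$transcripts[["TX1"]]
      gpos <- sspsearch:::.cds_offset_to_genomic(tx, off)
      ref_g <- substr(ann$chromosomes[["c1"]], gpos + 1, gpos + 1)
      cds_base <- substr(cds, off + 1, off + 1)
      alt_cds <- setdiff(c("A", "C", "G", "T"), cds_base)[1]
      alt_g <- if (strand == "+") alt_cds else chartr("ACGT", "TGCA", alt_cds)
      eff <- classify_variant_effect(ann, list(chrom = "c1", pos = gpos,
                                               ref = ref_g, alt = alt_g))
      expect_equal(eff$cds_offset, off)
      expect_equal(eff$codon_index, off %/% 3)
      ref_cod <- substr(cds, (off %/% 3) * 3 + 1, (off %/% 3) * 3 + 3)
      alt_cod <- ref_cod
      substr(alt_cod, off %% 3 + 1, off %% 3 + 1) <- alt_cds
      expect_equal(eff$ref_codon, ref_cod)
      expect_equal(eff$alt_codon, alt_cod)
      exp_ref <- unname(Biostrings::GENETIC_CODE[ref_cod])
      exp_alt <- unname(Biostrings::GENETIC_CODE[alt_cod])
      expect_equal(eff$ref_residue, exp_ref)
      expect_equal(eff$alt_residue, exp_alt)
      exp_cat <- if (exp_ref == exp_alt) "synonymous"
                 else if (exp_alt == "*") "stop_gain" else "nonsynonymous"
      expect_equal(eff$category, exp_cat)
    }
  }
})

test_that("specific codon changes classify as expected", {
  ann <- tiny_annotation("+")
  tx <- ann$transcripts[["TX1"]]
  g <- function(off) sspsearch:::.cds_offset_to_genomic(tx, off)
  chrom <- ann$chromosomes[["c1"]]
  base_at <- function(p) substr(chrom, p + 1, p + 1)
  # CDS offset 3: AAA -> GAA, K -> E (nonsynonymous)
  e <- classify_variant_effect(ann, list(chrom = "c1", pos = g(3L),
                                         ref = base_at(g(3L)), alt = "G"))
  expect_equal(e$category, "nonsynonymous")
  expect_equal(c(e$ref_residue, e$alt_residue), c("K", "E"))
  # CDS offset 5: AAA -> AAG, K -> K (synonymous)
  e <- classify_variant_effect(ann, list(chrom = "c1", pos = g(5L),
                                         ref = base_at(g(5L)), alt = "G"))
  expect_equal(e$category, "synonymous")
  # intron position -> noncoding
  e <- classify_variant_effect(ann, list(chrom = "c1", pos = 14L,
                                         ref = base_at(14L), alt = "C"))
  expect_equal(e$category, "noncoding")
  # ref mismatch carries both bases
  wrong <- setdiff(c("A", "C", "G", "T"), base_at(g(3L)))[1]
  expect_error(
    classify_variant_effect(ann, list(chrom = "c1", pos = g(3L),
                                      ref = wrong, alt = "T")),
    "mismatch")
})

test_that("SAV entries apply exactly one substitution with the p. tag", {
  ref <- protein_entries("TX1", "MKTAYIAK", "REF", "TX1")
  eff <- data.frame(transcript_id = "TX1", codon_index = 2L,
                    ref_residue = "T", alt_residue = "I",
                    category = "nonsynonymous", stringsAsFactors = FALSE)
  sav <- build_sav_entries(eff, ref)
  expect_equal(sav$sequence, "MKIAYIAK")
  expect_equal(sav$provenance, "TX1;p.T3I")

  # synonymous effects emit nothing; duplicates collapse
  eff2 <- rbind(eff, eff,
                data.frame(transcript_id = "TX1", codon_index = 1L,
                           ref_residue = "K", alt_residue = "K",
                           category = "synonymous", stringsAsFactors = FALSE))
  expect_equal(nrow(build_sav_entries(eff2, ref)), 1L)

  # stop gain truncates; short truncations are dropped
  eff3 <- data.frame(transcript_id = "TX1", codon_index = 6L,
                     ref_residue = "A", alt_residue = "*",
                     category = "stop_gain", stringsAsFactors = FALSE)
  sav3 <- build_sav_entries(eff3, ref, min_length = 6L)
  expect_equal(sav3$sequence, "MKTAYI")
  expect_equal(nrow(build_sav_entries(eff3, ref, min_length = 7L)), 0L)

  expect_error(build_sav_entries(
    data.frame(transcript_id = "NOPE", codon_index = 1L, ref_residue = "K",
               alt_residue = "R", category = "nonsynonymous"), ref),
    "unknown transcript")
})

test_that("planted nsSNPs are recovered exactly from generated VCFs", {
  truth <- simulate_genome_and_truth(12, 3, seed = 21)
  ev <- simulate_sample_evidence(truth, n_nssnp = 8, n_syn = 4,
                                 n_novel_junctions = 2, seed = 22,
                                 dir = tempfile())
  calls <- read_vcf_calls(ev$vcf, "S1")
  expect_equal(nrow(calls), 12L)
  eff <- classify_variant_effects(truth$annotation, calls)
  expect_equal(sum(eff$category == "nonsynonymous"), 8L)
  expect_equal(sum(eff$category == "synonymous"), 4L)
  ref <- reference_entries(truth$annotation)
  sav <- build_sav_entries(eff, ref)
  expect_equal(nrow(sav), 8L)
  want <- ev$snvs[ev$snvs$category == "nonsynonymous", ]
  expect_setequal(sav$provenance, paste0(want$transcript_id, ";", want$tag))
  # each entry differs from its reference protein at exactly one position
  tags <- parse_sav_tag(sav$provenance)
  for (i in seq_len(nrow(sav))) {
    p_ref <- ref$sequence[ref$accession == tags$transcript_id[i]]
    expect_equal(nchar(sav$sequence[i]), nchar(p_ref))
    diffs <- which(strsplit(sav$sequence[i], "")[[1]] !=
                     strsplit(p_ref, "")[[1]])
    expect_equal(diffs, tags$position[i])
  }
})
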