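bed12_line <- function(chrom = "c1", start = 100L, sizes = c(20L, 20L),
                       starts = c(0L, 80L), strand = "+", score = 10L,
                       name = "J1") {
  end <- start + starts[length(starts)] + sizes[length(sizes)]
  paste(chrom, start, end, name, score, strand, start, end, "0",
        length(sizes), paste(sizes, collapse = ","),
        paste(starts, collapse = ","), sep = "\t")
}

test_that("BED12 junction arithmetic follows the block structure", {
  f <- tempfile(fileext = ".bed")
  writeLines(bed12_line(), f)
  j <- read_junction_bed(f)
  expect_equal(j$intron_start, 120L)   # chromStart + blockSize1
  expect_equal(j$intron_end, 180L)     # chromStart + blockStart2
  expect_equal(j$left_flank, 20L)
  expect_equal(j$right_flank, 20L)
  expect_equal(j$read_count, 10L)

  writeLines(bed12_line(strand = "."), f)
  expect_equal(read_junction_bed(f)$strand, ".")

  writeLines(bed12_line(sizes = c(10L, 10L, 10L), starts = c(0L, 40L, 80L)), f)
  expect_error(read_junction_bed(f), "expected 2 blocks")
})

test_that("novelty detection is an exact coordinate set difference", {
  jdf <- function(chrom, s, e, strand = "+")
    data.frame(chrom = chrom, intron_start = s, intron_end = e,
               strand = strand, left_flank = 20L, right_flank = 20L,
               read_count = 5L, name = NA, stringsAsFactors = FALSE)
  tx <- list(id = "t", gene_id = "g", chrom = "c1", strand = "+",
             exons = rbind(c(50L, 100L), c(200L, 260L)),
             cds = rbind(c(50L, 100L), c(200L, 260L)),
             frame = 0L, complete = TRUE)
  ann <- genome_annotation(NULL, list(list(id = "g", strand = "+",
                                           transcripts = list(t = tx))))
  obs <- rbind(jdf("c1", 100L, 200L), jdf("c1", 100L, 300L))
  nov <- detect_novel_junctions(obs, ann)
  expect_equal(nov$intron_end, 300L)
  # observed == annotated -> empty
  expect_equal(nrow(detect_novel_junctions(jdf("c1", 100L, 200L), ann)), 0L)
  # unknown strand matches on coordinates alone
  expect_equal(nrow(detect_novel_junctions(jdf("c1", 100L, 200L, "."), ann)), 0L)
  # opposite known strand does not match
  expect_equal(nrow(detect_novel_junctions(jdf("c1", 100L, 200L, "-"), ann)), 1L)

  # random junction sets vs a brute-force set-difference oracle
  set.seed(31)
  for (rep in 1:20) {
    coords <- unique(cbind(sample(100:400, 30, TRUE), sample(500:900, 30, TRUE)))
    ann_idx <- sample(nrow(coords), 12)
    exlist <- lapply(ann_idx, function(i)
      rbind(c(coords[i, 1] - 30L, coords[i, 1]),
            c(coords[i, 2], coords[i, 2] + 30L)))
    genes <- lapply(seq_along(ann_idx), function(k)
      list(id = paste0("g", k), strand = "+",
           transcripts = stats::setNames(list(list(
             id = paste0("t", k), gene_id = paste0("g", k), chrom = "c1",
             strand = "+", exons = exlist[[k]], cds = exlist[[k]],
             frame = 0L, complete = TRUE)), paste0("t", k))))
    ann2 <- genome_annotation(NULL, genes)
    obs <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i)
      jdf("c1", coords[i, 1], coords[i, 2])))
    nov <- detect_novel_junctions(obs, ann2)
    expect_setequal(paste(nov$intron_start, nov$intron_end),
                    paste(coords[-ann_idx, 1], coords[-ann_idx, 2]))
  }
})

test_that("junction translation spans the splice point in three frames", {
  # left flank ATGGCT | right flank GGTTAA: frame 0 reads ATG GCT GGT TAA
  genome <- c(c1 = paste0("ATGGCT", strrep("C", 60), "GGTTAA"))
  j <- data.frame(chrom = "c1", intron_start = 6L, intron_end = 66L,
                  strand = "+", left_flank = 6L, right_flank = 6L,
                  read_count = 3L, name = "J", stringsAsFactors = FALSE)
  e <- junction_entries(j, genome, flank_nt = 66L, min_length = 3L)
  expect_true("MAG" %in% e$sequence)
  tag <- parse_sj_tag(e$provenance[e$sequence == "MAG"])
  expect_equal(tag$frame, 0L)
  expect_equal(c(tag$span_from, tag$span_to), c(2L, 3L))

  # segments that do not reach across the junction are not retained:
  # a stop right at the junction kills the frame-0 segment
  genome2 <- c(c1 = paste0("ATGGCT", strrep("C", 60), "TAAGGG"))
  e2 <- junction_entries(
    transform(j, chrom = "c1"), genome2, flank_nt = 66L, min_length = 1L)
  expect_false(any(vapply(seq_len(nrow(e2)), function(i)
    parse_sj_tag(e2$provenance[i])$frame == 0 &&
      parse_sj_tag(e2$provenance[i])$orientation == "+", TRUE)))

  # unknown strand: both orientations attempted
  j3 <- transform(j, strand = ".")
  e3 <- junction_entries(j3, genome, flank_nt = 66L, min_length = 2L)
  expect_setequal(unique(parse_sj_tag(e3$provenance)$orientation),
                  c("+", "-"))

  expect_error(junction_entries(transform(j, intron_end = 1000L), genome),
               "outside chromosome")
})

test_that("every SJ entry contains its junction-spanning residue pair", {
  truth <- simulate_genome_and_truth(10, 4, seed = 41)
  ev <- simulate_sample_evidence(truth, 2, 1, 4, seed = 42, dir = tempfile())
  jx <- read_junction_bed(ev$bed)
  nov <- detect_novel_junctions(jx, truth$annotation)
  expect_equal(nrow(nov), 4L)
  expect_setequal(paste(nov$intron_start, nov$intron_end),
                  paste(ev$novel_junctions$intron_start,
                        ev$novel_junctions$intron_end))
  entries <- junction_db(nov, truth$genome)
  expect_gt(nrow(entries), 0)
  tags <- parse_sj_tag(entries$provenance)
  expect_true(all(tags$span_from >= 1))
  expect_true(all(tags$span_to <= nchar(entries$sequence)))
  expect_true(all(tags$span_to - tags$span_from %in% c(0L, 1L)))
  # the true in-frame translation appears among the emitted entries
  expect_true(all(ev$novel_junctions$expected_peptide %in% entries$sequence))
  # re-detecting against an annotation containing these introns yields nothing
  expect_equal(nrow(detect_novel_junctions(
    jx[!paste(jx$intron_start, jx$intron_end) %in%
         paste(nov$intron_start, nov$intron_end), , drop = FALSE],
    truth$annotation)), 0L)
})
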