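test_that("the score is matched fragments plus matched-intensity fraction", {
  s <- search_settings()
  # spectrum built so 4 of the 12 fragments of PEPTIDE match, with
  # matched intensity 800 of TIC 1000
  fr <- theoretical_fragments("PEPTIDE")
  hit <- fr$mz[c(1, 4, 7, 10)]
  sp <- list(mz = sort(c(hit, 1200, 1300)),
             intensity = c(200, 200, 200, 200, 100, 100), scan = "s")
  sp$intensity <- sp$intensity[order(c(hit, 1200, 1300))]
  expect_equal(score_psm(sp, "PEPTIDE", "", s), 4 + 800 / 1000)

  # nothing within tolerance scores zero
  sp0 <- list(mz = c(1900, 1950), intensity = c(1, 1), scan = "s")
  expect_equal(score_psm(sp0, "PEPTIDE", "", s), 0)

  # tolerance boundary: fragment at m, peaks at m+0.020 and m+0.030
  m <- fr$mz[5]
  spb <- list(mz = sort(c(m + 0.020, m + 0.030)), intensity = c(10, 90),
              scan = "s")
  spb$intensity <- c(10, 90)[order(c(m + 0.020, m + 0.030))]
  expect_equal(score_psm(spb, "PEPTIDE", "", s), 1 + 10 / 100)

  expect_error(score_psm(list(mz = numeric(), intensity = numeric()),
                         "PEPTIDE", "", s), "empty")
})

test_that("precursor windows use neutral mass arithmetic", {
  db <- add_decoys(assemble_database(
    protein_entries("P1", "AAARPEPTIDEK", "REF", "P1")))
  s <- search_settings(min_peptide_length = 4L)
  idx <- build_candidate_index(db, s)
  expect_true("PEPTIDEK" %in% idx$table$sequence)
  # masses sorted for binary search
  expect_false(is.unsorted(idx$table$mass))

  # m/z 400.68725 at z=2 -> neutral 799.3599; PEPTIDE itself is in-window
  mt <- mass_table()
  expect_equal(2 * 400.68725 - 2 * mt$proton,
               peptide_monoisotopic_mass("PEPTIDE"), tolerance = 1e-4)

  # a spectrum of PEPTIDEK fragments is matched to PEPTIDEK
  fr <- theoretical_fragments("PEPTIDEK")
  M <- peptide_monoisotopic_mass("PEPTIDEK")
  sp <- list(scan = "s1", title = "s1", charge = 2L,
             pepmass = (M + 2 * mt$proton) / 2,
             mz = fr$mz, intensity = rep(100, nrow(fr)))
  psm <- run_search(idx, list(sp), s)
  expect_equal(psm$peptide, "PEPTIDEK")
  expect_false(psm$is_decoy)

  # unknown charge: all assumed charges evaluated, still recovered
  sp$charge <- NA_integer_
  psm2 <- run_search(idx, list(sp), s)
  expect_equal(psm2$peptide, "PEPTIDEK")
  expect_equal(psm2$charge, 2L)

  # a precursor far outside every window yields no PSM
  sp$charge <- 4L
  out <- run_search(idx, list(sp), s)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_unmatched"), 1L)
})

test_that("q-values follow the decoy/target ratio, monotonized", {
  psms <- data.frame(
    scan = as.character(1:6),
    peptide = c("A", "B", "C", "D", "E", "F"),
    score = c(10, 9, 8.5, 8, 7, 6),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    q = NA_real_, stringsAsFactors = FALSE)
  out <- compute_q_values(psms, search_settings())
  expect_equal(out$q[out$peptide %in% c("A", "B")], c(0, 0))
  expect_equal(out$q[out$peptide %in% c("D", "E")], c(0.25, 0.25))

  # no decoys: all q = 0
  nd <- transform(psms, is_decoy = FALSE)
  expect_true(all(compute_q_values(nd, search_settings())$q == 0))

  # all decoys above all targets: target q capped at 1
  ad <- data.frame(scan = as.character(1:4), peptide = c("A", "B", "C", "D"),
                   score = c(10, 9, 2, 1),
                   is_decoy = c(TRUE, TRUE, FALSE, FALSE),
                   q = NA_real_, stringsAsFactors = FALSE)
  expect_true(all(compute_q_values(ad, search_settings())$q[3:4] == 1))

  # q non-increasing with score; acceptance monotone in the FDR cap
  set.seed(111)
  r <- data.frame(scan = as.character(1:200), peptide = as.character(1:200),
                  score = runif(200, 0, 10),
                  is_decoy = runif(200) < 0.3, q = NA_real_,
                  stringsAsFactors = FALSE)
  out <- compute_q_values(r, search_settings())
  o <- order(-out$score)
  expect_true(all(diff(out$q[o]) >= -1e-12))
  n1 <- sum(compute_q_values(r, search_settings(max_fdr = 0.01))$accepted)
  n5 <- sum(compute_q_values(r, search_settings(max_fdr = 0.05))$accepted)
  n20 <- sum(compute_q_values(r, search_settings(max_fdr = 0.20))$accepted)
  expect_true(n1 <= n5 && n5 <= n20)
})

test_that("protein grouping merges indistinguishable and subsumed proteins", {
  mk_psms <- function(pep, acc)
    data.frame(peptide = pep, accessions = acc, stringsAsFactors = FALSE)
  # both peptides only in A -> one group
  g <- group_proteins(mk_psms(c("PEP1K", "PEP2K"), c("A", "A")))
  expect_equal(g$accessions, "A")
  # B's peptides are a subset of A's -> B subsumed
  g <- group_proteins(mk_psms(c("PEP1K", "PEP2K"), c("A;B", "A")))
  expect_equal(g$accessions, "A")
  # identical peptide sets -> one merged group
  g <- group_proteins(mk_psms(c("PEP1K", "PEP2K"), c("A;B", "A;B")))
  expect_equal(g$accessions, "A;B")
  # decoy parents never enter groups
  g <- group_proteins(mk_psms("PEP1K", "A;DECOY_B"))
  expect_equal(g$accessions, "A")
})

test_that("a planted spectrum ranks its generating peptide first", {
  truth <- simulate_genome_and_truth(8, 3, seed = 121)
  db <- add_decoys(build_refdb(truth$annotation))
  sim <- simulate_spectra(db, n_true = 30, n_noise = 0, jitter_sd_da = 0.005,
                          frac_peaks_dropped = 0, n_noise_peaks = 0,
                          seed = 122)
  psms <- run_search(db, sim$spectra)
  hit <- merge(psms, sim$manifest, by = "scan")
  expect_gte(mean(hit$peptide.x == hit$peptide.y), 0.97)
})
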