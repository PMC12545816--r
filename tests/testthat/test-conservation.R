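test_that("window extraction clips at promoter boundaries with flags", {
  prom <- tibble::tibble(gene_id = "g1", length = 5000L,
                         seq = paste(rep("ACGTA", 1000), collapse = ""))
  hit <- tibble::tibble(motif_id = "m", gene_id = "g1",
                        start = -1000L, end = -940L)
  w <- extract_window(hit, prom, flank = 100)
  expect_equal(c(w$rel_start, w$rel_end), c(-1100, -840))
  expect_equal(nchar(w$seq), 260)
  expect_false(w$clipped5 || w$clipped3)

  hit2 <- tibble::tibble(motif_id = "m", gene_id = "g1",
                         start = -4970L, end = -4910L)
  w2 <- extract_window(hit2, prom, flank = 100)
  expect_true(w2$clipped5)
  expect_equal(w2$rel_start, -5000)

  w0 <- extract_window(hit, prom, flank = 0)
  expect_equal(c(w0$rel_start, w0$rel_end), c(-1000, -940))
})

test_that("progressive alignment handles identity, substitution, indel", {
  aln <- align_windows(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  expect_false(any(aln$mat == "-"))
  expect_true(all(aln$column_conservation == 1))

  aln2 <- align_windows(c(a = "ACGTACGTAC", b = "ACGTACCTAC"))
  expect_equal(ncol(aln2$mat), 10)
  expect_equal(sum(aln2$column_conservation < 1), 1)

  aln3 <- align_windows(c(a = "ACGT", b = "AGT"))
  expect_equal(ncol(aln3$mat), 4)
  expect_equal(sum(aln3$mat == "-"), 1)

  expect_error(align_windows(c(a = "ACGT")), "at least two")
})

test_that("pairwise alignment agrees with an independent aligner", {
  # Biostrings::pairwiseAlignment with the same scoring scheme is the oracle
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(21)
  for (k in 1:10) {
    a <- random_dna(60)
    b <- random_dna(55)
    ours <- attr(plantcns:::nw_pair(plantcns:::encode_seq(a),
                                    plantcns:::encode_seq(b), 1, -1, 4, 1),
                 "score")
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                         gapOpening = 3, gapExtension = 1,
                                         type = "global",
                                         scoreOnly = TRUE)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("alignment rows ungap back to their inputs", {
  set.seed(5)
  seqs <- stats::setNames(
    vapply(1:8, function(i) random_dna(sample(40:60, 1)), character(1)),
    paste0("s", 1:8))
  aln <- align_windows(seqs)
  for (i in seq_len(nrow(aln$mat))) {
    back <- paste(aln$mat[i, aln$mat[i, ] != "-"], collapse = "")
    expect_identical(back, unname(seqs[aln$ids[i]]))
  }
})

test_that("CNS delineation extends through conserved columns only", {
  # fully conserved alignment -> CNS spans all columns
  aln <- align_windows(c(a = strrep("ACGTT", 10), b = strrep("ACGTT", 10)))
  aln$meta$rel_start <- c(-500L, -500L)
  core <- 21:30
  reg <- delineate_cns(aln, core)
  expect_equal(attr(reg, "columns"), 1:50)
  expect_equal(reg$length, c(50L, 50L))

  # conserved core, random flanks -> CNS = core
  set.seed(31)
  mkseq <- function() paste0(random_dna(20), "ACACGTGTCGAT", random_dna(20))
  win <- tibble::tibble(gene_id = paste0("s", 1:6),
                        seq = vapply(1:6, function(i) mkseq(), character(1)),
                        rel_start = -400L)
  aln2 <- align_windows(win)
  core2 <- columns_for_interval(aln2, "s1", -380L, -368L)
  reg2 <- delineate_cns(aln2, core2)
  s1 <- reg2[reg2$gene_id == "s1", ]
  # core recovered; unconserved flanks may contribute at most a few lucky
  # columns, never a long extension
  expect_gte(s1$length, 12)
  expect_lte(s1$length, 26)

  # raising the threshold never widens the span
  cfg <- small_family_config(seed = 51, n_rosids = 6L, n_asterids = 5L)
  sim <- simulate_family(cfg)
  prom <- extract_promoters(sim$genes, sim$genome, mode = "truncated",
                            annotation = sim$annotation)
  hits <- scan_promoters(prom, element_motif(cfg$elements[[2]]))
  win3 <- extract_windows(hits, prom, "BOX1", flank = 100)
  aln3 <- align_windows(win3)
  core3 <- columns_for_interval(aln3, win3$gene_id[1],
                                win3$hit_rel_start[1], win3$hit_rel_end[1])
  lens <- vapply(c(0.4, 0.5, 0.7, 0.9), function(thr) {
    length(attr(delineate_cns(aln3, core3, cons_threshold = thr), "columns"))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))

  # delineated length close to the planted element length (90 bp)
  reg3 <- delineate_cns(aln3, core3)
  expect_lt(abs(mean(reg3$length) - 90) / 90, 0.2)

  expect_error(delineate_cns(aln3, integer(0)), "absent")
})

test_that("percent identity satisfies its axioms and examples", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  set.seed(9)
  a <- random_dna(60)
  b <- random_dna(60)
  expect_equal(percent_identity(a, b), percent_identity(b, a))
  expect_equal(percent_identity(a, b),
               percent_identity(revcomp(a), revcomp(b)))
  expect_error(percent_identity("", "ACGT"), "empty")

  m <- pid_matrix(c(x = a, y = b, z = random_dna(60)))
  expect_equal(diag(m), c(x = 100, y = 100, z = 100))
  expect_equal(m, t(m))
})

test_that("identity enrichment computes log2 ratios per lineage", {
  ids <- c("ref", "o1", "o2", "o3")
  box <- matrix(90, 4, 4, dimnames = list(ids, ids))
  cds <- matrix(45, 4, 4, dimnames = list(ids, ids))
  cds["ref", "o2"] <- cds["o2", "ref"] <- 90
  cds["ref", "o3"] <- cds["o3", "ref"] <- 0
  meta <- tibble::tibble(gene_id = ids,
                         species = c("sref", "s1", "s2", "s3"),
                         lineage = c("rosids", "rosids", "asterids", "asterids"))
  enr <- identity_enrichment(box, cds, meta, "ref")
  expect_equal(enr$log2_enrichment[enr$gene_id == "o1"], 1)
  expect_equal(enr$log2_enrichment[enr$gene_id == "o2"], 0)
  expect_false("o3" %in% enr$gene_id) # cds_pid = 0 dropped
  expect_equal(attr(enr, "dropped")$gene_id, "o3")

  # same-species pairs excluded
  meta2 <- meta
  meta2$species[2] <- "sref"
  enr2 <- identity_enrichment(box, cds, meta2, "ref")
  expect_false("o1" %in% enr2$gene_id)

  box_bad <- box[1:3, 1:3]
  expect_error(identity_enrichment(box_bad, cds, meta, "ref"),
               "different ortholog sets")
})
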