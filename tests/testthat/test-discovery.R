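test_that("background model applies the documented pseudocounts", {
  expect_equal(background_model("AAAA"),
               c(A = 5 / 8, C = 1 / 8, G = 1 / 8, T = 1 / 8))
  expect_equal(unname(background_model("ACGT")), rep(0.25, 4))
  expect_equal(unname(background_model(c("AC", "GT"))), rep(0.25, 4))
  expect_equal(background_model("ANNA")[["A"]], 3 / 6)
  expect_error(background_model("NNNN"), "no A/C/G/T")
})

test_that("one EM iteration reproduces the direct Bayes posterior", {
  # tiny enumerable case: 3 sequences of length 8, w = 4
  seqs <- c(s1 = "ACGTACGT", s2 = "TTTTACGT", s3 = "ACGTAAAA")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  probs0 <- plantcns:::seed_probs_from_string("ACGT")
  index <- plantcns:::scan_index(seqs, 4L)
  fit <- plantcns:::em_run(index, probs0, bg, lambda = 0.4, max_iter = 1L)

  # direct posterior with the same start parameters
  lambda <- 0.4
  z_direct <- numeric(nrow(index$W))
  for (i in 1:3) {
    sel <- which(index$group == i)
    lr <- vapply(sel, function(j) {
      prod(probs0[cbind(index$W[j, ], 1:4)] / 0.25)
    }, numeric(1))
    Wi <- length(sel)
    denom <- (1 - lambda) + (lambda / Wi) * sum(lr)
    z_direct[sel] <- (lambda / Wi) * lr / denom
  }
  expect_equal(fit$z, z_direct, tolerance = 1e-10)
})

test_that("EM log likelihood is non-decreasing (runtime assertion)", {
  set.seed(3)
  seqs <- vapply(1:10, function(i) random_dna(120), character(1))
  expect_no_error(em_zoops(seqs, 12, n_starts = 4, debug_monotone = TRUE))
})

test_that("a single promoter equal to the motif yields one-hot columns", {
  fit <- em_zoops("ACGTACGTTTGCACG", 15, n_starts = 1,
                  background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  m <- fit$motif
  expect_equal(m$w, 15)
  ok_fwd <- m$consensus == "ACGTACGTTTGCACG"
  ok_rc <- m$consensus == revcomp("ACGTACGTTTGCACG")
  expect_true(ok_fwd || ok_rc)
  expect_true(all(apply(m$probs, 2, max) > 0.85))
})

test_that("exact planted 15-mers are recovered verbatim", {
  set.seed(10)
  planted <- "ATCGAACGGAGCCGG"
  seqs <- vapply(1:30, function(i) {
    s <- random_dna(200)
    p <- sample(1:(200 - 15), 1)
    paste0(substr(s, 1, p - 1), planted, substr(s, p + 15, 200))
  }, character(1))
  fit <- em_zoops(seqs, 15)
  hit <- fit$motif$consensus == planted ||
    revcomp(fit$motif$consensus) == planted
  expect_true(hit)
  expect_gt(fit$motif$n_sites, 25)
})

test_that("discovery on reverse-complemented promoters mirrors the motif", {
  cfg <- discovery_config(seed = 31, n_species = 20L)
  sim <- simulate_family(cfg)
  prom <- extract_promoters(sim$genes, sim$genome, mode = "truncated",
                            annotation = sim$annotation)
  f1 <- em_zoops(prom$seq, 15)
  f2 <- em_zoops(revcomp(prom$seq), 15)
  expect_equal(f1$motif$llr, f2$motif$llr, tolerance = 1e-6)
  same <- f1$motif$consensus == f2$motif$consensus ||
    f1$motif$consensus == revcomp(f2$motif$consensus)
  expect_true(same)
})

test_that("dinucleotide shuffles preserve dinucleotide counts exactly", {
  dint <- function(x) {
    s <- strsplit(x, "", fixed = TRUE)[[1]]
    sort(table(paste0(utils::head(s, -1), utils::tail(s, -1))))
  }
  set.seed(4)
  for (k in 1:20) {
    s <- random_dna(sample(10:400, 1))
    r <- dinucleotide_shuffle(s)
    expect_identical(dint(r), dint(s))
  }
  # N runs participate like any other symbol
  s <- paste0(random_dna(50), strrep("N", 20), random_dna(50))
  expect_identical(dint(dinucleotide_shuffle(s)), dint(s))
})

test_that("E-value estimation enforces its contracts", {
  fit <- em_zoops(c("ACGTACGTACGTACGTAAAA", "ACGTACGTACGTACGTTTTT"), 15,
                  n_starts = 1)
  expect_error(estimate_evalue(fit$motif, c("A", "B"), n_shuffles = 5),
               "at least 10")
  degenerate <- fit$motif
  degenerate$llr <- -Inf
  out <- estimate_evalue(degenerate, c("ACGTACGTACGTACGTAAAA"),
                         n_shuffles = 10)
  expect_equal(out$evalue, degenerate$n_candidates)
})

test_that("motifs supported by fewer than min_sites promoters are dropped", {
  set.seed(6)
  planted <- "GACCTTGCAAGTCCA"
  seqs <- vapply(1:30, function(i) {
    s <- random_dna(150)
    if (i <= 14) {
      p <- 60
      s <- paste0(substr(s, 1, p - 1), planted, substr(s, p + 15, 150))
    }
    s
  }, character(1))
  found <- discover(seqs, widths = 15, min_sites = 15, n_motifs = 1,
                    n_shuffles = 20, seed = 1)
  # planted in exactly 14 promoters -> not reported under min_sites = 15
  reported <- vapply(found, function(m) {
    m$consensus == planted || revcomp(m$consensus) == planted
  }, logical(1))
  expect_false(any(reported))
})

test_that("curation flags repetitive and low-conservation motifs", {
  rep_counts <- matrix(0.1, 4, 15)
  rep_counts[1, seq(1, 15, 2)] <- 20 # A at odd columns
  rep_counts[4, seq(2, 15, 2)] <- 20 # T at even columns
  m_rep <- motif_from_counts(rep_counts, id = "rep")
  expect_equal(m_rep$consensus, "ATATATATATATATA")

  sharp <- matrix(0.01, 4, 15)
  sharp[cbind(rep(1:4, length.out = 15), 1:15)] <- 50
  m_sharp <- motif_from_counts(sharp, id = "sharp")

  flat <- matrix(5, 4, 15)
  flat[1, ] <- 9 # ~0.5 bit columns
  m_flat <- motif_from_counts(flat, id = "flat")

  verdicts <- curate(list(m_rep, m_sharp, m_flat))
  expect_equal(verdicts$verdict[verdicts$motif_id == "rep"], "fail")
  expect_match(verdicts$reason[verdicts$motif_id == "rep"], "repetitive")
  expect_equal(verdicts$verdict[verdicts$motif_id == "sharp"], "pass")
  expect_equal(verdicts$verdict[verdicts$motif_id == "flat"], "fail")
  expect_match(verdicts$reason[verdicts$motif_id == "flat"], "low_conservation")

  # non-specificity rule via scan hit counts
  v2 <- curate(list(m_sharp), scan_hit_counts = c(sharp = 1000))
  expect_equal(v2$verdict, "fail")
  expect_match(v2$reason, "non_specific")
})

test_that("MEME minimal format round-trips probabilities and metadata", {
  motifs <- fixture_motifs_small()[3:5]
  motifs <- lapply(motifs, function(m) {
    m$evalue <- 0.01
    m
  })
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- read_meme(path)
  expect_equal(length(back), 3)
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$id, motifs[[k]]$id)
    expect_equal(back[[k]]$w, motifs[[k]]$w)
    expect_equal(unname(back[[k]]$probs), unname(motifs[[k]]$probs),
                 tolerance = 1e-5)
  }
})

test_that("tidy and glance summarize fitted motifs", {
  m <- fixture_motifs_small()[[5]]
  td <- tidy(m)
  expect_equal(nrow(td), m$w)
  expect_equal(td$A + td$C + td$G + td$T, rep(1, m$w), tolerance = 1e-9)
  expect_true(all(td$ic >= 0 & td$ic <= 2))
  gl <- glance(m)
  expect_equal(gl$width, m$w)
})
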