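test_that("log-odds scores match their closed forms", {
  # one-hot-ish motif, uniform background
  counts <- matrix(0.001, 4, 4)
  counts[cbind(1:4, 1:4)] <- 100
  m <- motif_from_counts(counts, id = "onehot")
  s <- score_pssm(m, "ACGT", 1)
  expect_equal(s, sum(log2(m$probs[cbind(1:4, 1:4)] / 0.25)), tolerance = 1e-12)

  # uniform column contributes 0 under uniform background
  counts2 <- counts
  counts2[, 2] <- 25
  m2 <- motif_from_counts(counts2, id = "unifcol")
  contrib <- unname(log2(m2$probs[2, 2] / 0.25))
  expect_equal(contrib, 0, tolerance = 1e-3)

  # N contributes zero for its column
  sN <- score_pssm(m, "ANGT", 1)
  expect_equal(sN, s - unname(log2(m$probs[2, 2] / 0.25)), tolerance = 1e-12)

  # brute-force per-column re-summation on a width-5 motif
  m5 <- fixture_motifs_small()[[5]]
  set.seed(2)
  seq <- random_dna(40)
  for (pos in c(1, 7, 30)) {
    win <- substr(seq, pos, pos + 4)
    code <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    brute <- sum(vapply(1:5, function(j) {
      log2(m5$probs[code[j], j] / 0.25)
    }, numeric(1)))
    expect_equal(score_pssm(m5, seq, pos), brute, tolerance = 1e-12)
  }
})

test_that("p-value tables are exact against exhaustive enumeration", {
  # width-1 motif favoring A: P(score >= max) = 0.25
  m1 <- motif_from_counts(matrix(c(10, 1, 1, 1), 4, 1), id = "w1")
  tab1 <- pvalue_table(m1)
  smax <- max(round(log2(m1$probs[, 1] / 0.25) / 1e-3))
  expect_equal(pssm_pvalue(tab1, smax, integer_score = TRUE), 0.25)
  # below the minimum achievable score the p-value is 1
  expect_equal(pssm_pvalue(tab1, -1e6, integer_score = TRUE), 1)
  expect_error(pvalue_table(m1, granularity = 0), "positive")

  for (m in fixture_motifs_small()) {
    tab <- pvalue_table(m)
    w <- m$w
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    iscore <- apply(words, 1, function(wd) sum(tab$off[cbind(wd, 1:w)]))
    exact <- vapply(iscore, function(s) mean(iscore >= s), numeric(1))
    dp <- pssm_pvalue(tab, iscore, integer_score = TRUE)
    expect_lt(max(abs(dp - exact)), 1e-6)
  }
})

test_that("scanning matches brute-force per-position scoring", {
  set.seed(12)
  motifs <- fixture_motifs_small()[4:5]
  seqs <- stats::setNames(vapply(1:6, function(i) random_dna(200), character(1)),
                          paste0("g", 1:6))
  hits <- scan_promoters(seqs, motifs, p_threshold = 5e-2)
  brute <- list()
  for (m in motifs) {
    tab <- pvalue_table(m)
    for (gi in seq_along(seqs)) {
      L <- nchar(seqs[[gi]])
      cand <- list()
      for (strand in c("+", "-")) {
        src <- if (strand == "+") seqs[[gi]] else revcomp(seqs[[gi]])
        for (p in 1:(L - m$w + 1)) {
          code <- plantcns:::encode_seq(substr(src, p, p + m$w - 1))
          isc <- sum(tab$off[cbind(code, 1:m$w)])
          pv <- pssm_pvalue(tab, isc, integer_score = TRUE)
          if (pv < 5e-2) {
            fwd_start <- if (strand == "+") p else L - p - m$w + 2L
            cand[[length(cand) + 1]] <- data.frame(
              gene_id = names(seqs)[gi], start = fwd_start - 1L - L,
              strand_match = strand, pvalue = pv)
          }
        }
      }
      df <- do.call(rbind, cand)
      if (is.null(df)) next
      # same greedy best-p overlap resolution (ties: downstream start, then +)
      df <- df[order(df$pvalue, -df$start, df$strand_match), ]
      kept <- integer(0)
      for (i in seq_len(nrow(df))) {
        if (length(kept) == 0 ||
            all(df$start[i] >= df$start[kept] + m$w |
                  df$start[i] + m$w <= df$start[kept])) {
          kept <- c(kept, i)
        }
      }
      df <- df[kept, ]
      df$motif_id <- m$id
      brute[[length(brute) + 1]] <- df
    }
  }
  bdf <- do.call(rbind, brute)
  key <- function(d) sort(paste(d$motif_id, d$gene_id, d$start, d$strand_match))
  expect_identical(key(hits), key(bdf))
})

test_that("an all-N promoter yields no hits", {
  m <- fixture_motifs_small()[[5]]
  hits <- scan_promoters(c(gN = strrep("N", 60)), m)
  expect_equal(nrow(hits), 0)
})

test_that("palindromic matches collapse to one hit after deduplication", {
  counts <- matrix(0.001, 4, 6)
  pal <- c(3, 1, 4, 1, 2, 3) # GATATC... use GAATTC: G A A T T C
  pal <- match(strsplit("GAATTC", "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(pal, 1:6)] <- 50
  m <- motif_from_counts(counts, id = "pal")
  seq <- c(g1 = paste0(strrep("C", 25), "GAATTC", strrep("A", 25)))
  hits <- scan_promoters(seq, m, p_threshold = 1e-2)
  expect_equal(nrow(hits), 1)
})

test_that("BH q-values follow the step-up closed form", {
  h1 <- tibble::tibble(motif_id = "m", pvalue = 0.005)
  expect_equal(bh_qvalues(h1, m = 1)$qvalue, 0.005)

  h3 <- tibble::tibble(motif_id = "m", pvalue = c(0.01, 0.02, 0.03))
  expect_equal(bh_qvalues(h3, m = 3)$qvalue, c(0.03, 0.03, 0.03))

  set.seed(1)
  hr <- tibble::tibble(motif_id = "m", pvalue = runif(50))
  q <- bh_qvalues(hr, m = 50)$qvalue
  o <- order(hr$pvalue)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_equal(q, stats::p.adjust(hr$pvalue, "BH"))

  expect_error(bh_qvalues(h3, m = 2), "smaller than the number of hits")
})

make_filter_fixture <- function() {
  promoters <- tibble::tibble(
    gene_id = paste0("g", 1:46),
    species = paste0("s", 1:46),
    clade = "c1",
    lineage = c(rep("rosids", 40), rep("early_diverged", 3), rep("asterids", 3))
  )
  hits <- tibble::tibble(
    motif_id = "m1",
    gene_id = c("g1", "g2", "g3",       # 3/40 rosids = 7.5% < 10%
                "g41",                  # 1/3 exempt early-diverged
                "g44", "g45", "g46"),   # 3/3 asterids
    start = -100L, end = -85L,
    strand_match = c("+", "+", "+", "+", "+", "+", "-"),
    score = 10, pvalue = 1e-6,
    qvalue = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 0.5, 1e-6)
  )
  list(promoters = promoters, hits = hits)
}

test_that("q, orientation and prevalence filters apply in order", {
  fx <- make_filter_fixture()
  out <- filter_hits(fx$hits, fx$promoters,
                     exempt_lineages = "early_diverged")
  log <- out$removal_log
  expect_equal(log$n_removed[log$step == "q_filter"], 1)         # g45
  expect_equal(log$n_removed[log$step == "orientation_filter"], 1) # g46
  expect_equal(log$n_removed[log$step == "prevalence_filter"], 3)  # rosids
  expect_equal(sort(out$hits$gene_id), c("g41", "g44"))
  # exempt lineage retained despite 1/3 prevalence
  prev <- out$prevalence
  ed <- prev[prev$lineage == "early_diverged", ]
  expect_true(ed$exempt && ed$retained)
  expect_error(filter_hits(fx$hits, fx$promoters[1:10, ]),
               "without promoter metadata")
})

test_that("filtering is invariant to row permutations", {
  fx <- make_filter_fixture()
  out1 <- filter_hits(fx$hits, fx$promoters, exempt_lineages = "early_diverged")
  set.seed(3)
  out2 <- filter_hits(fx$hits[sample(nrow(fx$hits)), ],
                      fx$promoters[sample(nrow(fx$promoters)), ],
                      exempt_lineages = "early_diverged")
  expect_identical(out1$hits, out2$hits)
  expect_identical(out1$removal_log, out2$removal_log)
})

test_that("p-values are calibrated on iid background", {
  # width 10 so the discretized score distribution is effectively continuous
  set.seed(55)
  m <- motif_from_counts(matrix(sample(1:9, 40, replace = TRUE), nrow = 4),
                         id = "cal_w10")
  tab <- pvalue_table(m)
  set.seed(99)
  n <- 2e5
  code <- sample.int(4L, n, replace = TRUE)
  np <- n - m$w + 1
  isc <- numeric(np)
  for (j in 1:m$w) isc <- isc + tab$off[cbind(code[j:(j + np - 1)], j)]
  pv <- pssm_pvalue(tab, isc, integer_score = TRUE)
  alpha <- 1e-3
  frac <- mean(pv < alpha)
  se <- sqrt(alpha * (1 - alpha) / np)
  expect_lt(abs(frac - alpha), 4 * se)
})
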