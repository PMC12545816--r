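# ZOOPS (zero-or-one-occurrence-per-sequence) motif discovery by
# expectation-maximization, with Monte-Carlo E-values from dinucleotide
# shuffles and programmatic curation of candidate motifs.

#' 0-order background model of a promoter set
#'
#' Nucleotide frequencies over `{A,C,G,T}` with a pseudocount of 1 per letter;
#' `N` bases are excluded from counting.
#'
#' @param promoters Promoter tibble (with a `seq` column) or character vector.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
background_model <- function(promoters) {
  seqs <- promoter_seqs(promoters)
  counts <- numeric(4)
  for (s in seqs) {
    code <- encode_seq(s)
    counts <- counts + tabulate(code[code <= 4L], nbins = 4L)
  }
  if (sum(counts) == 0) stop("background_model: input contains no A/C/G/T bases")
  freqs <- (counts + 1) / (sum(counts) + 4)
  stats::setNames(freqs, DNA_BASES)
}

promoter_seqs <- function(promoters) {
  if (is.character(promoters)) {
    seqs <- promoters
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    seqs <- stats::setNames(promoters$seq, promoters$gene_id)
  }
  normalize_alphabet(seqs)
}

# Window index over both strands of a sequence set. Positions are 1-based
# starts on the forward (gene-orientation) strand for either strand's window.
scan_index <- function(seqs, w) {
  lens <- nchar(seqs)
  short <- which(lens < w)
  if (length(short) > 0) {
    stop("width ", w, " exceeds promoter length of ", names(seqs)[short[1]],
         " (", lens[short[1]], " bp)")
  }
  per_seq <- purrr::map(seq_along(seqs), function(i) {
    code <- encode_seq(seqs[[i]])
    rc <- encode_seq(revcomp(seqs[[i]]))
    L <- lens[i]
    np <- L - w + 1L
    starts <- seq_len(np)
    idx_f <- outer(starts, 0:(w - 1L), `+`)
    Wf <- matrix(code[idx_f], nrow = np)
    Wr <- matrix(rc[idx_f], nrow = np)
    list(
      W = rbind(Wf, Wr),
      group = rep(i, 2L * np),
      strand = rep(c("+", "-"), each = np),
      # forward-strand start of the window (1-based)
      pos = c(starts, L - starts - w + 2L)
    )
  })
  W <- do.call(rbind, purrr::map(per_seq, "W"))
  list(
    W = W,
    Wt = t(W),
    group = unlist(purrr::map(per_seq, "group")),
    strand = unlist(purrr::map(per_seq, "strand")),
    pos = unlist(purrr::map(per_seq, "pos")),
    n_seq = length(seqs),
    n_win = 2L * (lens - w + 1L),
    lens = lens
  )
}

# Reverse-complement a 4 x w base matrix (rows ordered A, C, G, T).
rc_matrix <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

consensus_of <- function(probs) {
  paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
}

column_ic <- function(probs) {
  apply(probs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

seed_probs_from_string <- function(s, consensus_weight = 0.7) {
  code <- encode_seq(s)
  w <- length(code)
  probs <- matrix((1 - consensus_weight) / 3, nrow = 4, ncol = w,
                  dimnames = list(DNA_BASES, NULL))
  for (c in seq_len(w)) {
    if (code[c] <= 4L) {
      probs[code[c], c] <- consensus_weight
    } else {
      probs[, c] <- 0.25
    }
  }
  probs
}

# MEME-like deterministic starts: rank k-mers by background-corrected count,
# then lift actual promoter substrings around top-word occurrences to width w.
seed_words <- function(seqs, w, background, n_starts, k = 8L) {
  k <- min(k, w)
  code_chunks <- list()
  meta_seq <- list()
  meta_pos <- list()
  meta_fwd <- list()
  pow <- 4^(0:(k - 1))
  for (i in seq_along(seqs)) {
    for (fwd in c(TRUE, FALSE)) {
      s <- if (fwd) seqs[[i]] else revcomp(seqs[[i]])
      L <- nchar(s)
      if (L < k) next
      code <- encode_seq(s)
      np <- L - k + 1L
      wcode <- numeric(np)
      has_n <- logical(np)
      for (j in seq_len(k)) {
        cj <- code[j:(j + np - 1L)]
        has_n <- has_n | cj == 5L
        wcode <- wcode + (pmin(cj, 4L) - 1L) * pow[j]
      }
      wcode[has_n] <- NA_real_
      code_chunks[[length(code_chunks) + 1]] <- wcode
      meta_seq[[length(meta_seq) + 1]] <- rep(i, np)
      meta_pos[[length(meta_pos) + 1]] <- seq_len(np)
      meta_fwd[[length(meta_fwd) + 1]] <- rep(fwd, np)
    }
  }
  cvec <- unlist(code_chunks)
  if (length(cvec) == 0 || all(is.na(cvec))) return(character(0))
  mseq <- unlist(meta_seq)
  mpos <- unlist(meta_pos)
  mfwd <- unlist(meta_fwd)
  cnt_tab <- tabulate(cvec + 1, nbins = 4^k)
  present <- which(cnt_tab > 0)
  # background probability of each present word from its digit expansion
  lbg <- log(background)
  digits <- matrix(0L, nrow = length(present), ncol = k)
  rem <- present - 1L
  bglp <- numeric(length(present))
  for (j in seq_len(k)) {
    dj <- rem %% 4L
    bglp <- bglp + lbg[dj + 1L]
    rem <- rem %/% 4L
  }
  enr <- cnt_tab[present] / (length(cvec) * exp(bglp))
  ord <- order(-enr, present)
  top <- present[ord][seq_len(min(length(present), max(n_starts, 5L)))]

  seeds <- character(0)
  for (wd in top) {
    j <- match(wd - 1L, cvec)
    i <- mseq[j]
    src <- if (mfwd[j]) seqs[[i]] else revcomp(seqs[[i]])
    start <- max(1L, min(mpos[j] - floor((w - k) / 2), nchar(src) - w + 1L))
    sd <- substr(src, start, start + w - 1L)
    if (!grepl("N", sd, fixed = TRUE)) seeds <- c(seeds, sd)
    if (length(unique(seeds)) >= n_starts) break
  }
  seeds <- unique(seeds)
  # fall back to evenly spaced substrings if the word heuristic was starved
  if (length(seeds) < n_starts) {
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[[i]])
      if (L < w) next
      for (p in unique(round(seq(1, L - w + 1, length.out = 3)))) {
        sd <- substr(seqs[[i]], p, p + w - 1L)
        if (!grepl("N", sd, fixed = TRUE)) seeds <- unique(c(seeds, sd))
        if (length(seeds) >= n_starts) break
      }
      if (length(seeds) >= n_starts) break
    }
  }
  utils::head(seeds, n_starts)
}

# One EM run from a given probability-matrix start. Returns the converged
# model; the objective is the ZOOPS log likelihood minus the (constant)
# all-background log likelihood, in nats.
em_run <- function(index, probs, background, lambda = 0.5, tol = 1e-4,
                   max_iter = 200L, pseudo = 0.1, debug_monotone = FALSE) {
  fit <- zoops_em_cpp(index$Wt, index$group, as.numeric(index$n_win),
                      probs, unname(background), lambda, tol, max_iter,
                      pseudo, debug_monotone)
  rownames(fit$probs) <- DNA_BASES
  rownames(fit$counts) <- DNA_BASES
  fit
}

#' Fit a ZOOPS motif model of a given width by expectation-maximization
#'
#' Each promoter contributes at most one motif site on either strand. EM is
#' started from deterministic substring seeds (top background-corrected words
#' lifted to width-`w` promoter substrings at 0.7 consensus weight); the start
#' with the highest converged log likelihood wins, ties broken by lowest seed
#' index. The objective is non-decreasing across iterations within one start
#' (assert with `debug_monotone = TRUE`).
#'
#' @param promoters Promoter tibble or character vector; every sequence must
#'   be at least `w` long.
#' @param w Motif width in bp (15-100 for discovery; smaller widths are
#'   permitted for diagnostic fits).
#' @param n_starts Number of EM starts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param background Optional 0-order background; defaults to
#'   [background_model()] of the input.
#' @param debug_monotone Assert the EM monotonicity invariant at runtime.
#' @return A list with `motif` (class `zoops_motif`: counts, probs, per-column
#'   information content, background, expected site count `n_sites`, log
#'   likelihood ratio `llr` in nats, search multiplicity `n_candidates`) and
#'   `model` (class `zoops_model`: `lambda`, per-window responsibilities `z`,
#'   per-sequence totals `Qi`, `loglik`).
#' @export
em_zoops <- function(promoters, w, n_starts = 16L, tol = 1e-4,
                     max_iter = 200L, background = NULL,
                     debug_monotone = FALSE) {
  seqs <- promoter_seqs(promoters)
  background <- background %||% background_model(seqs)
  index <- scan_index(seqs, w)
  seeds <- seed_words(seqs, w, background, n_starts)
  if (length(seeds) == 0) stop("no usable seed substrings (all-N input?)")
  best <- NULL
  for (si in seq_along(seeds)) {
    fit <- em_run(index, seed_probs_from_string(seeds[si]), background,
                  tol = tol, max_iter = max_iter,
                  debug_monotone = debug_monotone)
    if (is.null(best) || fit$llr > best$llr) {
      best <- fit
      best$seed_index <- si
    }
  }
  # Orient the motif to the strand carrying most site responsibility, so
  # "same orientation as the gene" filtering downstream is meaningful.
  minus_mass <- sum(best$z[index$strand == "-"])
  plus_mass <- sum(best$z[index$strand == "+"])
  if (minus_mass > plus_mass) {
    best$probs <- rc_matrix(best$probs)
    best$counts <- rc_matrix(best$counts)
  }
  motif <- new_zoops_motif(
    id = paste0("motif_w", w),
    counts = best$counts,
    probs = best$probs,
    background = background,
    n_sites = sum(best$Qi),
    llr = best$llr,
    n_candidates = length(seeds)
  )
  model <- structure(
    list(lambda = best$lambda, z = best$z, Qi = best$Qi, loglik = best$llr,
         index_group = index$group, index_strand = index$strand,
         index_pos = index$pos, iterations = best$iter,
         seed_index = best$seed_index),
    class = "zoops_model"
  )
  list(motif = motif, model = model)
}

new_zoops_motif <- function(id, counts, probs, background, n_sites, llr,
                            n_candidates = 1L, evalue = NA_real_) {
  rownames(counts) <- DNA_BASES
  structure(
    list(id = id, w = ncol(probs), counts = counts, probs = probs,
         ic = column_ic(probs), background = background, n_sites = n_sites,
         llr = llr, n_candidates = n_candidates, evalue = evalue,
         consensus = consensus_of(probs)),
    class = "zoops_motif"
  )
}

#' @export
print.zoops_motif <- function(x, ...) {
  cat("<zoops_motif> ", x$id, "  w=", x$w, "  consensus=", x$consensus,
      "\n  n_sites=", round(x$n_sites, 1),
      "  mean IC=", round(mean(x$ic), 2), " bits",
      "  E-value=", format(x$evalue, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted ZOOPS motif into one row per column
#'
#' @param x A `zoops_motif`.
#' @param ... Unused.
#' @return Tibble with per-column probabilities, information content and
#'   consensus letter.
#' @importFrom generics tidy
#' @export
tidy.zoops_motif <- function(x, ...) {
  tibble::tibble(
    column = seq_len(x$w),
    A = x$probs["A", ], C = x$probs["C", ], G = x$probs["G", ],
    T = x$probs["T", ],
    ic = x$ic,
    consensus = strsplit(x$consensus, "")[[1]]
  )
}

#' One-row summary of a fitted ZOOPS motif
#'
#' @inheritParams tidy.zoops_motif
#' @importFrom generics glance
#' @export
glance.zoops_motif <- function(x, ...) {
  tibble::tibble(id = x$id, width = x$w, n_sites = x$n_sites,
                 mean_ic = mean(x$ic), llr = x$llr, evalue = x$evalue)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: the returned sequence has exactly the same
#' dinucleotide (and hence mononucleotide) counts as the input.
#'
#' @param seq A single sequence string.
#' @return A shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3) return(seq)
  syms <- unique(s)
  edges <- split(s[-1], factor(s[-n], levels = syms))
  last <- s[n]
  sources <- syms[vapply(edges, length, integer(1)) > 0 & syms != last]

  # Random in-tree toward the last vertex (Wilson's loop-erased random walk,
  # edge choice weighted by multiplicity). Every vertex reaches `last` because
  # the original sequence is itself an Eulerian walk ending there.
  last_edge <- list()
  intree <- stats::setNames(rep(FALSE, length(syms)), syms)
  intree[last] <- TRUE
  for (v in sources) {
    cur <- v
    while (!intree[[cur]]) {
      ev <- edges[[cur]]
      last_edge[[cur]] <- ev[sample.int(length(ev), 1)]
      cur <- last_edge[[cur]]
    }
    cur <- v
    while (!intree[[cur]]) {
      intree[[cur]] <- TRUE
      cur <- last_edge[[cur]]
    }
  }

  shuffled <- list()
  for (v in syms) {
    ev <- edges[[v]]
    if (length(ev) == 0) {
      shuffled[[v]] <- ev
      next
    }
    if (v %in% sources) {
      drop <- match(last_edge[[v]], ev)
      rest <- ev[-drop]
      shuffled[[v]] <- c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      shuffled[[v]] <- ev[sample.int(length(ev))]
    }
  }
  ptr <- stats::setNames(rep(1L, length(syms)), syms)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Monte-Carlo motif E-value from dinucleotide-shuffled promoters
#'
#' The E-value is the expected number of motifs in the search space with a
#' ZOOPS log-likelihood ratio at least the observed one, under a null in
#' which every promoter is dinucleotide-shuffled. The null distribution of
#' best-start LLRs is sampled by re-running single-start EM on `n_shuffles`
#' shuffled promoter sets; the tail probability is the larger of the empirical
#' exceedance fraction and a normal-tail fit, multiplied by the search
#' multiplicity (`n_candidates * n_widths`). A degenerate observed LLR of
#' `-Inf` maps to the maximal E (the full search multiplicity).
#'
#' @param motif A `zoops_motif` fitted on `promoters`.
#' @param promoters The promoter set the motif was fitted on.
#' @param n_shuffles Number of shuffled null sets (at least 10).
#' @param seed RNG seed for the shuffles.
#' @param n_widths Number of widths searched when the motif was selected.
#' @return The motif with `evalue`, `evalue_n_shuffles` and `null_llr` filled.
#' @export
estimate_evalue <- function(motif, promoters, n_shuffles = 100L, seed = 1L,
                            n_widths = 1L) {
  if (n_shuffles < 10) stop("n_shuffles must be at least 10 (estimate too coarse)")
  seqs <- promoter_seqs(promoters)
  multiplicity <- motif$n_candidates * n_widths
  if (!is.finite(motif$llr)) {
    motif$evalue <- multiplicity
    motif$evalue_n_shuffles <- n_shuffles
    return(motif)
  }
  null_llr <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    shuf <- with_derived_seed(seed, "shuffle", b, expr = {
      vapply(seqs, dinucleotide_shuffle, character(1))
    })
    fit <- em_zoops(shuf, motif$w, n_starts = 1L,
                    background = motif$background)
    null_llr[b] <- fit$motif$llr
  }
  p_emp <- mean(null_llr >= motif$llr)
  mu <- mean(null_llr)
  sdv <- stats::sd(null_llr)
  p_norm <- if (is.finite(sdv) && sdv > 0) {
    stats::pnorm(motif$llr, mean = mu, sd = sdv, lower.tail = FALSE)
  } else {
    as.numeric(motif$llr <= mu)
  }
  motif$evalue <- multiplicity * max(p_emp, p_norm)
  motif$evalue_n_shuffles <- n_shuffles
  motif$null_llr <- null_llr
  motif
}

#' Iterative ZOOPS motif discovery
#'
#' Widths are searched over a coarse grid; the best-E motif across widths
#' fills one motif slot, its sites are masked (posterior best site per
#' contributing promoter replaced by `N`), and discovery repeats until a
#' candidate fails the E-value or minimum-site thresholds or `n_motifs` slots
#' are filled.
#'
#' @inheritParams em_zoops
#' @param widths Integer vector of widths to search (subset of 15-100).
#' @param min_sites Minimum expected number of contributing promoters.
#' @param n_motifs Maximum number of motifs to report.
#' @param e_max Motif significance threshold (default 0.05).
#' @param n_shuffles Shuffled sets per E-value estimate.
#' @param seed RNG seed (shuffles only; EM itself is deterministic).
#' @return List of accepted `zoops_motif` objects (possibly empty), each with
#'   ids `motif_1`, `motif_2`, ...
#' @export
discover <- function(promoters, widths = c(15L, 20L, 25L, 30L, 40L, 50L, 69L, 100L),
                     min_sites = 15L, n_motifs = 3L, e_max = 0.05,
                     n_starts = 16L, n_shuffles = 100L, seed = 1L) {
  seqs <- promoter_seqs(promoters)
  if (length(seqs) < min_sites) {
    stop("discovery requires at least min_sites = ", min_sites,
         " promoters, got ", length(seqs))
  }
  widths <- widths[widths <= min(nchar(seqs))]
  if (length(widths) == 0) stop("no search width fits the shortest promoter")
  background <- background_model(seqs)
  work <- seqs
  accepted <- list()
  for (slot in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths) {
      fit <- em_zoops(work, w, n_starts = n_starts, background = background)
      cand <- estimate_evalue(fit$motif, work, n_shuffles = n_shuffles,
                              seed = derive_seed(seed, "slot", slot, w),
                              n_widths = length(widths))
      cand_model <- fit$model
      if (is.null(best) || cand$evalue < best$motif$evalue) {
        best <- list(motif = cand, model = cand_model)
      }
    }
    ok <- best$motif$evalue < e_max && best$motif$n_sites >= min_sites
    if (!ok) break
    best$motif$id <- paste0("motif_", length(accepted) + 1)
    accepted[[length(accepted) + 1]] <- best$motif
    work <- mask_sites(work, best$motif, best$model)
  }
  accepted
}

# Replace each contributing promoter's best posterior site with N.
mask_sites <- function(seqs, motif, model) {
  w <- motif$w
  for (i in seq_along(seqs)) {
    sel <- model$index_group == i
    if (!any(sel) || sum(model$z[sel]) < 0.5) next
    zi <- model$z[sel]
    best <- which.max(zi)
    p <- model$index_pos[sel][best]
    substr(seqs[[i]], p, p + w - 1L) <- paste(rep("N", w), collapse = "")
  }
  seqs
}

#' Programmatic curation of discovered motifs
#'
#' Operationalizes manual motif curation with three explicit, configurable
#' rules: a motif fails as `repetitive` when at least `repeat_frac` of its
#' consensus columns follow a mono- or di-nucleotide repeat; as
#' `low_conservation` when the longest run of columns with information
#' content above 1 bit is shorter than `min_run`; and as `non_specific` when
#' a scanner callback reports more than `max_hit_ratio` times `n_sites` hits
#' at q < 0.01.
#'
#' @param motifs List of `zoops_motif` objects.
#' @param repeat_frac Repeat fraction threshold (default 0.8).
#' @param min_run Minimum run of >1-bit columns (default 8).
#' @param max_hit_ratio Scan-hit excess threshold (default 3).
#' @param scan_hit_counts Optional named numeric vector of q < 0.01 hit counts
#'   per motif id (from a scanner); when absent the non-specificity rule is
#'   skipped.
#' @return Tibble with `motif_id`, `verdict` (`pass`/`fail`) and `reason`.
#' @export
curate <- function(motifs, repeat_frac = 0.8, min_run = 8L,
                   max_hit_ratio = 3, scan_hit_counts = NULL) {
  purrr::map_dfr(motifs, function(m) {
    reasons <- character(0)
    if (repeat_fraction(m$consensus) >= repeat_frac) {
      reasons <- c(reasons, "repetitive")
    }
    runs <- rle(m$ic > 1)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (longest < min_run) reasons <- c(reasons, "low_conservation")
    if (!is.null(scan_hit_counts) && m$id %in% names(scan_hit_counts) &&
        scan_hit_counts[[m$id]] > max_hit_ratio * m$n_sites) {
      reasons <- c(reasons, "non_specific")
    }
    tibble::tibble(
      motif_id = m$id,
      verdict = if (length(reasons) == 0) "pass" else "fail",
      reason = if (length(reasons) == 0) NA_character_ else paste(reasons, collapse = ";")
    )
  })
}

# Fraction of consensus columns consistent with the best phased 2-periodic
# (or homopolymer) pattern.
repeat_fraction <- function(consensus) {
  s <- strsplit(consensus, "", fixed = TRUE)[[1]]
  w <- length(s)
  odd <- s[seq(1, w, by = 2)]
  even <- if (w > 1) s[seq(2, w, by = 2)] else character(0)
  modal <- function(x) if (length(x) == 0) 0 else max(table(x))
  (modal(odd) + modal(even)) / w
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs List of `zoops_motif` objects.
#' @param path Output file.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "), "")
  for (m in motifs) {
    lines <- c(lines,
               paste("MOTIF", m$id, m$consensus),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
                       m$w, round(m$n_sites), if (is.na(m$evalue)) 0 else m$evalue),
               apply(m$probs, 2, function(p) paste(sprintf("%.6f", p), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path MEME minimal format file.
#' @return List of `zoops_motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[DNA_BASES]
  }
  motifs <- list()
  motif_at <- grep("^MOTIF", lines)
  for (start in motif_at) {
    id <- strsplit(trimws(lines[start]), "\\s+")[[1]][2]
    hdr_at <- start + grep("^letter-probability matrix",
                           lines[(start + 1):length(lines)])[1]
    hdr <- lines[hdr_at]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
    nsites <- suppressWarnings(as.numeric(sub(".*nsites= *([0-9.]+).*", "\\1", hdr)))
    evalue <- suppressWarnings(as.numeric(sub(".*E= *([0-9.eE+-]+).*", "\\1", hdr)))
    probs <- t(vapply(lines[(hdr_at + 1):(hdr_at + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(4)))
    probs <- t(probs)
    rownames(probs) <- DNA_BASES
    motifs[[length(motifs) + 1]] <- new_zoops_motif(
      id = id, counts = probs * max(nsites, 1, na.rm = TRUE), probs = probs,
      background = bg, n_sites = ifelse(is.na(nsites), 0, nsites),
      llr = NA_real_, evalue = evalue)
  }
  motifs
}
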