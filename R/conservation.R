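# CNS conservation: motif-anchored windows, progressive alignment, boundary
# delineation, percent identity and CNS-vs-CDS identity enrichment.

#' Extract a motif hit's window with flanking sequence
#'
#' @param hit One-row hit tibble (CDS-relative `start`/`end`).
#' @param promoter One-row promoter tibble for the same gene.
#' @param flank Flank length on each side in bp (default 100).
#' @return One-row tibble: `gene_id`, `rel_start`, `rel_end`, `seq`,
#'   `clipped5`, `clipped3`.
#' @export
extract_window <- function(hit, promoter, flank = 100L) {
  L <- promoter$length
  lo <- hit$start - flank
  hi <- hit$end + flank
  clipped5 <- lo < -L
  clipped3 <- hi > 0
  lo <- max(lo, -L)
  hi <- min(hi, 0L)
  # promoter 0-based index i holds CDS-relative coordinate i - L
  seq <- substr(promoter$seq, lo + L + 1L, hi + L)
  tibble::tibble(gene_id = hit$gene_id, element_id = hit$motif_id,
                 rel_start = lo, rel_end = hi, seq = seq,
                 clipped5 = clipped5, clipped3 = clipped3)
}

#' Extract windows for every best hit of one element
#'
#' @param hits Retained hit tibble.
#' @param promoters Promoter tibble.
#' @param element_id Motif/element id to extract.
#' @inheritParams extract_window
#' @return Tibble of windows, one per promoter carrying the element.
#' @export
extract_windows <- function(hits, promoters, element_id, flank = 100L) {
  eh <- best_hits(hits[hits$motif_id == element_id, ])
  purrr::map_dfr(seq_len(nrow(eh)), function(i) {
    p <- promoters[promoters$gene_id == eh$gene_id[i], ]
    if (nrow(p) == 0) return(tibble::tibble())
    w <- extract_window(eh[i, ], p[1, ], flank = flank)
    w$hit_rel_start <- eh$start[i]
    w$hit_rel_end <- eh$end[i]
    w
  })
}

seq_profile <- function(chars) {
  # 4 x L frequency profile of a character matrix (rows = sequences);
  # N spreads 0.25 over the four bases, gaps contribute nothing.
  L <- ncol(chars)
  prof <- matrix(0, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  n <- nrow(chars)
  for (b in 1:4) {
    prof[b, ] <- colSums(chars == DNA_BASES[b]) / n
  }
  prof <- prof + matrix(colSums(chars == "N") / n / 4, nrow = 4, ncol = L,
                        byrow = TRUE)
  prof
}

#' Progressive multiple alignment of element windows
#'
#' Guide tree from pairwise k-mer distances (k = 6, average linkage);
#' pairwise and profile-profile steps by global alignment with match +1,
#' mismatch -1, gap open -4, gap extend -1. Deterministic.
#'
#' @param windows Tibble from [extract_windows()] (needs `gene_id`, `seq`,
#'   optionally `rel_start`), or a named character vector.
#' @return A `cns_alignment`: `ids`, `mat` (character matrix with `-` gaps),
#'   `column_conservation` (fraction of non-gap rows sharing the modal base),
#'   `meta` (per-row window metadata).
#' @export
align_windows <- function(windows) {
  if (is.character(windows)) {
    windows <- tibble::tibble(gene_id = names(windows) %||%
                                paste0("seq", seq_along(windows)),
                              seq = unname(windows))
  }
  n <- nrow(windows)
  if (n < 2) stop("alignment requires at least two windows")
  seqs <- normalize_alphabet(windows$seq)
  if (any(nchar(seqs) == 0)) stop("empty window sequence")

  merge_order <- if (n == 2) {
    matrix(c(-1L, -2L), nrow = 1)
  } else {
    d <- kmer_distance(seqs, k = 6L)
    stats::hclust(stats::as.dist(d), method = "average")$merge
  }

  clusters <- purrr::map(seqs, function(s) {
    matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
  })
  state <- vector("list", nrow(merge_order))
  idx <- vector("list", nrow(merge_order))
  get_cluster <- function(ref) {
    if (ref < 0) list(mat = clusters[[-ref]], rows = -ref)
    else list(mat = state[[ref]], rows = idx[[ref]])
  }
  for (mi in seq_len(nrow(merge_order))) {
    a <- get_cluster(merge_order[mi, 1])
    b <- get_cluster(merge_order[mi, 2])
    path <- nw_profile(seq_profile(a$mat), seq_profile(b$mat),
                       1, -1, 4, 1)
    la <- sum(path != 3)
    lb <- sum(path != 2)
    newA <- matrix("-", nrow = nrow(a$mat), ncol = length(path))
    newB <- matrix("-", nrow = nrow(b$mat), ncol = length(path))
    newA[, path != 3] <- a$mat
    newB[, path != 2] <- b$mat
    state[[mi]] <- rbind(newA, newB)
    idx[[mi]] <- c(a$rows, b$rows)
  }
  final <- state[[nrow(merge_order)]]
  rows <- idx[[nrow(merge_order)]]
  o <- order(rows)
  mat <- final[o, , drop = FALSE]
  rownames(mat) <- windows$gene_id
  structure(
    list(ids = windows$gene_id, mat = mat,
         column_conservation = conservation_profile(mat),
         meta = windows),
    class = "cns_alignment"
  )
}

kmer_distance <- function(seqs, k = 6L) {
  sets <- purrr::map(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - inter / uni
    }
  }
  d
}

conservation_profile <- function(mat) {
  apply(mat, 2, function(col) {
    nongap <- col != "-"
    if (!any(nongap)) return(0)
    counts <- tabulate(match(col[nongap], DNA_BASES), nbins = 4L)
    max(counts) / sum(nongap)
  })
}

#' @export
print.cns_alignment <- function(x, ...) {
  cat("<cns_alignment> ", length(x$ids), " sequences x ", ncol(x$mat),
      " columns; mean conservation ",
      round(mean(x$column_conservation), 3), "\n", sep = "")
  invisible(x)
}

#' Alignment columns covering a CDS-relative interval of one row
#'
#' @param alignment A `cns_alignment` whose `meta` carries `rel_start`.
#' @param gene_id Row to anchor on.
#' @param rel_start,rel_end CDS-relative half-open interval (e.g. the motif
#'   core of that row's hit).
#' @return Integer vector of alignment column indices.
#' @export
columns_for_interval <- function(alignment, gene_id, rel_start, rel_end) {
  ri <- match(gene_id, alignment$ids)
  if (is.na(ri)) stop("gene not in alignment: ", gene_id)
  meta <- alignment$meta[ri, ]
  row <- alignment$mat[ri, ]
  ungapped_before <- cumsum(row != "-") - as.integer(row != "-")
  rel_of_col <- meta$rel_start + ungapped_before
  which(row != "-" & rel_of_col >= rel_start & rel_of_col < rel_end)
}

#' Delineate CNS boundaries around a motif core
#'
#' The CNS column span extends the core in both directions for as long as
#' every sliding window of `window` newly added columns (truncated while the
#' extension is shorter than `window`) keeps mean column conservation at or
#' above `cons_threshold`. Raising the threshold never widens the span.
#' Per-ortholog intervals and sequences are obtained by ungapping each row
#' over the delineated columns.
#'
#' @param alignment A `cns_alignment` (with `rel_start` in its meta).
#' @param core_columns Integer vector of alignment columns of the motif core.
#' @param cons_threshold Minimum mean conservation per window (default 0.5).
#' @param window Sliding-window size in columns (default 10).
#' @return Tibble per ortholog: `gene_id`, `rel_start`, `rel_end`, `length`,
#'   `seq`; the delineated column span is attached as attribute `"columns"`.
#' @export
delineate_cns <- function(alignment, core_columns, cons_threshold = 0.5,
                          window = 10L) {
  if (length(core_columns) == 0) stop("motif core columns absent from alignment")
  cons <- alignment$column_conservation
  nc <- length(cons)
  lo <- min(core_columns)
  hi <- max(core_columns)

  left <- lo
  while (left > 1) {
    a <- left - 1L
    win_cols <- a:min(a + window - 1L, lo - 1L)
    if (mean(cons[win_cols]) >= cons_threshold) left <- a else break
  }
  right <- hi
  while (right < nc) {
    b <- right + 1L
    win_cols <- max(b - window + 1L, hi + 1L):b
    if (mean(cons[win_cols]) >= cons_threshold) right <- b else break
  }
  span <- left:right

  out <- purrr::map_dfr(seq_along(alignment$ids), function(ri) {
    row <- alignment$mat[ri, ]
    nongap <- row != "-"
    in_span <- nongap & seq_along(row) %in% span
    if (!any(in_span)) {
      return(tibble::tibble(gene_id = alignment$ids[ri],
                            rel_start = NA_integer_, rel_end = NA_integer_,
                            length = 0L, seq = ""))
    }
    ungapped_before <- cumsum(nongap) - as.integer(nongap)
    offs <- ungapped_before[in_span]
    rel0 <- alignment$meta$rel_start[ri]
    tibble::tibble(
      gene_id = alignment$ids[ri],
      rel_start = rel0 + min(offs),
      rel_end = rel0 + max(offs) + 1L,
      length = sum(in_span),
      seq = paste(row[in_span], collapse = "")
    )
  })
  attr(out, "columns") <- span
  out
}

#' Pairwise percent identity from a fresh global alignment
#'
#' Global alignment with the same parameters as [align_windows()];
#' `PID = 100 * matches / alignment columns`. Symmetric, 100 on identical
#' sequences, invariant under simultaneous reverse-complement.
#'
#' @param a,b Sequence strings.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  ca <- encode_seq(normalize_alphabet(a))
  cb <- encode_seq(normalize_alphabet(b))
  path <- nw_pair(ca, cb, 1, -1, 4, 1)
  ai <- cumsum(path != 3)
  bi <- cumsum(path != 2)
  aligned <- path == 1
  ia <- ai[aligned]
  ib <- bi[aligned]
  matches <- sum(ca[ia] == cb[ib] & ca[ia] <= 4L)
  100 * matches / length(path)
}

#' Symmetric percent-identity matrix
#'
#' @param seqs Named character vector of sequences.
#' @return Symmetric matrix with a 100 diagonal.
#' @export
pid_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- percent_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' CNS-vs-CDS identity enrichment relative to a reference ortholog
#'
#' For each non-reference ortholog, `log2(box_pid / cds_pid)` of its pairwise
#' identities with the reference, grouped by lineage. Same-species pairs are
#' excluded; pairs with zero CDS identity are dropped and logged.
#'
#' @param box_pid,cds_pid Percent-identity matrices over the same ortholog
#'   ids (rows/columns named by `gene_id`).
#' @param meta Tibble with `gene_id`, `species`, `lineage`.
#' @param reference Reference `gene_id` (e.g. the Arabidopsis-like ortholog).
#' @return Tibble: `gene_id`, `lineage`, `box_pid`, `cds_pid`,
#'   `log2_enrichment`; dropped pairs in attribute `"dropped"`.
#' @export
identity_enrichment <- function(box_pid, cds_pid, meta, reference) {
  if (!setequal(rownames(box_pid), rownames(cds_pid))) {
    stop("box and CDS identity matrices cover different ortholog sets")
  }
  if (!(reference %in% rownames(box_pid))) {
    stop("reference ortholog not in identity matrices: ", reference)
  }
  ref_species <- meta$species[meta$gene_id == reference][1]
  others <- setdiff(rownames(box_pid), reference)
  rows <- purrr::map_dfr(others, function(g) {
    tibble::tibble(
      gene_id = g,
      lineage = meta$lineage[meta$gene_id == g][1],
      species = meta$species[meta$gene_id == g][1],
      box_pid = box_pid[reference, g],
      cds_pid = cds_pid[reference, g]
    )
  })
  rows <- rows[rows$species != ref_species, , drop = FALSE]
  dropped <- rows[rows$cds_pid == 0, , drop = FALSE]
  kept <- rows[rows$cds_pid > 0, , drop = FALSE]
  kept$log2_enrichment <- log2(kept$box_pid / kept$cds_pid)
  out <- kept[, c("gene_id", "lineage", "box_pid", "cds_pid", "log2_enrichment")]
  attr(out, "dropped") <- dropped
  out
}
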