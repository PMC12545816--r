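# Rescanning promoters for curated motifs: log-odds scoring, exact PSSM
# p-values by dynamic programming over the discretized score distribution,
# Benjamini-Hochberg q-values over the full scanned universe, and the
# orientation / clade-prevalence hit filters.

#' Log-odds score of a motif window
#'
#' `score = sum_j log2(probs[base_j, j] / background[base_j])`; `N` bases
#' contribute 0 for their column.
#'
#' @param motif A `zoops_motif`.
#' @param sequence Sequence string.
#' @param position 1-based window start.
#' @param strand `"+"` to score the window as-is, `"-"` to score its reverse
#'   complement.
#' @return Log-odds score in log2 units.
#' @export
score_pssm <- function(motif, sequence, position, strand = "+") {
  w <- motif$w
  win <- substr(normalize_alphabet(sequence), position, position + w - 1L)
  if (nchar(win) < w) stop("window does not fit in sequence")
  if (strand == "-") win <- revcomp(win)
  code <- encode_seq(win)
  lod <- log2(motif$probs / motif$background)
  unname(sum(ifelse(code <= 4L, lod[cbind(pmin(code, 4L), seq_len(w))], 0)))
}

#' Exact PSSM p-value table by score-distribution dynamic programming
#'
#' Computes `P(score >= s)` for a window drawn from the 0-order background by
#' column-wise convolution of per-column score distributions, discretized on a
#' log2-score grid of the given granularity. Exact up to discretization.
#'
#' @param motif A `zoops_motif` with finite log-odds (pseudocounted probs).
#' @param granularity Score bin width in log2 units (default 1e-3).
#' @return A `pssm_pvalue_table` with the per-column integer score offsets and
#'   the tail distribution; use [pssm_pvalue()] to look up p-values.
#' @export
pvalue_table <- function(motif, granularity = 1e-3) {
  if (granularity <= 0) stop("granularity must be positive")
  lod <- log2(motif$probs / motif$background)
  if (!all(is.finite(lod))) stop("motif has non-finite log-odds; apply pseudocounts")
  off <- round(lod / granularity)
  w <- ncol(off)
  # running support of the convolved distribution: [vec_lo, vec_lo + length - 1]
  vec <- 1
  vec_lo <- 0L
  for (c in seq_len(w)) {
    col_lo <- min(off[, c])
    col_hi <- max(off[, c])
    new_lo <- vec_lo + col_lo
    new_len <- length(vec) + (col_hi - col_lo)
    nv <- numeric(new_len)
    for (b in 1:4) {
      sh <- off[b, c] - col_lo
      nv[(1 + sh):(length(vec) + sh)] <-
        nv[(1 + sh):(length(vec) + sh)] + vec * motif$background[b]
    }
    vec <- nv
    vec_lo <- new_lo
  }
  tail <- rev(cumsum(rev(vec)))
  structure(
    list(granularity = granularity, off = off, min_score = vec_lo,
         tail = tail, w = w),
    class = "pssm_pvalue_table"
  )
}

#' Look up exact PSSM p-values
#'
#' @param table A `pssm_pvalue_table` from [pvalue_table()].
#' @param score Numeric log2 scores (discretized internally on the table's
#'   grid) or integer grid offsets when `integer_score = TRUE`.
#' @param integer_score Whether `score` is already on the integer grid.
#' @return `P(score' >= score)` under the background model.
#' @export
pssm_pvalue <- function(table, score, integer_score = FALSE) {
  idx <- if (integer_score) score else round(score / table$granularity)
  idx <- idx - table$min_score + 1L
  idx <- pmin(pmax(idx, 1L), length(table$tail))
  unname(table$tail[idx])
}

#' Scan promoters for motif occurrences
#'
#' Both strands of every promoter are scanned with each motif's discretized
#' log-odds matrix; windows with `p < p_threshold` are retained and
#' overlapping hits of the same motif in the same promoter are resolved to
#' the best p-value (ties: most-downstream start, then plus strand).
#' Benjamini-Hochberg q-values are computed per motif over the full scanned
#' universe (all candidate positions on both strands, the BH denominator m),
#' before overlap resolution.
#'
#' @param promoters Promoter tibble or named character vector.
#' @param motifs List of `zoops_motif` objects (or a single motif).
#' @param p_threshold Raw p-value threshold for retaining hits (default 1e-4).
#' @param granularity Score discretization in log2 units.
#' @return Tibble of hits: `motif_id`, `gene_id`, CDS-relative half-open
#'   `start`/`end` (`end <= 0`), `strand_match`, `score` (log2), `pvalue`,
#'   `qvalue`. The scanned-position counts per motif are attached as
#'   attribute `"n_scanned"`.
#' @export
scan_promoters <- function(promoters, motifs, p_threshold = 1e-4,
                           granularity = 1e-3) {
  if (inherits(motifs, "zoops_motif")) motifs <- list(motifs)
  seqs <- promoter_seqs(promoters)
  lens <- nchar(seqs)
  all_hits <- list()
  n_scanned <- stats::setNames(numeric(length(motifs)),
                               vapply(motifs, `[[`, character(1), "id"))
  for (m in motifs) {
    tab <- pvalue_table(m, granularity)
    offm <- rbind(m$off %||% tab$off, 0L) # row 5: N contributes 0
    w <- m$w
    scannable <- lens >= w
    if (!any(scannable)) next
    index <- scan_index(seqs[scannable], w)
    offv <- as.vector(offm)
    IDX <- index$W + matrix((0:(w - 1L)) * 5L, nrow = nrow(index$W),
                            ncol = w, byrow = TRUE)
    iscore <- .rowSums(offv[IDX], nrow(index$W), w)
    pvals <- pssm_pvalue(tab, iscore, integer_score = TRUE)
    m_total <- length(pvals)
    n_scanned[m$id] <- m_total

    q_all <- bh_stepup(pvals, m_total)
    keep <- which(pvals < p_threshold)
    if (length(keep) == 0) next
    gid <- names(seqs[scannable])[index$group[keep]]
    L <- index$lens[index$group[keep]]
    rel_start <- index$pos[keep] - 1L - L
    hits <- tibble::tibble(
      motif_id = m$id,
      gene_id = gid,
      start = rel_start,
      end = rel_start + w,
      strand_match = index$strand[keep],
      score = iscore[keep] * granularity,
      pvalue = pvals[keep],
      qvalue = q_all[keep]
    )
    all_hits[[length(all_hits) + 1]] <- resolve_overlaps(hits)
  }
  out <- dplyr::bind_rows(all_hits)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, .data$motif_id, .data$gene_id, .data$start,
                          .data$strand_match)
  }
  attr(out, "n_scanned") <- n_scanned
  out
}

# Greedy best-p resolution of overlapping same-motif hits within a promoter.
resolve_overlaps <- function(hits) {
  hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$pvalue, -df$start, df$strand_match), ]
      kept <- integer(0)
      for (i in seq_len(nrow(df))) {
        if (length(kept) == 0 ||
            all(df$start[i] >= df$end[kept] | df$end[i] <= df$start[kept])) {
          kept <- c(kept, i)
        }
      }
      df[sort(kept), ]
    }) |>
    dplyr::ungroup()
}

bh_stepup <- function(p, m) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Benjamini-Hochberg q-values with an explicit candidate universe
#'
#' Step-up BH over each motif's p-value set with denominator `m`, the number
#' of scanned candidate positions for that motif (not just retained hits).
#'
#' @param hits Hit tibble with `motif_id` and `pvalue`.
#' @param m Named vector (per motif id) or single number of scanned candidate
#'   positions.
#' @return `hits` with a recomputed `qvalue` column.
#' @export
bh_qvalues <- function(hits, m) {
  purrr::map_dfr(split(hits, hits$motif_id), function(df) {
    mi <- if (length(m) == 1 && is.null(names(m))) m else m[[df$motif_id[1]]]
    if (is.null(mi) || is.na(mi)) stop("no m for motif ", df$motif_id[1])
    if (mi < nrow(df)) {
      stop("m (", mi, ") smaller than the number of hits (", nrow(df),
           ") for motif ", df$motif_id[1])
    }
    df$qvalue <- bh_stepup(df$pvalue, mi)
    df
  })
}

#' Apply significance, orientation and clade-prevalence hit filters
#'
#' Hits with `q >= q_max` are dropped first, then antisense hits
#' (`strand_match == "-"`, i.e. not in the gene's orientation), and finally
#' all hits of a motif within a lineage-by-clade cell whose promoter
#' prevalence is below `prevalence_min` - unless the lineage is exempt (low
#' sampling depth, e.g. early-diverged groups).
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param promoters Promoter tibble carrying `gene_id`, `lineage`, `clade`
#'   (and `species` for species-level prevalence).
#' @param q_max q-value threshold (default 0.01).
#' @param prevalence_min Minimum fraction of promoters in the cell with a hit
#'   (default 0.10).
#' @param exempt_lineages Lineages exempt from the prevalence filter.
#' @param level Prevalence denominator: `"gene"` counts promoters, `"species"`
#'   counts species with at least one hit over species in the cell.
#' @return List: `hits` (retained, sorted), `prevalence` (per motif x lineage
#'   x clade cell), `removal_log` (hits removed at each step).
#' @export
filter_hits <- function(hits, promoters, q_max = 0.01, prevalence_min = 0.10,
                        exempt_lineages = character(0),
                        level = c("gene", "species")) {
  level <- match.arg(level)
  unknown <- setdiff(hits$gene_id, promoters$gene_id)
  if (length(unknown) > 0) {
    stop("hits reference gene(s) without promoter metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  meta_cols <- intersect(c("gene_id", "species", "lineage", "clade"),
                         names(promoters))
  if (!all(c("lineage", "clade") %in% meta_cols)) {
    stop("promoters must carry lineage and clade labels")
  }
  h <- dplyr::left_join(hits, promoters[, meta_cols], by = "gene_id")

  log_rows <- list()
  n0 <- nrow(h)
  h1 <- h[h$qvalue < q_max, , drop = FALSE]
  log_rows$q_filter <- n0 - nrow(h1)
  h2 <- h1[h1$strand_match == "+", , drop = FALSE]
  log_rows$orientation_filter <- nrow(h1) - nrow(h2)

  cells <- promoters |>
    dplyr::count(.data$lineage, .data$clade, name = "n_promoters")
  prev <- h2 |>
    dplyr::distinct(.data$motif_id, .data$lineage, .data$clade, .data$gene_id,
                    .data$species) |>
    dplyr::group_by(.data$motif_id, .data$lineage, .data$clade) |>
    dplyr::summarise(n_with_hit = dplyr::n_distinct(.data$gene_id),
                     n_species_with_hit = dplyr::n_distinct(.data$species),
                     .groups = "drop") |>
    dplyr::left_join(cells, by = c("lineage", "clade"))
  if (level == "species") {
    sp_cells <- promoters |>
      dplyr::group_by(.data$lineage, .data$clade) |>
      dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                       .groups = "drop")
    prev <- dplyr::left_join(prev, sp_cells, by = c("lineage", "clade"))
    prev$prevalence <- prev$n_species_with_hit / prev$n_species
  } else {
    prev$prevalence <- prev$n_with_hit / prev$n_promoters
  }
  prev$exempt <- prev$lineage %in% exempt_lineages
  prev$retained <- prev$exempt | prev$prevalence >= prevalence_min

  h3 <- dplyr::semi_join(
    h2, prev[prev$retained, c("motif_id", "lineage", "clade")],
    by = c("motif_id", "lineage", "clade"))
  log_rows$prevalence_filter <- nrow(h2) - nrow(h3)

  h3 <- dplyr::arrange(h3, .data$motif_id, .data$gene_id, .data$start,
                       .data$strand_match)
  list(
    hits = h3,
    prevalence = dplyr::arrange(prev, .data$motif_id, .data$lineage, .data$clade),
    removal_log = tibble::tibble(step = names(log_rows),
                                 n_removed = unlist(log_rows, use.names = FALSE))
  )
}

#' Map CDS-relative hits to genomic coordinates
#'
#' @param hits Hit tibble.
#' @param promoters Promoter tibble with `gene_id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end`.
#' @return Hits with `chrom`, `gstart`, `gend` (0-based half-open) and
#'   `gstrand` (genomic strand of the match) columns added.
#' @export
hits_to_genomic <- function(hits, promoters) {
  h <- dplyr::left_join(
    hits, promoters[, c("gene_id", "chrom", "strand", "cds_start", "cds_end")],
    by = "gene_id")
  g <- promoter_rel_to_genomic(h, h$start, h$end)
  h$gstart <- g$start
  h$gend <- g$end
  h$gstrand <- ifelse(h$strand_match == "+", h$strand,
                      ifelse(h$strand == "+", "-", "+"))
  h
}

#' Export hits as GFF3 in genomic coordinates
#'
#' @inheritParams hits_to_genomic
#' @param path Output file.
#' @export
write_hits_gff3 <- function(hits, promoters, path) {
  g <- hits_to_genomic(hits, promoters)
  lines <- c("##gff-version 3",
             paste(g$chrom, "plantcns", "nucleotide_motif",
                   g$gstart + 1L, g$gend, sprintf("%.3f", g$score), g$gstrand,
                   ".",
                   paste0("ID=", g$motif_id, ":", g$gene_id, ":", g$start,
                          ";Name=", g$motif_id,
                          ";pvalue=", signif(g$pvalue, 4),
                          ";qvalue=", signif(g$qvalue, 4)),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
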