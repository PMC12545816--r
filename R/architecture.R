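# Promoter motif architecture: positional summaries, consensus order,
# colinear/unordered classification, co-occurrence and spacer statistics.

#' Per-motif positional summary
#'
#' @param hits Retained hit tibble (CDS-relative coordinates).
#' @param promoters Promoter tibble (used only to report the denominator).
#' @return Tibble per motif: hit count, promoters with a hit, quantiles of the
#'   CDS-relative midpoint and width.
#' @export
position_summary <- function(hits, promoters = NULL) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(motif_id = character(), n_hits = integer(),
                          n_promoters = integer(), width = integer(),
                          midpoint_q25 = numeric(), midpoint_median = numeric(),
                          midpoint_q75 = numeric()))
  }
  hits |>
    dplyr::mutate(midpoint = (.data$start + .data$end) / 2,
                  width = .data$end - .data$start) |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_promoters = dplyr::n_distinct(.data$gene_id),
      width = as.integer(stats::median(.data$width)),
      midpoint_q25 = stats::quantile(.data$midpoint, 0.25),
      midpoint_median = stats::median(.data$midpoint),
      midpoint_q75 = stats::quantile(.data$midpoint, 0.75),
      .groups = "drop"
    )
}

# Best (lowest-p) hit per motif per promoter.
best_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$gene_id, .data$motif_id) |>
    dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Family-wide consensus motif order
#'
#' Motifs are ordered by their median CDS-relative midpoint, most 5' (most
#' negative) first; ties are broken lexicographically by motif id and
#' flagged. Support is the fraction of multi-motif promoters classified
#' colinear against this order.
#'
#' @param hits Retained hit tibble (one clade).
#' @return A list of class `consensus_order`: `order` (motif ids 5' to 3'),
#'   `medians`, `tied` flag, `support`.
#' @export
consensus_order <- function(hits) {
  bh <- best_hits(hits)
  multi <- bh |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(multi) == 0) {
    stop("order undefined: no promoter carries two or more distinct motifs")
  }
  med <- bh |>
    dplyr::mutate(midpoint = (.data$start + .data$end) / 2) |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(median_mid = stats::median(.data$midpoint), .groups = "drop") |>
    dplyr::arrange(.data$median_mid, .data$motif_id)
  tied <- anyDuplicated(med$median_mid) > 0
  out <- structure(
    list(order = med$motif_id, medians = stats::setNames(med$median_mid, med$motif_id),
         tied = tied, support = NA_real_),
    class = "consensus_order"
  )
  cls <- classify_colinearity(hits, out)
  n_multi <- sum(cls$class %in% c("colinear", "unordered"))
  out$support <- if (n_multi > 0) sum(cls$class == "colinear") / n_multi else NA_real_
  out
}

#' @export
print.consensus_order <- function(x, ...) {
  cat("<consensus_order> ", paste(x$order, collapse = " -> "),
      if (x$tied) "  (ties broken lexicographically)" else "",
      "\n  support = ", round(x$support, 3), "\n", sep = "")
  invisible(x)
}

#' Classify each promoter's motif arrangement against the consensus order
#'
#' A promoter is `colinear` when its distinct motifs, sorted by midpoint,
#' form an order-consistent restriction of the consensus; `unordered`
#' otherwise; `single` with exactly one distinct motif; `none` with zero.
#' Order only is compared, never distances, so the classification is
#' invariant under uniform translation of coordinates.
#'
#' @param hits Hit tibble (deduplicated to best hit per motif per promoter
#'   internally).
#' @param consensus A `consensus_order`.
#' @param promoters Optional promoter tibble so promoters without hits are
#'   reported as `none`.
#' @return Tibble: `gene_id`, `n_motifs`, `class`.
#' @export
classify_colinearity <- function(hits, consensus, promoters = NULL) {
  bh <- best_hits(hits) |>
    dplyr::mutate(midpoint = (.data$start + .data$end) / 2)
  per_gene <- bh |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$midpoint, .by_group = TRUE) |>
    dplyr::summarise(n_motifs = dplyr::n(),
                     order_seq = list(.data$motif_id), .groups = "drop")
  rank_of <- stats::setNames(seq_along(consensus$order), consensus$order)
  per_gene$class <- vapply(seq_len(nrow(per_gene)), function(i) {
    ids <- per_gene$order_seq[[i]]
    if (length(ids) == 1) return("single")
    r <- rank_of[ids]
    if (anyNA(r)) return("unordered")
    if (all(diff(r) > 0)) "colinear" else "unordered"
  }, character(1))
  out <- per_gene[, c("gene_id", "n_motifs", "class")]
  if (!is.null(promoters)) {
    missing <- setdiff(promoters$gene_id, out$gene_id)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(gene_id = missing, n_motifs = 0L, class = "none"))
  }
  dplyr::arrange(out, .data$gene_id)
}

#' Element co-occurrence counts
#'
#' For a pair of elements, counts promoters per lineage carrying both, only
#' the upstream one, only the downstream one, or neither, plus per-species
#' "at least once" counts.
#'
#' @param hits Retained hit tibble.
#' @param promoters Promoter tibble with `gene_id`, `species`, `lineage`.
#' @param elements Length-2 character vector `(upstream_id, downstream_id)`.
#' @return List: `genes` (per-lineage contingency counts), `species`
#'   (per-lineage species-level at-least-once counts), `overall` (totals).
#' @export
cooccurrence <- function(hits, promoters, elements) {
  stopifnot(length(elements) == 2)
  has <- promoters |>
    dplyr::select("gene_id", "species", "lineage") |>
    dplyr::mutate(
      has_up = .data$gene_id %in% hits$gene_id[hits$motif_id == elements[1]],
      has_down = .data$gene_id %in% hits$gene_id[hits$motif_id == elements[2]]
    )
  genes <- has |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(
      both = sum(.data$has_up & .data$has_down),
      only_upstream = sum(.data$has_up & !.data$has_down),
      only_downstream = sum(!.data$has_up & .data$has_down),
      neither = sum(!.data$has_up & !.data$has_down),
      .groups = "drop"
    )
  species <- has |>
    dplyr::group_by(.data$lineage, .data$species) |>
    dplyr::summarise(up_once = any(.data$has_up), down_once = any(.data$has_down),
                     both_once = any(.data$has_up & .data$has_down),
                     .groups = "drop") |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(n_species = dplyr::n(),
                     species_with_upstream = sum(.data$up_once),
                     species_with_downstream = sum(.data$down_once),
                     species_with_both = sum(.data$both_once),
                     .groups = "drop")
  overall <- genes |>
    dplyr::summarise(dplyr::across(c("both", "only_upstream",
                                    "only_downstream", "neither"), sum))
  list(genes = genes, species = species, overall = overall)
}

#' Spacer distances between an element pair
#'
#' For each promoter carrying both elements,
#' `d_spacer = downstream.start - upstream.end` (CDS-relative). With
#' duplicated copies the order-consistent pair minimizing the spacer is used
#' and flagged `multi_copy`; overlapping elements yield `d_spacer = 0` with an
#' `overlap` flag.
#'
#' @param hits Retained hit tibble.
#' @param elements Length-2 character vector `(upstream_id, downstream_id)`.
#' @return Tibble: `gene_id`, `upstream_id`, `downstream_id`, `d_spacer`,
#'   `multi_copy`, `overlap`.
#' @export
spacer_distances <- function(hits, elements) {
  stopifnot(length(elements) == 2)
  up <- hits[hits$motif_id == elements[1], ]
  down <- hits[hits$motif_id == elements[2], ]
  genes <- intersect(up$gene_id, down$gene_id)
  purrr::map_dfr(genes, function(g) {
    u <- up[up$gene_id == g, ]
    d <- down[down$gene_id == g, ]
    pairs <- tidyr::expand_grid(ui = seq_len(nrow(u)), di = seq_len(nrow(d)))
    pairs$d_spacer <- d$start[pairs$di] - u$end[pairs$ui]
    ordered <- pairs[pairs$d_spacer >= 0, , drop = FALSE]
    if (nrow(ordered) > 0) {
      best <- ordered[which.min(ordered$d_spacer), ]
      overlap <- FALSE
      dsp <- best$d_spacer
    } else {
      best <- pairs[which.max(pairs$d_spacer), ]
      overlap <- TRUE
      dsp <- 0
    }
    tibble::tibble(
      gene_id = g, upstream_id = elements[1], downstream_id = elements[2],
      d_spacer = dsp,
      multi_copy = nrow(u) > 1 || nrow(d) > 1,
      overlap = overlap
    )
  })
}
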