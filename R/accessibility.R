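# Chromatin accessibility over promoter windows: track loading, per-promoter
# max normalization, element fold changes, stage statistics, pseudo-bulk.

#' Genomic promoter window for coverage analysis
#'
#' @param gene One-row gene/promoter tibble (`chrom`, `strand`, `cds_start`,
#'   `cds_end`).
#' @param rel CDS-relative window, default `c(-2000, 500)`.
#' @return Window spec list used by [load_tracks()].
#' @export
coverage_window <- function(gene, rel = c(-2000L, 500L)) {
  if (gene$strand == "+") {
    gstart <- gene$cds_start + rel[1]
    gend <- gene$cds_start + rel[2]
  } else {
    gstart <- gene$cds_end - rel[2]
    gend <- gene$cds_end - rel[1]
  }
  list(chrom = gene$chrom, gstart = gstart, gend = gend,
       strand = gene$strand, rel = rel)
}

#' Load per-cell-type coverage tracks over a promoter window
#'
#' Reads bedGraph (or BigWig, via the same importer) tracks and expands them
#' to per-base values over the CDS-relative window; positions without an
#' interval are 0. Overlapping bedGraph intervals raise an error naming the
#' interval.
#'
#' @param tracks Tibble with `cell_type`, `stage`, `path`.
#' @param window Window spec from [coverage_window()].
#' @return Tibble: `cell_type`, `stage`, `rel_pos`, `value`.
#' @export
load_tracks <- function(tracks, window) {
  npos <- window$gend - window$gstart
  rel_pos <- seq(window$rel[1], window$rel[2] - 1L)
  purrr::map_dfr(seq_len(nrow(tracks)), function(i) {
    gr <- rtracklayer::import(tracks$path[i])
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == window$chrom]
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(ov) > 0) {
      bad <- gr[S4Vectors::queryHits(ov)[1]]
      stop("overlapping bedGraph intervals in ", tracks$path[i], " at ",
           window$chrom, ":", GenomicRanges::start(bad) - 1, "-",
           GenomicRanges::end(bad))
    }
    vals <- numeric(npos)
    starts <- pmax(GenomicRanges::start(gr) - 1L, window$gstart)
    ends <- pmin(GenomicRanges::end(gr), window$gend)
    keep <- which(starts < ends)
    for (k in keep) {
      vals[(starts[k] - window$gstart + 1L):(ends[k] - window$gstart)] <-
        gr$score[k]
    }
    if (window$strand == "-") vals <- rev(vals)
    tibble::tibble(cell_type = tracks$cell_type[i],
                   stage = tracks$stage[i] %||% NA_character_,
                   rel_pos = rel_pos, value = vals)
  })
}

#' Normalize tracks to the highest value across all cell types
#'
#' Every track over one promoter window is divided by the single global
#' maximum across all tracks, so at least one position equals 1 afterwards.
#'
#' @param tracks Track tibble (`cell_type`, `rel_pos`, `value`).
#' @return Tracks with `value` scaled to `[0, 1]`.
#' @export
normalize_tracks <- function(tracks) {
  mx <- max(tracks$value)
  if (mx <= 0) stop("no signal: global maximum across tracks is 0")
  dplyr::mutate(tracks, value = .data$value / mx)
}

#' Element fold change and normalized coverage per cell type
#'
#' `FC = mean(values over element) / mean(values over window)` on raw values
#' (scale-invariant); `norm_cov` is the mean normalized value within the
#' element, after global max normalization across all cell types.
#'
#' @param tracks Raw track tibble over one promoter window.
#' @param elements Tibble with `element_id`, `rel_start`, `rel_end`
#'   (CDS-relative, intersected with the window).
#' @return Tibble per element x cell type: `FC`, `norm_cov`,
#'   `undefined` flag (window mean 0).
#' @export
box_fold_change <- function(tracks, elements) {
  norm <- tryCatch(normalize_tracks(tracks), error = function(e) NULL)
  purrr::map_dfr(seq_len(nrow(elements)), function(ei) {
    e <- elements[ei, ]
    purrr::map_dfr(split(tracks, tracks$cell_type), function(tr) {
      inside <- tr$rel_pos >= e$rel_start & tr$rel_pos < e$rel_end
      if (!any(inside)) {
        stop("element ", e$element_id, " lies outside the coverage window")
      }
      wmean <- mean(tr$value)
      fc <- if (wmean > 0) mean(tr$value[inside]) / wmean else NA_real_
      nc <- if (!is.null(norm)) {
        ntr <- norm[norm$cell_type == tr$cell_type[1], ]
        mean(ntr$value[inside])
      } else {
        NA_real_
      }
      tibble::tibble(element_id = e$element_id, cell_type = tr$cell_type[1],
                     stage = tr$stage[1], FC = fc, norm_cov = nc,
                     undefined = wmean == 0)
    })
  })
}

#' One-tailed t-test of element fold changes against 1
#'
#' One-sample t of the per-cell-type fold changes against the promoter
#' average (FC = 1), one-tailed in the direction of the sample mean.
#'
#' @param fc Numeric fold changes across cell types (at least 3).
#' @return Tibble: `n`, `mean_fc`, `t`, `df`, `p`, `direction`, `degenerate`
#'   (zero variance away from 1).
#' @export
test_fc_vs_one <- function(fc) {
  fc <- fc[is.finite(fc)]
  n <- length(fc)
  if (n < 3) stop("at least 3 cell-type fold changes required, got ", n)
  m <- mean(fc)
  s <- stats::sd(fc)
  direction <- if (m >= 1) "greater" else "less"
  if (s == 0) {
    if (m == 1) {
      return(tibble::tibble(n = n, mean_fc = m, t = 0, df = n - 1, p = 0.5,
                            direction = direction, degenerate = FALSE))
    }
    return(tibble::tibble(n = n, mean_fc = m, t = ifelse(m > 1, Inf, -Inf),
                          df = n - 1, p = 0, direction = direction,
                          degenerate = TRUE))
  }
  t <- (m - 1) / (s / sqrt(n))
  p <- if (direction == "greater") {
    stats::pt(t, df = n - 1, lower.tail = FALSE)
  } else {
    stats::pt(t, df = n - 1, lower.tail = TRUE)
  }
  tibble::tibble(n = n, mean_fc = m, t = t, df = n - 1, p = p,
                 direction = direction, degenerate = FALSE)
}

#' Pairwise developmental-stage comparison with Bonferroni correction
#'
#' Welch two-sample t-tests between stages of normalized element coverage;
#' raw p-values are multiplied by the number of tested pairs and capped at 1.
#' Stage pairs with fewer than 2 members on either side are skipped and
#' logged.
#'
#' @param values Tibble with `stage` and `value` (e.g. `norm_cov` per cell
#'   type).
#' @return Tibble per stage pair: group means, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `skipped`.
#' @export
stage_comparison <- function(values) {
  stages <- unique(values$stage)
  if (length(stages) < 2) stop("at least 2 stages required")
  pairs <- utils::combn(sort(stages), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    x <- values$value[values$stage == pr[1]]
    y <- values$value[values$stage == pr[2]]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                            mean_a = mean(x), mean_b = mean(y),
                            t = NA_real_, df = NA_real_, p_raw = NA_real_,
                            skipped = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                   mean_a = mean(x), mean_b = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value, skipped = FALSE)
  })
  n_tested <- sum(!rows$skipped)
  rows$p_bonferroni <- pmin(rows$p_raw * n_tested, 1)
  rows
}

#' Pseudo-bulk aggregation of coverage tracks
#'
#' Per-base sum across all cell types; the stage label is dropped.
#'
#' @param tracks Track tibble over one window.
#' @return Single-track tibble (`cell_type = "pseudo_bulk"`, `stage = NA`).
#' @export
pseudo_bulk <- function(tracks) {
  npos <- tracks |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n = dplyr::n(), lo = min(.data$rel_pos),
                     hi = max(.data$rel_pos), .groups = "drop")
  if (dplyr::n_distinct(npos$n) > 1 || dplyr::n_distinct(npos$lo) > 1 ||
      dplyr::n_distinct(npos$hi) > 1) {
    stop("tracks cover mismatched windows")
  }
  tracks |>
    dplyr::group_by(.data$rel_pos) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::mutate(cell_type = "pseudo_bulk", stage = NA_character_) |>
    dplyr::select("cell_type", "stage", "rel_pos", "value")
}
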