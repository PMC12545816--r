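# End-to-end orchestration: a single declarative config drives promoter
# extraction, discovery, curation, rescanning, filtering, architecture, CNS
# delineation, accessibility and G-quadruplex stages, with per-stage output
# tables, record-level exclusion logging and checksummed manifests.

pipeline_defaults <- function() {
  list(
    fasta = NULL, gff = NULL, homologs = NULL,
    tracks = NULL, # tibble/data.frame: cell_type, stage, path
    stages = c("extract", "discover", "curate", "scan", "filter",
               "architecture", "cns", "accessibility", "gquad"),
    max_len = 20000, min_promoter = 50,
    widths = c(15, 20, 25, 30, 40, 50, 69, 100),
    min_sites = 15, e_max = 0.05, n_motifs = 3, n_starts = 16,
    n_shuffles = 100, p_threshold = 1e-4,
    q_max = 0.01, prevalence_min = 0.10, exempt_lineages = character(0),
    prevalence_level = "gene",
    flank = 100, cons_threshold = 0.5, cons_window = 10,
    atac_window = c(-2000, 500),
    gquad_params = list(list(g_group = 3, loop_range = c(1, 7)),
                        list(g_group = 2, loop_range = c(1, 4))),
    reference_gene = NULL,
    seed = 1
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys and checks threshold
#' ranges. Accepts a list or a path to a JSON file; the normalized config
#' round-trips through JSON unchanged.
#'
#' @param config A named list or a JSON file path (an empty file or list
#'   yields all defaults).
#' @return Normalized config list of class `pcns_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt))) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      list()
    }
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)

  check_range <- function(key, lo, hi, lo_open = FALSE) {
    v <- cfg[[key]]
    bad <- if (lo_open) any(v <= lo | v > hi) else any(v < lo | v > hi)
    if (bad) {
      stop("config key '", key, "' out of range [", lo, ", ", hi, "]: ",
           paste(v, collapse = ", "))
    }
  }
  check_range("q_max", 0, 1, lo_open = TRUE)
  check_range("e_max", 0, 1, lo_open = TRUE)
  check_range("prevalence_min", 0, 1)
  check_range("p_threshold", 0, 1, lo_open = TRUE)
  check_range("min_promoter", 0, Inf)
  check_range("max_len", 1, Inf)
  check_range("widths", 15, 100)
  check_range("min_sites", 1, Inf)
  if (!is.null(cfg$tracks)) cfg$tracks <- tibble::as_tibble(cfg$tracks)
  structure(cfg, class = c("pcns_config", "list"))
}

stage_enabled <- function(cfg, stage) stage %in% cfg$stages

#' Run the CNS discovery pipeline end to end
#'
#' Stages run in fixed order (extract, discover, curate, scan, filter,
#' architecture, cns, accessibility, gquad); motif discovery uses truncated
#' promoters per family clade, rescanning uses full promoters of all clades.
#' When `out_dir` is given every stage writes its tables plus a manifest of
#' parameters and output checksums; identical config + inputs produce
#' byte-identical outputs.
#'
#' @param config A [validate_config()] result (or list/path accepted by it).
#' @param out_dir Optional output directory.
#' @return Named list of stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  logs <- list()

  data <- read_genome(cfg$fasta, cfg$gff, cfg$homologs)
  res$genes <- data$genes

  # --- extract ---------------------------------------------------------------
  truncated <- extract_promoters(data$genes, data$genome, mode = "truncated",
                                 max_len = cfg$max_len,
                                 annotation = data$annotation)
  full <- extract_promoters(data$genes, data$genome, mode = "full",
                            max_len = cfg$max_len)
  logs$extract <- list(
    n_truncated = nrow(truncated), n_full = nrow(full),
    excluded = attr(truncated, "excluded"))
  res$promoters_truncated <- truncated
  res$promoters_full <- full

  # --- discover (per clade, truncated promoters) -----------------------------
  motifs <- list()
  if (stage_enabled(cfg, "discover")) {
    for (clade in unique(truncated$clade)) {
      sub <- truncated[truncated$clade == clade, ]
      if (nrow(sub) < cfg$min_sites) next
      found <- discover(sub, widths = cfg$widths, min_sites = cfg$min_sites,
                        n_motifs = cfg$n_motifs, e_max = cfg$e_max,
                        n_starts = cfg$n_starts, n_shuffles = cfg$n_shuffles,
                        seed = derive_seed(cfg$seed, "discover", clade))
      for (m in found) {
        m$id <- paste0(clade, "_", m$id)
        motifs[[m$id]] <- m
      }
    }
  }
  res$motifs <- motifs

  # --- curate ----------------------------------------------------------------
  if (stage_enabled(cfg, "curate") && length(motifs) > 0) {
    verdicts <- curate(motifs)
    res$curation <- verdicts
    motifs <- motifs[verdicts$motif_id[verdicts$verdict == "pass"]]
  }

  # --- scan + filter (full promoters, all clades) ----------------------------
  if (stage_enabled(cfg, "scan") && length(motifs) > 0) {
    hits <- scan_promoters(full, motifs, p_threshold = cfg$p_threshold)
    res$hits_raw <- hits
    if (stage_enabled(cfg, "filter")) {
      filt <- filter_hits(hits, full, q_max = cfg$q_max,
                          prevalence_min = cfg$prevalence_min,
                          exempt_lineages = cfg$exempt_lineages,
                          level = cfg$prevalence_level)
      res$hits <- filt$hits
      res$prevalence <- filt$prevalence
      logs$filter <- filt$removal_log
    } else {
      res$hits <- hits
    }
  }

  # --- architecture ----------------------------------------------------------
  if (stage_enabled(cfg, "architecture") && !is.null(res$hits) &&
      nrow(res$hits) > 0) {
    res$positions <- position_summary(res$hits, full)
    arch <- list()
    for (clade in unique(full$clade)) {
      ch <- res$hits[res$hits$gene_id %in% full$gene_id[full$clade == clade], ]
      if (dplyr::n_distinct(ch$motif_id) < 2) next
      cons <- tryCatch(consensus_order(ch), error = function(e) NULL)
      if (is.null(cons)) next
      cls <- classify_colinearity(ch, cons,
                                  promoters = full[full$clade == clade, ])
      pair <- utils::head(cons$order, 2)
      arch[[clade]] <- list(
        consensus = cons,
        classes = cls,
        cooccurrence = cooccurrence(ch, full[full$clade == clade, ], pair),
        spacers = spacer_distances(ch, pair)
      )
    }
    res$architecture <- arch
  }

  # --- cns -------------------------------------------------------------------
  if (stage_enabled(cfg, "cns") && !is.null(res$hits) && nrow(res$hits) > 0) {
    cds <- cds_sequences(data$genome, data$genes)
    cns <- list()
    for (mid in unique(res$hits$motif_id)) {
      win <- extract_windows(res$hits, full, mid, flank = cfg$flank)
      if (nrow(win) < 2) next
      aln <- align_windows(win)
      core <- columns_for_interval(aln, win$gene_id[1],
                                   win$hit_rel_start[1], win$hit_rel_end[1])
      regions <- delineate_cns(aln, core, cons_threshold = cfg$cons_threshold,
                               window = cfg$cons_window)
      box_seqs <- stats::setNames(regions$seq, regions$gene_id)
      box_seqs <- box_seqs[nchar(box_seqs) > 0]
      box_pid <- pid_matrix(box_seqs)
      cds_pid <- pid_matrix(cds[names(box_seqs)])
      ref <- cfg$reference_gene %||% names(box_seqs)[1]
      enr <- if (ref %in% names(box_seqs)) {
        identity_enrichment(box_pid, cds_pid, full, ref)
      } else {
        NULL
      }
      cns[[mid]] <- list(alignment = aln, regions = regions,
                         box_pid = box_pid, cds_pid = cds_pid,
                         enrichment = enr)
    }
    res$cns <- cns
  }

  # --- accessibility ---------------------------------------------------------
  if (stage_enabled(cfg, "accessibility") && !is.null(cfg$tracks) &&
      !is.null(res$hits) && nrow(res$hits) > 0) {
    ref <- cfg$reference_gene %||% res$genes$gene_id[1]
    gene <- res$genes[res$genes$gene_id == ref, ]
    win <- coverage_window(gene, rel = cfg$atac_window)
    tracks <- load_tracks(cfg$tracks, win)
    elements <- res$hits[res$hits$gene_id == ref, ] |>
      dplyr::group_by(.data$motif_id) |>
      dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(element_id = .data$motif_id,
                       rel_start = pmax(.data$start, cfg$atac_window[1]),
                       rel_end = pmin(.data$end, cfg$atac_window[2]))
    if (nrow(elements) > 0) {
      records <- box_fold_change(tracks, elements)
      tests <- records |>
        dplyr::group_by(.data$element_id) |>
        dplyr::group_modify(~ test_fc_vs_one(.x$FC)) |>
        dplyr::ungroup()
      stage_tests <- records |>
        dplyr::group_by(.data$element_id) |>
        dplyr::group_modify(function(df, key) {
          stage_comparison(dplyr::transmute(df, stage = .data$stage,
                                            value = .data$norm_cov))
        }) |>
        dplyr::ungroup()
      res$accessibility <- list(tracks = tracks, records = records,
                                fc_tests = tests, stage_tests = stage_tests,
                                pseudo_bulk = pseudo_bulk(tracks))
    }
  }

  # --- gquad -----------------------------------------------------------------
  if (stage_enabled(cfg, "gquad") && !is.null(res$cns) && length(res$cns) > 0) {
    gq <- list()
    for (mid in names(res$cns)) {
      seqs <- stats::setNames(res$cns[[mid]]$regions$seq,
                              res$cns[[mid]]$regions$gene_id)
      seqs <- seqs[nchar(seqs) > 0]
      gq[[mid]] <- purrr::map_dfr(cfg$gquad_params, function(gp) {
        s <- scan_gquad_set(seqs, g_group = gp$g_group,
                            loop_range = gp$loop_range)
        s$element_id <- mid
        s
      })
    }
    res$gquad <- dplyr::bind_rows(gq)
  }

  res$logs <- logs
  if (!is.null(out_dir)) {
    res$paths <- write_pipeline_outputs(res, out_dir)
  }
  res
}

# CDS sequence (gene orientation) per gene from the genome slice.
cds_sequences <- function(genome, genes) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- substr(genome[[g$chrom]], g$cds_start + 1, g$cds_end)
    if (g$strand == "-") s <- revcomp(s)
    s
  }, character(1))
  stats::setNames(out, genes$gene_id)
}

write_pipeline_outputs <- function(res, out_dir) {
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, p, progress = FALSE)
    paths[name] <<- p
  }
  put(res$promoters_truncated[, setdiff(names(res$promoters_truncated), "seq")],
      "promoters_truncated")
  put(res$promoters_full[, setdiff(names(res$promoters_full), "seq")],
      "promoters_full")
  write_promoters_fasta(res$promoters_full,
                        file.path(out_dir, "promoters_full.fa"))
  paths["promoters_full_fasta"] <- file.path(out_dir, "promoters_full.fa")
  if (length(res$motifs) > 0) {
    write_meme(res$motifs, file.path(out_dir, "motifs.meme"))
    paths["motifs"] <- file.path(out_dir, "motifs.meme")
  }
  if (!is.null(res$curation)) put(res$curation, "curation")
  if (!is.null(res$hits)) put(res$hits, "hits")
  if (!is.null(res$prevalence)) put(res$prevalence, "prevalence")
  if (!is.null(res$positions)) put(res$positions, "positions")
  if (!is.null(res$architecture)) {
    for (clade in names(res$architecture)) {
      a <- res$architecture[[clade]]
      put(a$classes, paste0("colinearity_", clade))
      put(a$spacers, paste0("spacers_", clade))
      put(a$cooccurrence$genes, paste0("cooccurrence_", clade))
    }
  }
  if (!is.null(res$cns)) {
    for (mid in names(res$cns)) {
      put(res$cns[[mid]]$regions, paste0("cns_", mid))
      if (!is.null(res$cns[[mid]]$enrichment)) {
        put(res$cns[[mid]]$enrichment, paste0("enrichment_", mid))
      }
    }
  }
  if (!is.null(res$accessibility)) {
    put(res$accessibility$records, "accessibility_records")
    put(res$accessibility$fc_tests, "accessibility_fc_tests")
    put(res$accessibility$stage_tests, "accessibility_stage_tests")
  }
  if (!is.null(res$gquad)) put(res$gquad, "gquad")
  if (!is.null(res$logs$filter)) put(res$logs$filter, "removal_log")

  manifest <- list(
    parameters = unclass(res$config)[setdiff(names(res$config), "tracks")],
    outputs = purrr::map(paths, ~ unname(tools::md5sum(.x)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths["manifest"] <- file.path(out_dir, "run_manifest.json")
  paths
}
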