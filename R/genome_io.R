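#' Read genome, annotation and homolog table
#'
#' Loads a multi-record FASTA, a GFF3 annotation (features of type
#' `gene`/`mRNA`/`CDS`; the CDS span of a gene defines its coding interval) and
#' a tab-separated homolog table with columns `gene_id`, `species`, `clade`,
#' `lineage`. One gene record is produced per homolog-table row; rows whose
#' `gene_id` is absent from the annotation are logged and skipped.
#'
#' All coordinates are 0-based half-open genomic: `cds_start` is the first base
#' of the annotated CDS span, `cds_end` its exclusive end. For genes with
#' several transcripts the span over all annotated CDS features is used, so
#' `cds_start` is the most-upstream CDS start.
#'
#' @param fasta_path Path to a FASTA file of genome sequences.
#' @param gff_path Path to a GFF3 annotation whose seqids match the FASTA ids.
#' @param homolog_path Path to a TSV with header
#'   `gene_id	species	clade	lineage`.
#' @return A list with elements `genome` (named character vector of sequences,
#'   ambiguity codes normalized to `N`), `genes` (tibble of family gene
#'   records), `annotation` (tibble of all annotated genes, used for promoter
#'   boundary computation) and `skipped` (tibble of homolog rows without an
#'   annotated gene).
#' @export
read_genome <- function(fasta_path, gff_path, homolog_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  genome <- normalize_alphabet(as.character(seqs))
  names(genome) <- sub("\\s.*$", "", names(seqs))

  check_gff3_lines(gff_path)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  annotation <- annotation_from_gff(gff)

  hom <- readr::read_tsv(homolog_path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("gene_id", "species", "clade", "lineage")
  missing_cols <- setdiff(required, names(hom))
  if (length(missing_cols) > 0) {
    stop("homolog table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }

  genes <- dplyr::inner_join(hom, annotation, by = "gene_id")
  skipped <- dplyr::anti_join(hom, annotation, by = "gene_id")
  if (nrow(skipped) > 0) {
    message("read_genome: skipped ", nrow(skipped),
            " homolog row(s) absent from the annotation: ",
            paste(utils::head(skipped$gene_id, 5), collapse = ", "))
  }
  bad_chrom <- setdiff(genes$chrom, names(genome))
  if (length(bad_chrom) > 0) {
    stop("annotation seqid(s) absent from FASTA: ",
         paste(bad_chrom, collapse = ", "))
  }
  list(genome = genome,
       genes = tibble::as_tibble(genes),
       annotation = annotation,
       skipped = tibble::as_tibble(skipped))
}

# Cheap structural validation so malformed GFF3 errors name the line.
check_gff3_lines <- function(gff_path) {
  lines <- readLines(gff_path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9]
  if (length(bad) > 0) {
    stop("malformed GFF3 line ", bad[1], " in ", gff_path, ": '",
         substr(lines[bad[1]], 1, 60), "' (expected 9 tab-separated fields)")
  }
  invisible(TRUE)
}

# Collapse a GFF3 GRanges into one row per gene with its CDS span.
annotation_from_gff <- function(gff) {
  meta <- S4Vectors::mcols(gff)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID %||% rep(NA_character_, length(gff)))
  parents <- meta$Parent
  parent1 <- vapply(seq_along(gff), function(i) {
    p <- parents[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  # Map every feature to its owning gene id (CDS -> mRNA -> gene, or CDS -> gene).
  gene_of <- ids
  is_gene <- type == "gene"
  mrna <- type == "mRNA"
  mrna_gene <- stats::setNames(parent1[mrna], ids[mrna])
  cds <- which(type == "CDS")
  if (length(cds) == 0) stop("GFF3 contains no CDS features")
  cds_gene <- parent1[cds]
  via_mrna <- cds_gene %in% names(mrna_gene)
  cds_gene[via_mrna] <- mrna_gene[cds_gene[via_mrna]]

  tibble::tibble(
    gene_id = cds_gene,
    chrom = as.character(GenomicRanges::seqnames(gff)[cds]),
    start0 = GenomicRanges::start(gff)[cds] - 1L,
    end0 = GenomicRanges::end(gff)[cds],
    strand = as.character(GenomicRanges::strand(gff)[cds])
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      cds_start = min(.data$start0),
      cds_end = max(.data$end0),
      strand = dplyr::first(.data$strand),
      .groups = "drop"
    )
}

#' Extract strand-normalized upstream promoter regions
#'
#' For each family gene, the upstream region spans from the CDS start back
#' toward 5' until the nearest CDS boundary of a neighboring gene or `max_len`,
#' whichever is shorter, clipped at the sequence boundary. In `"truncated"`
#' mode the neighbor set is every other annotated gene (either strand); in
#' `"full"` mode only other family members bound the region. Promoters are
#' stored 5'-to-3' in gene orientation (minus-strand genes are
#' reverse-complemented) and regions of 50 bp or less are excluded and logged.
#'
#' @param genes Tibble of family gene records (as from [read_genome()]).
#' @param genome Named character vector of chromosome sequences.
#' @param mode `"truncated"` or `"full"`.
#' @param max_len Maximum promoter length in bp (default 20000).
#' @param annotation Tibble of all annotated genes used for boundary search in
#'   truncated mode; defaults to `genes`.
#' @return Tibble with one row per retained promoter: gene metadata, `mode`,
#'   genomic interval `prom_start`/`prom_end` (0-based half-open), `length`,
#'   and `seq`. Excluded genes are reported in the `"excluded"` attribute.
#'   Promoter index `i` (0-based) corresponds to CDS-relative coordinate
#'   `i - length`, so position -1 abuts the start codon.
#' @export
extract_promoters <- function(genes, genome, mode = c("truncated", "full"),
                              max_len = 20000, annotation = genes) {
  mode <- match.arg(mode)
  neighbors <- if (mode == "truncated") annotation else genes
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    extract_upstream_impl(genes[i, ], genome, mode = mode, max_len = max_len,
                          neighbors = neighbors)
  })
  excluded <- dplyr::bind_rows(purrr::map(rows, "excluded"))
  out <- dplyr::bind_rows(purrr::map(rows, "row"))
  if (nrow(excluded) > 0) {
    message("extract_promoters: excluded ", nrow(excluded), " region(s): ",
            paste(utils::head(paste0(excluded$gene_id, " (", excluded$reason, ")"), 5),
                  collapse = ", "))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Extract the upstream region of a single gene
#'
#' @param gene One-row tibble with `gene_id`, `chrom`, `cds_start`, `cds_end`,
#'   `strand` and optional metadata columns.
#' @param genome Named character vector of chromosome sequences.
#' @inheritParams extract_promoters
#' @param neighbors Tibble of genes whose CDS boundaries bound the region.
#' @return One-row promoter tibble, or `NULL` (with an `"excluded"` attribute)
#'   when the region is 50 bp or shorter.
#' @export
extract_upstream <- function(gene, genome, mode = c("truncated", "full"),
                             max_len = 20000, neighbors = gene) {
  res <- extract_upstream_impl(gene, genome, mode = match.arg(mode),
                               max_len = max_len, neighbors = neighbors)
  if (is.null(res$row)) {
    message("extract_upstream: ", gene$gene_id, " excluded (",
            res$excluded$reason, ")")
  }
  res$row
}

extract_upstream_impl <- function(gene, genome, mode, max_len, neighbors) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", gene$chrom)
  chrlen <- nchar(chrom_seq)
  others <- neighbors[neighbors$gene_id != gene$gene_id &
                        neighbors$chrom == gene$chrom, , drop = FALSE]
  bounds <- c(others$cds_start, others$cds_end)

  if (gene$strand == "+") {
    lim <- max(0, gene$cds_start - max_len, bounds[bounds <= gene$cds_start])
    prom_start <- lim
    prom_end <- gene$cds_start
  } else {
    lim <- min(chrlen, gene$cds_end + max_len, bounds[bounds >= gene$cds_end])
    prom_start <- gene$cds_end
    prom_end <- lim
  }
  len <- prom_end - prom_start
  if (len <= 50) {
    reason <- if (len <= 0) "empty promoter" else "length <= 50 bp"
    return(list(row = NULL,
                excluded = tibble::tibble(gene_id = gene$gene_id,
                                          reason = reason, length = len)))
  }
  seq <- substr(chrom_seq, prom_start + 1, prom_end)
  if (gene$strand == "-") seq <- revcomp(seq)

  keep <- intersect(c("gene_id", "species", "chrom", "clade", "lineage",
                      "strand", "cds_start", "cds_end"), names(gene))
  row <- dplyr::bind_cols(
    gene[, keep],
    tibble::tibble(mode = mode, prom_start = prom_start, prom_end = prom_end,
                   length = len, seq = seq)
  )
  list(row = row, excluded = NULL)
}

#' Map CDS-relative promoter intervals to genomic coordinates
#'
#' CDS-relative coordinates are negative half-open intervals with 0 at the
#' first base of the start codon.
#'
#' @param promoters Promoter tibble (one row per interval, recycled by
#'   `gene_id` join if needed).
#' @param rel_start,rel_end CDS-relative half-open interval bounds
#'   (`rel_start < rel_end <= 0`).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open genomic) and
#'   `strand`.
#' @export
promoter_rel_to_genomic <- function(promoters, rel_start, rel_end) {
  plus <- promoters$strand == "+"
  start <- ifelse(plus, promoters$cds_start + rel_start,
                  promoters$cds_end - rel_end)
  end <- ifelse(plus, promoters$cds_start + rel_end,
                promoters$cds_end - rel_start)
  tibble::tibble(chrom = promoters$chrom, start = start, end = end,
                 strand = promoters$strand)
}

#' Write promoters as FASTA
#'
#' Headers follow `gene_id|species|clade|mode|length`.
#'
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param path Output file path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  headers <- paste(promoters$gene_id, promoters$species, promoters$clade,
                   promoters$mode, promoters$length, sep = "|")
  writeLines(paste0(">", headers, "\n", promoters$seq), path)
  invisible(path)
}

#' Export promoters as BED6 in genomic coordinates
#'
#' @inheritParams write_promoters_fasta
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- tibble::tibble(
    chrom = promoters$chrom,
    start = promoters$prom_start,
    end = promoters$prom_end,
    name = promoters$gene_id,
    score = 0L,
    strand = promoters$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
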