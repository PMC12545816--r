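# Synthetic gene-family generator: genomes, annotations, homolog tables and
# coverage tracks with planted CNS structure, so every downstream stage can be
# tested against a known truth manifest.

#' Describe a planted promoter element
#'
#' An element is a motif core drawn per species from a probability matrix of
#' configurable per-column information content, flanked on both sides by
#' conserved sequence that evolves along the species tree at the CNS
#' substitution rate. Elements are planted in list order, 5' to 3'.
#'
#' @param id Element identifier (e.g. `"BOX1"`).
#' @param consensus Core consensus string over `{A,C,G,T}`, 15-100 bp.
#' @param ic Target per-column information content of the core, in bits
#'   (0 to 2).
#' @param cns_flank Length of the conserved flank on each side, in bp.
#' @return A `planted_element` list.
#' @export
planted_element <- function(id, consensus, ic = 1.8, cns_flank = 15) {
  w <- nchar(consensus)
  if (w < 15 || w > 100) stop("element core width must be in [15, 100], got ", w)
  if (ic < 0 || ic > 2) stop("per-column information content must be in [0, 2]")
  structure(list(id = id, consensus = toupper(consensus), ic = ic,
                 cns_flank = cns_flank),
            class = "planted_element")
}

#' Build a synthetic family configuration
#'
#' Defaults emulate the structure of a deeply conserved two-element promoter
#' architecture in an angiosperm-like panel: four lineages, a ~60 bp and a
#' ~90 bp planted element (core + conserved flanks) in fixed order with
#' lineage-specific geometric spacers, neutral background divergence along the
#' species tree, and 13-cell-type coverage tracks with enrichment over planted
#' elements in meristematic cell types.
#'
#' @param seed Master RNG seed; every stream is derived from it by stable
#'   hashing, so outputs are byte-identical for identical configurations.
#' @param lineages Tibble with columns `lineage`, `n_species`, `spacer_mean`
#'   (bp), `stem_length`, `tip_length` (branch lengths, relative time units).
#' @param elements List of [planted_element()] objects, 5' to 3'.
#' @param tree Optional newick string; when `NULL` a lineage-star tree is built
#'   from `lineages`.
#' @param background_rate,cns_rate,cds_rate Substitutions per site per unit
#'   branch length for background, planted-element flanks, and CDS.
#' @param promoter_len,tail_len,cds_len Promoter length, distance from the
#'   last element to the CDS start, and CDS length (bp).
#' @param min_lead Minimum background upstream of the first element (bp).
#' @param clades Family clade labels; one gene per species per clade.
#' @param loss Tibble (`lineage`, `element_id`, `loss_prob`, `dup_prob`) of
#'   per-lineage loss/duplication probabilities; unlisted pairs default to 0.
#' @param swap_prob Per-gene probability of planting the elements in reversed
#'   order.
#' @param swap_fraction When non-`NULL`, overrides `swap_prob` with a
#'   deterministic rearrangement: elements are planted in reversed order in
#'   exactly this fraction of genes (every other gene first, so lineages stay
#'   balanced).
#' @param bg_freqs Background nucleotide frequencies (A, C, G, T).
#' @param coverage List: `cell_types` tibble (`cell_type`, `stage`), `depth`
#'   (mean per-base counts), `cns_enrichment` (multiplier over planted
#'   elements in meristematic cell types), `window` (CDS-relative, default
#'   `c(-2000, 500)`), `reference_species` (default: first species).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         lineages = default_lineages(),
                         elements = default_elements(),
                         tree = NULL,
                         background_rate = 1.0,
                         cns_rate = 0.25,
                         cds_rate = 0.5,
                         promoter_len = 3000,
                         tail_len = 400,
                         cds_len = 900,
                         min_lead = 60,
                         clades = "PLT1_2",
                         loss = NULL,
                         swap_prob = 0,
                         swap_fraction = NULL,
                         bg_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         coverage = default_coverage()) {
  if (cns_rate > background_rate) {
    stop("cns_rate must not exceed background_rate")
  }
  if (is.null(loss)) {
    loss <- tibble::tibble(lineage = character(), element_id = character(),
                           loss_prob = numeric(), dup_prob = numeric())
  }
  if (!all(loss$loss_prob >= 0 & loss$loss_prob <= 1) ||
      !all(loss$dup_prob >= 0 & loss$dup_prob <= 1)) {
    stop("loss_prob and dup_prob must lie in [0, 1]")
  }
  stages <- unique(coverage$cell_types$stage)
  bad <- setdiff(stages, c("meristematic", "elongating", "mature"))
  if (length(bad) > 0) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  cfg <- list(seed = seed, lineages = lineages, elements = elements,
              tree = tree, background_rate = background_rate,
              cns_rate = cns_rate, cds_rate = cds_rate,
              promoter_len = promoter_len, tail_len = tail_len,
              cds_len = cds_len, min_lead = min_lead, clades = clades,
              loss = loss, swap_prob = swap_prob,
              swap_fraction = swap_fraction,
              bg_freqs = bg_freqs / sum(bg_freqs), coverage = coverage)
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @export
default_lineages <- function() {
  tibble::tibble(
    lineage = c("monocots", "rosids", "asterids", "early_diverged"),
    n_species = c(10L, 14L, 10L, 3L),
    spacer_mean = c(700, 500, 1000, 700),
    stem_length = 0.5,
    tip_length = 0.75
  )
}

#' @rdname synth_config
#' @export
default_elements <- function() {
  list(
    planted_element("BOX2", "AGTCCCCAGGCTAAACCGTCTGAATACCGT", ic = 1.8,
                    cns_flank = 15),
    planted_element("BOX1",
                    "ATGTAACCAGTATCACCGAGACTTATGCGCAGCAATCTTGCATCATTGTT",
                    ic = 1.8, cns_flank = 20)
  )
}

#' @rdname synth_config
#' @export
default_coverage <- function() {
  list(
    cell_types = tibble::tibble(
      cell_type = c(paste0("meristem_", 1:4), paste0("elongation_", 1:4),
                    paste0("mature_", 1:5)),
      stage = rep(c("meristematic", "elongating", "mature"), c(4L, 4L, 5L))
    ),
    depth = 50,
    cns_enrichment = 3,
    window = c(-2000L, 500L),
    reference_species = NULL
  )
}

# Per-column core probability matrix for a target information content.
element_ppm <- function(element) {
  target <- element$ic
  p <- if (target >= 2 - 1e-9) {
    1
  } else if (target <= 0) {
    0.25
  } else {
    stats::uniroot(function(p) {
      2 + p * log2(p) + (1 - p) * log2((1 - p) / 3) - target
    }, c(0.2500001, 1 - 1e-9))$root
  }
  cons <- encode_seq(element$consensus)
  ppm <- matrix((1 - p) / 3, nrow = 4, ncol = length(cons),
                dimnames = list(DNA_BASES, NULL))
  ppm[cbind(cons, seq_along(cons))] <- p
  ppm
}

# Jukes-Cantor per-site substitution of integer-coded sequence over distance d
# (expected substitutions/site). N sites (code 5) are left untouched.
mutate_jc <- function(codes, d) {
  if (d <= 0) return(codes)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(stats::runif(length(codes)) < p & codes <= 4L)
  if (length(hit) > 0) {
    codes[hit] <- ((codes[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  codes
}

# Evolve a root sequence along every edge of the tree; returns a list of
# integer-coded tip sequences named by tip label. RNG streams are derived per
# edge from (seed, label, child node), so results do not depend on iteration
# order.
evolve_along_tree <- function(root_codes, tree, rate, seed, label) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- root_codes
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # parent-before-child traversal
  todo <- which(tree$edge[, 1] == root)
  while (length(todo) > 0) {
    e <- todo[1]
    todo <- todo[-1]
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    child_name <- if (child <= ntip) tree$tip.label[child] else paste0("node", child)
    node_seq[[child]] <- with_derived_seed(seed, label, child_name, expr = {
      mutate_jc(node_seq[[parent]], rate * tree$edge.length[e])
    })
    todo <- c(todo, which(tree$edge[, 1] == child))
  }
  stats::setNames(node_seq[seq_len(ntip)], tree$tip.label)
}

random_codes <- function(n, bg_freqs) {
  sample.int(4L, n, replace = TRUE, prob = bg_freqs)
}

build_lineage_tree <- function(lineages, species_table) {
  clades <- purrr::map_chr(seq_len(nrow(lineages)), function(i) {
    sp <- species_table$species[species_table$lineage == lineages$lineage[i]]
    tips <- paste0(sp, ":", format(lineages$tip_length[i], scientific = FALSE))
    paste0("(", paste(tips, collapse = ","), "):",
           format(lineages$stem_length[i], scientific = FALSE))
  })
  ape::read.tree(text = paste0("(", paste(clades, collapse = ","), ");"))
}

#' Simulate a gene family with planted conserved elements
#'
#' Generates one genome sequence per species, each carrying one gene per clade
#' whose upstream region hosts the configured planted elements. Element cores
#' are drawn per species from the element's probability matrix; conserved
#' flanks, tail background, lead background and CDS evolve along the species
#' tree under Jukes-Cantor substitution at their respective rates; spacer and
#' lost-element filler sequence is drawn independently per species, with the
#' spacer length resampled per gene from a geometric distribution around the
#' lineage's `spacer_mean`. Per-lineage losses, duplications and order swaps
#' are applied gene-wise and recorded in the truth manifest. Deterministic
#' given the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, FASTA/GFF3/homolog-table/manifest
#'   files are written there.
#' @return A list: `genome` (named character vector), `genes` (homolog table
#'   with coordinates, as from [read_genome()]), `annotation`, `manifest`
#'   (per planted element copy: CDS-relative interval, core interval, order
#'   rank), `gene_manifest` (per gene: spacer lengths, swap flag, strand),
#'   `cds` (per gene CDS sequence, gene orientation), `tree` (ape `phylo`),
#'   and `paths` when `dir` was given.
#' @export
simulate_family <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- config$seed
  lineages <- config$lineages
  elements <- config$elements
  el_ids <- vapply(elements, `[[`, character(1), "id")
  el_core_w <- vapply(elements, function(e) nchar(e$consensus), integer(1))
  el_flank <- vapply(elements, `[[`, numeric(1), "cns_flank")
  el_total <- el_core_w + 2 * el_flank
  n_el <- length(elements)

  fixed_len <- config$tail_len + sum(el_total) +
    (n_el - 1) * 0 + config$min_lead
  if (config$promoter_len < fixed_len) {
    stop("promoter_len (", config$promoter_len,
         ") too small to host planted elements + tail + min_lead (needs >= ",
         fixed_len, ")")
  }

  species_table <- purrr::map_dfr(seq_len(nrow(lineages)), function(i) {
    tibble::tibble(
      species = sprintf("%s_sp%02d", lineages$lineage[i],
                        seq_len(lineages$n_species[i])),
      lineage = lineages$lineage[i],
      spacer_mean = lineages$spacer_mean[i]
    )
  })

  tree <- if (is.null(config$tree)) {
    build_lineage_tree(lineages, species_table)
  } else {
    ape::read.tree(text = config$tree)
  }
  if (!setequal(tree$tip.label, species_table$species)) {
    stop("tree tips must match the configured species set")
  }

  # Root segments (shared ancestral sequence), evolved along the tree.
  roots <- with_derived_seed(seed, "roots", expr = {
    list(
      lead = random_codes(config$promoter_len, config$bg_freqs),
      tail = random_codes(config$tail_len, config$bg_freqs),
      cds = c(encode_seq("ATG"),
              random_codes(config$cds_len - 3L, config$bg_freqs)),
      flanks = purrr::map(seq_len(n_el), function(i) {
        list(left = random_codes(el_flank[i], config$bg_freqs),
             right = random_codes(el_flank[i], config$bg_freqs))
      })
    )
  })
  tip_lead <- evolve_along_tree(roots$lead, tree, config$background_rate, seed, "lead")
  tip_tail <- evolve_along_tree(roots$tail, tree, config$background_rate, seed, "tail")
  tip_cds <- evolve_along_tree(roots$cds, tree, config$cds_rate, seed, "cds")
  tip_flanks <- purrr::map(seq_len(n_el), function(i) {
    list(left = evolve_along_tree(roots$flanks[[i]]$left, tree, config$cns_rate,
                                  seed, paste0("flankL", i)),
         right = evolve_along_tree(roots$flanks[[i]]$right, tree, config$cns_rate,
                                   seed, paste0("flankR", i)))
  })
  ppms <- purrr::map(elements, element_ppm)

  loss_of <- function(lineage, element_id, what) {
    row <- config$loss[config$loss$lineage == lineage &
                         config$loss$element_id == element_id, ]
    if (nrow(row) == 0) 0 else row[[what]][1]
  }

  manifest <- list()
  gene_manifest <- list()
  genomes <- character(0)
  genes <- list()
  cds_seqs <- list()

  for (si in seq_len(nrow(species_table))) {
    sp <- species_table$species[si]
    lin <- species_table$lineage[si]
    sp_mean <- species_table$spacer_mean[si]
    cassettes <- character(0)
    gene_rows <- list()

    for (ci in seq_along(config$clades)) {
      clade <- config$clades[ci]
      gene_id <- paste0(sp, "_", clade)

      present <- with_derived_seed(seed, "loss", gene_id, expr = {
        stats::runif(n_el) >= vapply(el_ids, function(e) loss_of(lin, e, "loss_prob"), numeric(1))
      })
      dup <- with_derived_seed(seed, "dup", gene_id, expr = {
        stats::runif(n_el) < vapply(el_ids, function(e) loss_of(lin, e, "dup_prob"), numeric(1))
      })
      swapped <- if (!is.null(config$swap_fraction)) {
        gene_counter <- (si - 1L) * length(config$clades) + ci
        (gene_counter %% round(1 / max(config$swap_fraction, 1e-9))) == 0
      } else {
        with_derived_seed(seed, "swap", gene_id, expr = {
          stats::runif(1) < config$swap_prob
        })
      }

      max_spacer_total <- config$promoter_len - config$tail_len -
        sum(el_total) - config$min_lead
      spacers <- if (n_el > 1) {
        with_derived_seed(seed, "spacer", gene_id, expr = {
          stats::rgeom(n_el - 1, prob = 1 / (sp_mean + 1))
        })
      } else {
        integer(0)
      }
      if (length(spacers) > 0 && sum(spacers) > max_spacer_total) {
        spacers <- floor(spacers * max_spacer_total / sum(spacers))
      }

      # Element sequences (gene orientation), full = left flank + core + right.
      el_seq <- purrr::map(seq_len(n_el), function(i) {
        core <- with_derived_seed(seed, "core", gene_id, el_ids[i], expr = {
          draw_from_ppm(ppms[[i]])
        })
        c(tip_flanks[[i]]$left[[sp]], core, tip_flanks[[i]]$right[[sp]])
      })

      order_idx <- if (swapped) rev(seq_len(n_el)) else seq_len(n_el)
      slot_len <- el_total[order_idx]
      lead_len <- config$promoter_len - config$tail_len - sum(el_total) -
        sum(spacers)
      lead <- utils::tail(tip_lead[[sp]], lead_len)
      spacer_seq <- with_derived_seed(seed, "spacerseq", gene_id, expr = {
        purrr::map(spacers, ~ random_codes(.x, config$bg_freqs))
      })

      # Assemble promoter; record planted intervals (CDS-relative).
      parts <- list(lead)
      pos <- lead_len # 0-based offset within promoter
      for (k in seq_len(n_el)) {
        i <- order_idx[k]
        if (present[i]) {
          seq_i <- el_seq[[i]]
        } else {
          seq_i <- with_derived_seed(seed, "lostfill", gene_id, el_ids[i], expr = {
            random_codes(el_total[i], config$bg_freqs)
          })
        }
        if (present[i]) {
          rel_start <- pos - config$promoter_len
          manifest[[length(manifest) + 1]] <- tibble::tibble(
            gene_id = gene_id, species = sp, clade = clade, lineage = lin,
            element_id = el_ids[i], copy = 1L,
            rel_start = rel_start, rel_end = rel_start + el_total[i],
            core_rel_start = rel_start + el_flank[i],
            core_rel_end = rel_start + el_flank[i] + el_core_w[i],
            order_rank = i
          )
        }
        parts[[length(parts) + 1]] <- seq_i
        pos <- pos + el_total[i]
        if (k < n_el) {
          parts[[length(parts) + 1]] <- spacer_seq[[k]]
          pos <- pos + spacers[k]
        }
      }
      parts[[length(parts) + 1]] <- tip_tail[[sp]]

      # Duplicated copies overwrite the 5' end of the lead background.
      prom <- unlist(parts)
      dup_at <- 0L
      for (i in which(dup & present)) {
        if (dup_at + el_total[i] + 10L < lead_len) {
          core2 <- with_derived_seed(seed, "dupcore", gene_id, el_ids[i], expr = {
            draw_from_ppm(ppms[[i]])
          })
          seq2 <- c(tip_flanks[[i]]$left[[sp]], core2, tip_flanks[[i]]$right[[sp]])
          prom[(dup_at + 1):(dup_at + el_total[i])] <- seq2
          manifest[[length(manifest) + 1]] <- tibble::tibble(
            gene_id = gene_id, species = sp, clade = clade, lineage = lin,
            element_id = el_ids[i], copy = 2L,
            rel_start = dup_at - config$promoter_len,
            rel_end = dup_at + el_total[i] - config$promoter_len,
            core_rel_start = dup_at + el_flank[i] - config$promoter_len,
            core_rel_end = dup_at + el_flank[i] + el_core_w[i] - config$promoter_len,
            order_rank = i
          )
          dup_at <- dup_at + el_total[i] + 10L
        }
      }

      gene_manifest[[length(gene_manifest) + 1]] <- tibble::tibble(
        gene_id = gene_id, species = sp, clade = clade, lineage = lin,
        spacer = if (n_el > 1) sum(spacers) else NA_integer_,
        swapped = swapped,
        n_elements = sum(present)
      )
      cds_seqs[[gene_id]] <- decode_seq(tip_cds[[sp]])
      cassettes[[length(cassettes) + 1]] <- decode_seq(c(prom, tip_cds[[sp]]))
      gene_rows[[length(gene_rows) + 1]] <- tibble::tibble(
        gene_id = gene_id, species = sp, clade = clade, lineage = lin,
        cassette = length(cassettes)
      )
    }

    # Chromosome: cassettes head-to-tail; in even-indexed species the last
    # gene is placed on the minus strand (cassette reverse-complemented), so
    # both orientations are exercised.
    minus_last <- (si %% 2L) == 0L
    chrom <- paste0(sp, "_chr1")
    offset <- 0L
    chrom_seq <- character(0)
    for (gi in seq_along(cassettes)) {
      cass <- cassettes[[gi]]
      is_minus <- minus_last && gi == length(cassettes)
      cass_len <- nchar(cass)
      if (is_minus) {
        chrom_seq <- c(chrom_seq, revcomp(cass))
        cds_start <- offset
        cds_end <- offset + config$cds_len
        strand <- "-"
      } else {
        chrom_seq <- c(chrom_seq, cass)
        cds_start <- offset + config$promoter_len
        cds_end <- offset + cass_len
        strand <- "+"
      }
      genes[[length(genes) + 1]] <- dplyr::bind_cols(
        gene_rows[[gi]][, c("gene_id", "species", "clade", "lineage")],
        tibble::tibble(chrom = chrom, cds_start = cds_start,
                       cds_end = cds_end, strand = strand)
      )
      offset <- offset + cass_len
    }
    genomes[[chrom]] <- paste(chrom_seq, collapse = "")
  }

  genes <- dplyr::bind_rows(genes)
  out <- list(
    genome = genomes,
    genes = genes,
    annotation = genes[, c("gene_id", "chrom", "cds_start", "cds_end", "strand")],
    manifest = dplyr::bind_rows(manifest),
    gene_manifest = dplyr::bind_rows(gene_manifest),
    cds = tibble::tibble(gene_id = names(cds_seqs),
                         cds_seq = unlist(cds_seqs, use.names = FALSE)),
    tree = tree,
    config = config
  )
  if (!is.null(dir)) {
    out$paths <- write_family(out, dir)
  }
  out
}

#' Scanning motif for a planted element
#'
#' Builds the `zoops_motif` corresponding to a planted element's core
#' probability matrix, so promoters can be rescanned for the ground-truth
#' elements without running discovery.
#'
#' @param element A [planted_element()].
#' @param background Background frequencies (default uniform).
#' @param n_sites Nominal site count recorded on the motif.
#' @return A `zoops_motif`.
#' @export
element_motif <- function(element, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                          n_sites = 20) {
  ppm <- element_ppm(element)
  counts <- ppm * n_sites
  probs <- sweep(counts + 0.1 * background, 2, colSums(counts) + 0.1, `/`)
  rownames(probs) <- DNA_BASES
  new_zoops_motif(id = element$id, counts = counts, probs = probs,
                  background = background, n_sites = n_sites, llr = NA_real_)
}

draw_from_ppm <- function(ppm) {
  apply(ppm, 2, function(p) sample.int(4L, 1, prob = p))
}

# Write FASTA, GFF3, homolog TSV and JSON manifest for a simulated family.
write_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), fasta)
  gff <- file.path(dir, "annotation.gff3")
  write_gff3(sim$genes, gff)
  hom <- file.path(dir, "homologs.tsv")
  readr::write_tsv(sim$genes[, c("gene_id", "species", "clade", "lineage")],
                   hom, progress = FALSE)
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(elements = sim$manifest,
                            genes = sim$gene_manifest),
                       man, dataframe = "rows", digits = NA)
  list(fasta = fasta, gff = gff, homologs = hom, manifest = man)
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- g$cds_start + 1L # GFF3 is 1-based inclusive
    e <- g$cds_end
    lines <- c(
      lines,
      paste(g$chrom, "plantcns", "gene", s, e, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "plantcns", "mRNA", s, e, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".1;Parent=", g$gene_id), sep = "\t"),
      paste(g$chrom, "plantcns", "CDS", s, e, ".", g$strand, "0",
            paste0("ID=", g$gene_id, ".1.cds;Parent=", g$gene_id, ".1"),
            sep = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-cell-type chromatin accessibility tracks
#'
#' For each gene of the reference species, per-base integer counts are drawn
#' independently as Poisson with mean `depth` over the promoter window; over
#' manifest element intervals the mean is multiplied by `cns_enrichment`, but
#' only in cell types whose stage is `"meristematic"`. Deterministic given the
#' configuration seed.
#'
#' @param config A [synth_config()].
#' @param sim Output of [simulate_family()] run with the same config.
#' @param dir Optional directory to write one bedGraph per cell type.
#' @return Tibble with columns `gene_id`, `cell_type`, `stage`, `rel_pos`
#'   (CDS-relative base), `value`; the enriched truth intervals are attached
#'   as attribute `"enriched"`.
#' @export
simulate_coverage <- function(config, sim, dir = NULL) {
  cov <- config$coverage
  stages <- unique(cov$cell_types$stage)
  bad <- setdiff(stages, c("meristematic", "elongating", "mature"))
  if (length(bad) > 0) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  ref <- cov$reference_species %||% sim$genes$species[1]
  win <- cov$window
  genes <- sim$genes[sim$genes$species == ref, ]
  if (nrow(genes) == 0) stop("reference species has no genes: ", ref)

  rel_pos <- seq(win[1], win[2] - 1L)
  out <- list()
  enriched <- sim$manifest |>
    dplyr::filter(.data$species == ref,
                  .data$rel_end > win[1], .data$rel_start < win[2])
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    em <- enriched[enriched$gene_id == g$gene_id, ]
    in_elem <- rep(FALSE, length(rel_pos))
    for (k in seq_len(nrow(em))) {
      in_elem <- in_elem | (rel_pos >= em$rel_start[k] & rel_pos < em$rel_end[k])
    }
    for (ci in seq_len(nrow(cov$cell_types))) {
      ct <- cov$cell_types$cell_type[ci]
      st <- cov$cell_types$stage[ci]
      mu <- rep(cov$depth, length(rel_pos))
      if (st == "meristematic") mu[in_elem] <- mu[in_elem] * cov$cns_enrichment
      vals <- with_derived_seed(config$seed, "coverage", g$gene_id, ct, expr = {
        stats::rpois(length(mu), mu)
      })
      out[[length(out) + 1]] <- tibble::tibble(
        gene_id = g$gene_id, cell_type = ct, stage = st,
        rel_pos = rel_pos, value = vals)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "enriched") <- enriched
  if (!is.null(dir)) {
    attr(res, "paths") <- write_coverage_bedgraph(res, sim, dir)
  }
  res
}

#' Write simulated coverage as bedGraph, one file per cell type
#'
#' CDS-relative positions are mapped to genomic coordinates through each
#' gene's strand; equal-valued runs are merged into intervals.
#'
#' @param coverage Tibble from [simulate_coverage()].
#' @param sim Output of [simulate_family()].
#' @param dir Output directory.
#' @return Named character vector of file paths.
#' @export
write_coverage_bedgraph <- function(coverage, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim$genes
  paths <- character(0)
  for (ct in unique(coverage$cell_type)) {
    sub <- coverage[coverage$cell_type == ct, ]
    rows <- list()
    for (gid in unique(sub$gene_id)) {
      g <- genes[genes$gene_id == gid, ]
      gs <- sub[sub$gene_id == gid, ]
      gs <- gs[order(gs$rel_pos), ]
      if (g$strand == "+") {
        gpos <- g$cds_start + gs$rel_pos
        vals <- gs$value
      } else {
        gpos <- g$cds_end - gs$rel_pos - 1L
        o <- order(gpos)
        gpos <- gpos[o]
        vals <- gs$value[o]
      }
      r <- rle(vals)
      ends <- cumsum(r$lengths)
      starts <- c(0L, utils::head(ends, -1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = g$chrom, start = gpos[1] + starts, end = gpos[1] + ends,
        value = r$values)
    }
    bed <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$chrom, .data$start)
    path <- file.path(dir, paste0(ct, ".bedGraph"))
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
    paths[ct] <- path
  }
  paths
}
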