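# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the helpers themselves write to tempdirs.

random_dna <- function(n, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# A small two-lineage family with the default two planted elements.
small_family_config <- function(seed = 1, n_rosids = 6L, n_asterids = 5L,
                                promoter_len = 2000, ...) {
  synth_config(
    seed = seed,
    lineages = tibble::tibble(
      lineage = c("rosids", "asterids"),
      n_species = c(n_rosids, n_asterids),
      spacer_mean = c(300, 500),
      stem_length = 0.5, tip_length = 0.75),
    promoter_len = promoter_len, tail_len = 300,
    ...
  )
}

# Single-lineage, single short element: cheap discovery fixture. The neutral
# rate is saturating so the background is effectively independent across
# species and promoters share only the planted signal; with ic = 0 the
# "planted" core is itself an iid draw, i.e. a pure-background control.
discovery_config <- function(seed = 1, n_species = 30L, ic = 1.8,
                             promoter_len = 500, background_rate = 30) {
  synth_config(
    seed = seed,
    lineages = tibble::tibble(lineage = "rosids", n_species = n_species,
                              spacer_mean = 100, stem_length = 0.2,
                              tip_length = 0.3),
    elements = list(planted_element("M1", "ATCGAACGGAGCCGG", ic = ic,
                                    cns_flank = 0)),
    background_rate = background_rate,
    promoter_len = promoter_len, tail_len = 100, min_lead = 20
  )
}

pipeline_fixture <- function(seed = 21) {
  cfg <- synth_config(
    seed = seed,
    lineages = tibble::tibble(
      lineage = c("rosids", "asterids"), n_species = c(10L, 8L),
      spacer_mean = c(300, 500), stem_length = 0.5, tip_length = 0.75),
    elements = list(
      planted_element("BOX2", "AGTCCCCAGGCTAAACCGTCTGAATACCGT",
                      ic = 1.9, cns_flank = 10),
      planted_element("BOX1", "ATGTAACCAGTATCACCGAGACTTATGCGC",
                      ic = 1.9, cns_flank = 10)),
    promoter_len = 2200, tail_len = 300)
  dir <- tempfile("pipefix")
  dir.create(dir)
  sim <- simulate_family(cfg, dir = dir)
  cov <- simulate_coverage(cfg, sim, dir = file.path(dir, "tracks"))
  paths <- attr(cov, "paths")
  tracks <- data.frame(
    cell_type = names(paths),
    stage = cfg$coverage$cell_types$stage[
      match(names(paths), cfg$coverage$cell_types$cell_type)],
    path = unname(paths), stringsAsFactors = FALSE)
  list(cfg = cfg, sim = sim, dir = dir,
       pcfg = list(fasta = sim$paths$fasta, gff = sim$paths$gff,
                   homologs = sim$paths$homologs, tracks = tracks,
                   widths = 30, n_shuffles = 20, n_motifs = 2, seed = 4))
}

# A zoops_motif from an explicit count matrix (uniform background).
motif_from_counts <- function(counts, id = "fix",
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  probs <- sweep(counts + 0.1 * background, 2, colSums(counts) + 0.1, `/`)
  rownames(probs) <- rownames(counts) <- c("A", "C", "G", "T")
  plantcns:::new_zoops_motif(id = id, counts = counts, probs = probs,
                             background = background,
                             n_sites = max(colSums(counts)), llr = 0)
}

# Deterministic set of width <= 5 fixture motifs.
fixture_motifs_small <- function() {
  set.seed(420)
  lapply(1:5, function(w) {
    counts <- matrix(sample(1:9, 4 * w, replace = TRUE), nrow = 4)
    motif_from_counts(counts, id = paste0("fix_w", w))
  })
}

# Write a tiny genome/annotation/homolog fixture to dir; two genes on one
# chromosome (one per strand) plus one chromosome with a gene at position 0.
write_tiny_genome <- function(dir) {
  set.seed(77)
  chr1 <- paste0(random_dna(3000))
  chr2 <- random_dna(400)
  writeLines(c(">chr1", chr1, ">chr2", chr2), file.path(dir, "g.fa"))
  gff <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t1600\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1001\t1600\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tCDS\t1001\t1600\t.\t+\t0\tID=gA.1.c;Parent=gA.1",
    "chr1\ttest\tgene\t2001\t2400\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t2001\t2400\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\tCDS\t2001\t2400\t.\t-\t0\tID=gB.1.c;Parent=gB.1",
    "chr2\ttest\tgene\t1\t100\t.\t+\t.\tID=gC",
    "chr2\ttest\tmRNA\t1\t100\t.\t+\t.\tID=gC.1;Parent=gC",
    "chr2\ttest\tCDS\t1\t100\t.\t+\t0\tID=gC.1.c;Parent=gC.1"
  )
  writeLines(gff, file.path(dir, "g.gff3"))
  hom <- c("gene_id\tspecies\tclade\tlineage",
           "gA\tsp1\tcladeX\trosids",
           "gB\tsp1\tcladeX\trosids",
           "gC\tsp2\tcladeX\tasterids",
           "gMissing\tsp3\tcladeX\trosids")
  writeLines(hom, file.path(dir, "hom.tsv"))
  list(fasta = file.path(dir, "g.fa"), gff = file.path(dir, "g.gff3"),
       homologs = file.path(dir, "hom.tsv"), chr1 = chr1, chr2 = chr2)
}

# Independent brute-force G-quadruplex enumerator (naive run finding plus
# nested loops), used as the oracle for scan_gquad.
gquad_brute <- function(sequence, g_group, loop_range, max_span = 45L) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  one_strand <- function(s) {
    runs <- list()
    i <- 1
    n <- length(s)
    while (i <= n) {
      if (s[i] == "G") {
        j <- i
        while (j < n && s[j + 1] == "G") j <- j + 1
        if (j - i + 1 >= g_group) {
          runs[[length(runs) + 1]] <- c(i - 1, j) # 0-based start, exclusive end
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    out <- list()
    nr <- length(runs)
    if (nr >= 4) {
      for (a in 1:nr) for (b in 1:nr) for (cc in 1:nr) for (d in 1:nr) {
        if (!(a < b && b < cc && cc < d)) next
        l1 <- runs[[b]][1] - runs[[a]][2]
        l2 <- runs[[cc]][1] - runs[[b]][2]
        l3 <- runs[[d]][1] - runs[[cc]][2]
        if (l1 < loop_range[1] || l1 > loop_range[2]) next
        if (l2 < loop_range[1] || l2 > loop_range[2]) next
        if (l3 < loop_range[1] || l3 > loop_range[2]) next
        span <- runs[[d]][2] - runs[[a]][1]
        if (span > max_span) next
        out[[length(out) + 1]] <- c(runs[[a]][1], runs[[d]][2], l1, l2, l3)
      }
    }
    out
  }
  fwd <- one_strand(s)
  L <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rcs <- rev(unname(comp[s]))
  rev_hits <- one_strand(rcs)
  rows <- list()
  for (h in fwd) rows[[length(rows) + 1]] <-
    data.frame(start = h[1], end = h[2], strand = "+",
               loop1 = h[3], loop2 = h[4], loop3 = h[5])
  for (h in rev_hits) rows[[length(rows) + 1]] <-
    data.frame(start = L - h[2], end = L - h[1], strand = "-",
               loop1 = h[3], loop2 = h[4], loop3 = h[5])
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), loop1 = integer(),
                      loop2 = integer(), loop3 = integer()))
  }
  df <- do.call(rbind, rows)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}
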