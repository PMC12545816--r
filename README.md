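# plantcns

Discovery and characterization of deeply conserved non-coding sequences
(CNSs) in plant gene promoters.

Regulatory elements under purifying selection survive as short, strongly
conserved stretches of non-coding DNA upstream of developmental genes. Given
genomes (FASTA), annotations (GFF3) and a homolog table assigning each gene
of a family to a clade and a phylogenetic lineage, `plantcns` runs the full
analysis a comparative-promoter study needs:

1. **Promoter extraction** — upstream regions bounded by the nearest gene or
   20 kb (*truncated*) or by the nearest family member (*full*),
   strand-normalized, with a >50 bp filter.
2. **Motif discovery** — a ZOOPS (zero-or-one-occurrence-per-sequence)
   expectation–maximization model over 15–100 bp widths on both strands,
   with Monte-Carlo E-values from dinucleotide-shuffled nulls and
   programmatic curation (repetitive / low-conservation / non-specific
   rules). The per-promoter likelihood ratio is
   `(1 − λ) + (λ/W_i) Σ_j Π_c θ[x(j+c), c] / b[x(j+c)]`.
3. **Rescanning** — exact PSSM p-values by dynamic programming over the
   discretized log-odds score distribution, Benjamini–Hochberg q-values over
   the full scanned universe, then q < 0.01, same-orientation and
   10%-of-clade prevalence filters (with exemptions for sparsely sampled
   lineages), all with removal-count logging.
4. **Promoter architecture** — consensus element order, colinear/unordered
   classification, co-occurrence and spacer-distance statistics per lineage.
5. **CNS delineation** — motif ± 100 bp windows, progressive
   profile–profile alignment (match +1, mismatch −1, gap open −4, extend
   −1), sliding-window conservation boundaries, pairwise percent identity
   and `log2(PID_CNS / PID_CDS)` enrichment against a reference ortholog.
6. **Chromatin accessibility** — per-cell-type coverage over the −2000..+500
   promoter window, element fold change vs the promoter mean with one-tailed
   t-tests, per-promoter max normalization, Bonferroni-corrected stage
   comparisons, pseudo-bulk aggregation.
7. **G-quadruplex scan** — canonical G₃L₁₋₇ / G₂L₁₋₄ presence/absence.
8. **Synthetic data** — a generator that plants elements with configurable
   per-column information content along a species tree (Jukes–Cantor
   substitution, lineage-specific geometric spacers, loss/duplication/swap
   events, Poisson coverage with meristematic enrichment) plus a truth
   manifest, so every stage is testable without downloads.

Everything is tibble-in/tibble-out and pipe-friendly; fitted motifs have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(plantcns)
library(dplyr)

# Simulate a four-lineage family with the default two planted elements
cfg <- synth_config(seed = 1)
sim <- simulate_family(cfg)

prom <- extract_promoters(sim$genes, sim$genome, mode = "truncated",
                          annotation = sim$annotation)
motifs <- lapply(cfg$elements, element_motif)   # ground-truth matrices
hits <- scan_promoters(prom, motifs) |>
  filter_hits(prom, exempt_lineages = "early_diverged")

hits$removal_log
#> # A tibble: 3 × 2
#>   step               n_removed
#>   <chr>                  <int>
#> 1 q_filter                  24
#> 2 orientation_filter         1
#> 3 prevalence_filter          0

consensus_order(hits$hits)
#> <consensus_order> BOX2 -> BOX1
#>   support = 1

spacer_distances(hits$hits, c("BOX2", "BOX1")) |>
  left_join(prom[, c("gene_id", "lineage")], by = "gene_id") |>
  group_by(lineage) |>
  summarise(mean_spacer = mean(d_spacer))
#> # A tibble: 4 × 2
#>   lineage        mean_spacer
#>   <chr>                <dbl>
#> 1 asterids              811.
#> 2 early_diverged        383.
#> 3 monocots              859.
#> 4 rosids                780.
```

The q filter removed 24 marginal raw scan hits and one antisense match;
the planted order (BOX2 upstream of BOX1) is recovered in every
multi-element promoter (support = 1); and the measured spacers scatter
around the configured lineage means (500 bp rosids, 1000 bp asterids, plus
35 bp of conserved flank between the two motif cores) — spacer draws are
geometric, so per-lineage means at 3-14 genes are this noisy by design.

For a full run — discovery, curation, rescanning, architecture, CNS
delineation, accessibility, G4 — drive it from one config:

```r
res <- run_pipeline(list(fasta = "genome.fa", gff = "annotation.gff3",
                         homologs = "homologs.tsv", seed = 1),
                    out_dir = "results/")
```

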