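---
title: "Methods: discovering deeply conserved non-coding sequences in plant promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering deeply conserved non-coding sequences in plant promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantcns)
```

## The problem

Conserved non-coding sequences (CNSs) are stretches of promoter DNA held by
purifying selection across large phylogenetic distances; in angiosperms they
are short (tens of bp), moderately conserved, and usually within a few kb of
the start codon. `plantcns` implements a complete, testable pipeline for
finding such elements upstream of the members of a gene family across a
species panel and for characterizing them: their positions, their mutual
order and spacing, their boundaries and identity relative to coding
sequence, their chromatin accessibility across cell types, and their
potential to form G-quadruplexes.

Every stage is exercised end to end against a synthetic family generator
that plants CNS structure along a species tree, so each claim the pipeline
makes on real data has a corresponding recovery test on data with known
truth.

## Promoter extraction

For each family gene the upstream region runs from the first base of the
annotated CDS back toward 5' until the nearest CDS boundary of a neighboring
gene or 20 kb, whichever comes first, clipped at the sequence end. Two modes
exist: *truncated* promoters stop at any annotated gene (used for motif
discovery, where unrelated coding sequence would poison the motif model) and
*full* promoters stop only at another family member (used for rescanning, so
elements shared through tandem arrangements are not cut away). Regions of
50 bp or less are discarded and logged. Promoters are stored 5'→3' in gene
orientation; CDS-relative coordinates are negative and half-open with 0 at
the start codon, so position −1 always abuts the CDS. Neighboring-gene
boundaries are taken from either strand — the conservative reading that
avoids swallowing coding sequence. When a gene has several transcripts, the
CDS span over all of them is used, i.e. the most-upstream CDS start; this is
a documented convention of this package, not a claim about any upstream
pipeline. Ambiguity codes other than `N` are normalized to `N` because all
scoring models use a 5-letter alphabet.

## ZOOPS motif discovery

The discovery model is *zero-or-one-occurrence-per-sequence* (ZOOPS): each
promoter contributes at most one site of width $w$, on either strand. With
site probability $\lambda$ and motif columns $\theta$ over a 0-order
background $b$, the per-promoter likelihood ratio is

$$
\frac{P(X_i)}{P_0(X_i)} \;=\; (1-\lambda) \;+\;
\frac{\lambda}{W_i}\sum_{j\in\text{windows}} \prod_{c=1}^{w}
\frac{\theta_{x_{j+c},c}}{b_{x_{j+c}}},
$$

where $W_i$ counts candidate windows on both strands.
Expectation-maximization alternates posterior site responsibilities with
count updates; columns are smoothed with a pseudocount of $0.1\,b$ per cell,
which makes the procedure MAP-EM under a Dirichlet prior — the penalized
objective is non-decreasing every iteration, and `em_zoops(debug_monotone =
TRUE)` asserts exactly that at runtime. Starts are deterministic: the most
background-enriched 8-mers are lifted to width-$w$ promoter substrings and
converted to probability matrices at 0.7 consensus weight; the best
converged start wins, ties broken by lowest seed index. Since the model is
strand-symmetric, the fitted motif is re-oriented to the strand carrying the
majority of site responsibility, which is what makes the later
"same orientation as the gene" filter meaningful.

Significance is a Monte-Carlo E-value rather than an analytic approximation:
each of `n_shuffles` null promoter sets is produced by per-sequence
dinucleotide-preserving shuffling (an Eulerian-path shuffle; dinucleotide
counts are preserved exactly) and refit with single-start EM. The E-value is
the expected number of motifs in the search space at least as strong as the
observed one: the null tail probability (the larger of the empirical
exceedance fraction and a normal-tail fit to the null log-likelihood ratios)
times the search multiplicity (starts × widths). A motif refit on its own
shuffled null therefore lands near E ≈ multiplicity × U(0,1), while a
genuinely planted motif sits far in the fitted tail. A degenerate −∞
log-likelihood maps to the maximal E. Discovery iterates: accept the best-E
motif across the width grid, mask its sites with `N`, repeat; candidates
with E ≥ 0.05 or fewer than 15 expected contributing promoters are
discarded.

Manual motif curation is operationalized as three explicit rules with
configurable thresholds (these are this package's operationalization, not
anyone else's values): *repetitive* when ≥ 80% of consensus columns follow a
mono- or dinucleotide repeat; *low conservation* when the longest run of
columns above 1 bit is shorter than 8; *non-specific* when a rescan returns
more than 3× the fitted site count at q < 0.01.

## Rescanning, q-values and filters

Rescanning uses exact PSSM p-values: per-column log-odds are discretized on
a 1e-3 log2-unit grid and convolved column-wise, giving $P(\text{score} \ge
s)$ under the background exactly up to discretization. Scan scores use the
same discretized per-column table, so lookups are self-consistent; on iid
background the fraction of positions below any threshold matches the
binomial expectation. Raw hits are kept at p < 1e-4 (a conventional scan
threshold, exposed in the config); Benjamini–Hochberg q-values are computed
per motif over the *full* scanned universe — every candidate position on
both strands is a test, not just retained hits — which matches the
denominator a scan tool reports. Overlapping same-motif hits resolve to the
best p-value (ties: most-downstream start, then plus strand), so a
palindromic match counts once.

Three filters then apply in order, each logged with its removal count so the
bookkeeping is reproducible on any dataset: q < 0.01; orientation (hits
antisense to the gene are dropped); and prevalence — all hits of a motif in
a lineage × family-clade cell are dropped when fewer than 10% of that cell's
promoters carry the motif, except in exempt lineages where sampling depth is
too low for the fraction to be meaningful (e.g. early-diverged groups). The
prevalence denominator counts promoters (genes); a species-level mode is
available by flag, and q-value pooling across motifs likewise — per-motif is
the default because the alternative is not determinable from first
principles.

## Architecture: order, co-occurrence, spacers

The family-wide consensus order sorts motifs by median CDS-relative midpoint
(most 5' first; ties broken lexicographically and flagged). A promoter is
*colinear* when its distinct motifs, ordered by midpoint, form an
order-consistent restriction of the consensus, *unordered* otherwise,
*single* or *none* with fewer motifs; only order is compared, never
distances, and the classes partition the promoter set. Promoters are
counted, not motif pairs (a flag switches). Co-occurrence is tabulated per
lineage at gene and species granularity. Spacer distance is the gap between
the downstream edge of the upstream element and the upstream edge of the
downstream element; with duplicated copies the order-consistent pair with
the minimal spacer is used and flagged, and overlapping elements record a
zero spacer with an overlap flag — a deterministic, conservative convention
chosen because duplicates carry no natural pairing.

## CNS boundaries and identity enrichment

Each retained hit is extended by 100 bp of flank on both sides (clipped at
promoter ends, with flags) and the windows of all orthologs are aligned
progressively: guide tree from pairwise 6-mer Jaccard distances with
average-linkage clustering, profile–profile steps by global alignment with
match +1, mismatch −1, gap open −4, gap extend −1 (a gap of length $\ell$
costs $4 + (\ell-1)$). The aligner is deterministic, implemented in C++, and
checked against an independent pairwise aligner at identical scoring.

Boundary delineation replaces a manual call with an explicit rule: starting
from the motif core columns, the CNS span grows outward while every sliding
window of 10 newly added columns keeps mean column conservation (fraction of
non-gap rows sharing the modal base) at or above 0.5. The window covers only
extension columns, so a fully conserved alignment extends to its edges while
a conserved core inside random flanks stays at the core; raising the
threshold never widens a span. Both parameters are config keys. The defaults
were chosen once from first principles: random flank columns have expected
conservation near 0.25, conserved columns well above 0.5, so 0.5 separates
the regimes, and 10 columns keeps single lucky columns from extending a
boundary.

Percent identity is computed from a fresh pairwise global alignment (same
parameters), as matches over alignment columns — deliberately not from MSA
columns, so a pair's identity does not depend on which other orthologs were
aligned. CNS-vs-CDS enrichment is $\log_2(\mathrm{PID}_\mathrm{CNS} /
\mathrm{PID}_\mathrm{CDS})$ against a chosen reference ortholog, grouped by
lineage, with same-species pairs excluded and zero-CDS-identity pairs
dropped and logged. CDS identity uses nucleotide CDS with the same aligner
(protein mode is out of scope); this keeps a single identity convention
throughout.

## Chromatin accessibility

Coverage tracks (bedGraph; BigWig through the same importer) are expanded to
per-base values over the CDS-relative window −2000..+500 around the start
codon. Two distinct computations coexist deliberately: the element *fold
change* — mean signal inside the element over mean signal across the whole
window — is computed on raw values because it is scale-free; *normalized
coverage* divides every track by the single maximum across all cell types in
the window (so exactly one position reaches 1) and is used only where cell
types are compared with each other. The fold-change distribution across cell
types is tested against 1 with a one-sample t-test, one-tailed in the
direction of the sample mean (both enriched and depleted elements occur;
the direction is reported, and a zero-variance sample away from 1 is flagged
degenerate rather than assigned a fake t). Stages are compared pairwise with
Welch t-tests, Bonferroni-corrected by multiplication and capping; stages
with fewer than two cell types skip their pairs with a log entry.
Pseudo-bulk is the per-base sum over all cell types. Normalize-then-sum and
sum-then-normalize differ, so the order is fixed and tested: per-cell-type
normalization for cross-cell-type statistics, normalization after
aggregation for pseudo-bulk display.

## G-quadruplex scan

The canonical patterns G₃L₁₋₇ and G₂L₁₋₄ are detected as any four maximal
G-runs of length ≥ `g_group` whose three inter-run gaps fall within the loop
range, with total span ≤ 45 bp (the span bound is a config key; the upstream
tool's window is not restated anywhere authoritative, so 45 bp is this
package's documented default). Both strands are scanned by default. Only
presence/absence is consumed downstream — no G-score ranking, since the
scientific use is the negative control.

## The synthetic family generator

`simulate_family()` emulates the structure the pipeline is meant to detect:
a species tree (built from lineage blocks with configurable stem and tip
branch lengths, or supplied as newick), one gene per species per clade, and
promoters assembled as lead background + element₁ + spacer + element₂ + tail
background, each 3000 bp by default with the last element 400 bp from the
CDS. Elements are a motif core drawn per species from a probability matrix
whose per-column information content is configurable (1.8 bits/column by
default — this is what makes discovery power predictable under the ZOOPS
generative assumption) plus conserved flanks that evolve along the tree at
`cns_rate`; lead/tail background and the CDS evolve at `background_rate` and
`cds_rate`. Substitution is Jukes–Cantor per site with no indels inside
elements; spacer length is resampled per gene from a geometric distribution
around the lineage's mean (500 bp rosids, 1000 bp asterids by default,
mirroring the magnitude of real lineage differences), which stands in for
spacer indel evolution without a full indel evolver. Losses, duplications
and order swaps are applied per gene with per-lineage probabilities and
recorded in a truth manifest (lost elements are replaced by background of
equal length so other coordinates stay put). Default rates —
`background_rate = 1`, `cns_rate = 0.25`, `cds_rate = 0.5` per unit branch
length with root-to-tip length 1.25 — put background columns well below the
0.5 conservation threshold and element columns well above it, with CDS
intermediate, the regime the delineation rule expects.

Coverage simulation draws independent Poisson counts per base at a
configurable depth (50 by default) over 13 cell types in three developmental
stages, multiplying the mean by `cns_enrichment` (3 by default) over
manifest element intervals only in meristematic cell types. RNG streams are
derived from the master seed by stable string hashing per gene, segment and
cell type, so outputs are byte-identical across runs and independent of
iteration order.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: indels inside elements, rate variation across sites,
GC heterogeneity and repeats in the background, gene gain/loss beyond the
configured probabilities, ATAC fragment-length structure and
cross-cell-type contamination. Recovery results on synthetic data bound
what the pipeline can do when its model assumptions hold; they do not
certify performance on any real genome panel.

## Problem sizes and numerical choices

The shipped tests run the generator at desk scale, chosen once as the
package's own test conditions: discovery power uses 40 species with 1 kb
promoters and a 15-bp planted motif over 10 seeds with 60-shuffle E-values,
with a saturating neutral rate so the background is independent across
species (at moderate divergence the background itself is homologous and
ZOOPS correctly reports conserved background stretches — the power fixture
isolates the planted signal instead, and its control arm plants a
0-bit/column core, i.e. pure iid background);
architecture and conservation use 12–46 species with 2–4 kb promoters;
calibration uses one megabase of background. E-value resolution at 60
shuffles is coarser than at the default 100 but far finer than the 0.05
decision boundary, and the normal-tail fit supplies the deep tail either
way. Score discretization is 1e-3 log2 units; EM convergence is 1e-4
relative log-likelihood with 200 iterations maximum and a floor of 1e-8 on
λ; alignment tie-breaks prefer the match state, then the gap-in-first
profile, making every alignment deterministic.

## Known limitations

Discovery reports ungapped motifs only; a CNS with an internal
variable-length segment would surface as two motifs. The Monte-Carlo
E-value is honest but noisy near the threshold, and single-start null fits
can make it mildly conservative when the observed fit used many starts. The
prevalence filter needs sensible lineage sampling to be meaningful —
the exemption list exists precisely because small clades make the 10%
fraction unstable. Percent identity from global alignment of delineated
CNSs depends on the delineation parameters upstream of it; the tests
therefore treat positional recovery, not exact boundary agreement, as the
primary claim.
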