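---
title: "Phylogenetic footprinting, enrichment biclustering and compartment graphs with phyloFootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic footprinting, enrichment biclustering and compartment graphs with phyloFootprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloFootprint)
```

## The problem

Scanning a promoter with a position weight matrix (PWM) at any useful
sensitivity produces a flood of false positives: a 10-bp motif model with a
permissive cutoff matches somewhere in almost every 6-kb window.
Phylogenetic footprinting suppresses this noise by demanding evolutionary
conservation: a window is called a transcription-factor binding site (TFBS)
only when it scores above the matrix's threshold in *every* species of a
multiple alignment (here, by default, human, mouse, rat and dog). The
package implements this pipeline end to end — matrix parsing, exact p-value
calibration, conserved-site scanning over MAF alignments — and the two
downstream analyses that make the predictions interpretable: Fisher-exact
enrichment of each matrix's target set against annotation term collections
with BiMax-style biclustering of the resulting score matrix, and a
compartment-aware mixed interaction graph for browsing the regulatory and
physical neighborhood of a gene list.

## Motif model and scoring

A `PositionWeightMatrix` stores one probability distribution over A, C, G,
T per motif position. A window `S` of width `W` is scored in bits against a
zero-order background (uniform 0.25 per base by default):

$$\mathrm{SCORE} = \sum_{w=0}^{W-1} \log_2
  \frac{P(S_{w} \mid \mathrm{PWM}, w)}{P(S_{w} \mid \mathrm{background})}$$

Count matrices (TRANSFAC, JASPAR, generic tabular) are regularized with a
background-proportional pseudocount, `p = (c + \kappa\,bg)/(N + \kappa)`
with `\kappa = 1` by default, so every probability is strictly positive and
log-odds weights stay finite. The pseudocount choice is deliberately mild:
it shifts a zero count in a depth-100 column to roughly 2.5e-3 while
leaving well-sampled cells essentially untouched. Matrices that already
arrive as probabilities (UNIPROBE) are renormalized per column; the
pseudocount floor is applied to them *only when they contain zeros*. This
conditional rule is what makes write-then-parse of any collection an exact
identity, which the test suite relies on.

Windows containing `N`, alignment gaps or IUPAC ambiguity codes are
*unscoreable* (`NA`), not low-scoring: genomic alignments are full of such
columns and silently scoring them would bias conservation calls.

## Exact threshold calibration

Rather than using a fixed score cutoff, each matrix gets its own threshold
`t_m` calibrated so the probability that a random background window reaches
it is at most a target p-value (default `5e-5`). The null distribution of
the score is computed *exactly* by column-wise convolution: scores are
discretized on a grid of `binWidth = 0.01` bits, and each motif position
adds its four grid-rounded weights with their background probabilities.
The discretization error of a window score is bounded by `W * binWidth / 2`
(0.05 bits for a 10-bp motif), and the per-bin probability mass agrees with
brute-force enumeration of all `4^W` windows to better than 1e-9 — the
suite checks this for 20 random matrices per run.

Two decisions here are worth making explicit:

* **Non-strict tail.** "p-value below the target" is implemented as
  *achieved tail ≤ target*. On a discrete support a strict inequality is
  ill-posed: the achieved tail jumps between support points, and the
  smallest support score with tail ≤ α is the natural minimal threshold.
  When α is smaller than the mass of the maximum achievable score, no
  window can ever qualify; the threshold is `+Inf` and flagged
  unattainable (this genuinely happens for short matrices: a width-6
  motif's best window already has background probability `4^-6 ≈ 2.4e-4 >
  5e-5`).
* **One grid everywhere.** The scanner scores windows on the *same*
  integer bin grid used for calibration, so `score >= t_m` is an integer
  comparison and results are bit-reproducible across platforms.

```{r calibration}
pwm <- randomPwm(10, concentration = 0.05, seed = 7)
lom <- logOdds(pwm)
thr <- thresholdForPvalue(scoreDistribution(lom), 5e-5)
thr
```

## Conserved-site scanning

Promoter windows are `[tss - 3000, tss + 3000)` per transcript, clipped at
the chromosome boundaries, with the union of coding intervals subtracted
and windows of the same gene merged (interval arithmetic is delegated to
`GenomicRanges`). Scanning then walks every window of `W` consecutive
*reference* bases inside a promoter region and, per strand, extracts each
required species' characters at the *same alignment columns*:

* Conservation is evaluated on alignment columns, not by re-scanning each
  species' unaligned sequence — the question asked is "is this aligned
  position a site in every species", not "does each species have a site
  somewhere".
* A gap or unscoreable character in any required species disqualifies the
  position: a score simply does not exist there, and counting a gapped
  species as passing would fabricate conservation.
* Both strands are scanned independently, the reverse strand with the
  reverse-complemented matrix at the same reference coordinates; each
  strand may yield its own hit.
* The same threshold `t_m` applies to every species.
* A window inside the (merged, possibly overlapping) promoter windows of
  several genes is emitted once per gene, because downstream target sets
  are per-gene.
* Reference rows are expected on the forward strand (UCSC-style reference
  alignments); blocks with a reverse reference row or a missing required
  species are skipped with a message rather than an error, so one odd
  block does not abort a genome-scale run.

Hits are exported in an 8-field BED dialect (`chrom`, `chromStart`,
`chromEnd`, `name`, `score`, `strand`, `gene id`, `geneSymbol`) with the
matrix id and factor names pipe-separated in the `name` field.

## Enrichment biclustering

For each (annotation term, matrix target set) pair the one-sided Fisher
exact p-value `f` is computed — the implementation calls
`stats::fisher.test(alternative = "greater")`, and the test suite verifies
it against the independent hypergeometric closed form — and the score
matrix holds `-log10(f)`. Decisions:

* **Log base 10.** The base is a display convention; after binarization it
  cannot change a single bicluster, and base 10 makes scores readable as
  "orders of magnitude below chance".
* **Binarization at `p < 1e-3`, strict.** The cutoff is exposed as a
  parameter; 1e-3 keeps a 4,000 × 1,100 matrix sparse enough to mine while
  retaining associations far beyond chance. Benjamini–Hochberg q-values
  (`bhAdjust`, a validated wrapper over `stats::p.adjust`) are available
  when calibrated error control is wanted instead.
* **Size minima 2 × 2.** A 1 × k bicluster is just a significant row; the
  interesting structure is terms sharing several matrices and vice versa.

The miner enumerates **all inclusion-maximal all-ones submatrices**. It
does so by closed-set enumeration: the column sets of maximal biclusters
are exactly the intersections of row supports, so iterating intersections
to a fixpoint and reading off each closed column set's full row extent
enumerates every maximal bicluster exactly once. This is equivalent to the
output contract of the published divide-and-conquer recursion while being
considerably easier to verify; equivalence is enforced in the suite by an
independent brute-force oracle that walks all row subsets (matrices up to
14 rows). Worst-case output size is exponential in either formulation —
binarization thresholds keeping the matrix sparse are what make mining
practical.

## The compartment-aware interaction graph

Interaction records are typed (`tf_target_predicted`, `tf_target_chip`,
`tf_target_curated`, `mirna_target`, `kinase_substrate`, `ppi`) and signed
(`activation`, `repression`, `ambiguous`, `none`). Physical interactions
are undirected and unsigned; regulatory and kinase records are directed;
miRNA records default to repression (a miRNA's direct effect on its target
mRNA is inhibitory).

Each gene product may be instantiated once per annotated compartment — a
protein seen in both nucleus and cytosol appears twice, and an edge is
materialized between every instance pair of its two genes. This
deliberately over-draws the graph: it presents current knowledge
exhaustively and leaves pruning to the user and to the filters, rather
than silently picking one "representative" location.

* The bundled compartment tree is
  cell → {extracellular region, plasma membrane, intracellular →
  {cytosol, nucleus, mitochondrion, endoplasmic reticulum, Golgi
  apparatus}}; any user tree loads from a parent-child TSV or a minimal
  OBO subset. Terms outside the tree are walked up their stated ancestry
  to the nearest tree term; genes without usable annotation fall back to
  `intracellular`.
* Zones are nested rectangles computed from the tree (children tiled on a
  near-square grid strictly inside the parent), so zone nesting mirrors
  tree parentage by construction.
* The layout applies inverse-square repulsion between instances, springs
  on edges, and a constant-magnitude pull toward the compartment anchor
  capped at the remaining distance (so an isolated instance settles
  exactly on its anchor). After every step positions are clamped into the
  compartment zone: containment is guaranteed by construction, not by
  hoping the forces balance. The simulation is deterministic given its
  seed and stops after a fixed iteration budget or when the largest step
  falls below 1e-3 units.
* The intercompartmental filter removes undirected physical edges whose
  endpoints are in non-adjacent compartments; adjacency is identity,
  tree parent/child, plus the explicit (extracellular region, plasma
  membrane) pair — a secreted ligand binding a receptor is real biology,
  a nuclear protein binding an extracellular one is almost certainly an
  annotation artifact. Directed regulatory edges are never removed: a
  nuclear factor regulating a membrane protein's gene is exactly what
  transcription does.
* `common_interactors` means partners of *all* selected genes
  (intersection). The alternative reading — partners shared by at least
  two — reduces to repeated pairwise queries and gives no additional
  power, so the stricter and more useful semantics was chosen.
* A gene is flagged as having regulatory information when it appears as
  the source of any directed regulatory record in the supplied compendium.

Exports: SIF (gene-level, relation tokens `activates` / `represses` /
`regulates` / `binds` / `targets` / `phosphorylates`), GraphML
(instance-level via `igraph`, with node attributes and edge rendering
hints: activation green/arrow, repression red/T, ambiguous violet/dot) and
a TSV edge list.

## Synthetic fixtures: what they emulate and what they do not

Every pipeline input has a deterministic generator with planted signal, so
every stage can be tested against a known truth: Dirichlet-random PWMs
(concentration tunes information content), 4-species alignments with
planted consensus sites (per-species mutation and gap rates), annotation
universes with planted memberships, binary matrices with planted all-ones
blocks, and typed interaction tables. Generators are pure functions of
their seed and restore the caller's RNG state.

Two simplifications are deliberate and bound what passing tests can show.
Species rows are drawn *independently* — there is no phylogenetic
substitution model (no HKY/GTR, no branch lengths), so background
conservation arising from shared ancestry is absent and the scanner's
false-positive rate on real alignments will exceed the independent-species
bound tested here. And planted sites are exact consensus copies; real
binding sites are draws from the motif distribution, so real-data recall
at a `5e-5` threshold will be below the 100% the planted fixtures achieve.
The fixtures validate the machinery (coordinates, strand handling,
thresholds, set algebra), not the biology.

## Verification problem sizes

The shipped suite and the acceptance script work at desk scale, chosen so
the complete run finishes in well under a coffee break while still
exercising every code path: 20 random matrices of widths 3–8 for
calibration-vs-enumeration, one 2,000-column 4-species alignment with 10
planted width-10 sites for sensitivity, 50 seeded random alignments
(≈ 200,000 strand-windows) for specificity, 100 random Fisher tables, 30
random 8 × 8 matrices for miner-vs-oracle equivalence, 20 seeded graphs of
up to ~160 instances for the layout and export contracts, and a 30-gene
end-to-end run that recovers a planted two-matrix/two-term association as
a bicluster. Genome-scale inputs (thousands of matrices, full promoter
complements) run through exactly the same code paths; only wall-clock time
changes.

## Known limitations

* Zero-order background only; no Markov backgrounds and no GC-stratified
  calibration. GC-rich matrices will accumulate hits in GC-rich promoters
  (the `pwmStats` GC/information-content table exists precisely to
  diagnose this).
* No branch-length weighting: conservation is all-or-none across the
  required species, which is stringent but blind to lineage-specific
  sites (phylogenetic footprinting trades false positives for false
  negatives by design).
* No liftover between assemblies and no distal (enhancer) scanning;
  regions are TSS-anchored by construction.
* Annotations are used as given — no propagation up the GO graph; a gene
  annotated to a leaf term does not automatically count for its
  ancestors.
* The graph layout is a static 2-D embedding intended for export and
  inspection, not an interactive browser.
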