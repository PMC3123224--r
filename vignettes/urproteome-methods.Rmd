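---
title: "Reconstructing urancestral domain repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing urancestral domain repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urproteome)
```

## The evolutionary model

The package reconstructs upper and lower bounds of the protein fold-
superfamily (FSF) repertoire of the urancestor — the organism at the most
basal node of the tree of ribosome-containing life — from nothing but a
census of domain abundance in modern proteomes. Two assumptions do the
phylogenetic work:

* **Proteomes grow.** Lineages accumulate both diversity (new FSFs) and
  abundance (more copies of old FSFs); a proteome with a small, low-copy
  repertoire reflects an earlier stage of this expansion. Hence, on trees of
  proteomes, character states are polarized from `0` (absence, ancestral) to
  `N` (maximal abundance, derived).
* **Old domains are everywhere.** An FSF that arose early has had the longest
  time to duplicate and to spread across lineages; the most abundant, most
  universal FSFs are the oldest. Hence, on trees of FSFs (the transposed
  matrix), polarization runs from `N` (ancestral) to `0`.

Both polarities are implemented by the Lundberg device: the unrooted
maximum-parsimony tree is rooted by attaching a hypothetical ancestor with
fixed states (all `0` or all `N`) at the edge where it adds the fewest steps.
No outgroup is invoked; the evolutionary model itself supplies the arrow of
time.

Neither assumption is safe for lineages under reductive evolution, which is
why the census is restricted to free-living organisms before any tree is
built (`filter_proteomes`), mirroring the practice of excluding parasitic
genomes from deep phylogenomics.

## Ordered characters and the recoding formula

Raw abundance counts `g_ab` range over orders of magnitude, so they are
standardised to a fixed ordered-state alphabet before analysis:

```
state = round(g_ab / g_max * (n_states - 1)),     n_states = 24
```

with `g_max` the matrix-wide maximum (a per-character maximum is available as
`per_character = TRUE` for sensitivity work, and a logarithmic variant via
`scale = "log"`). Two numerical choices are deliberately pinned down:

* **Rounding ties go half away from zero** (`round_half_up`). Banker's
  rounding — R's default — would flip cells like `11.5 → 12` vs `12.5 → 12`
  silently and make matrices irreproducible across languages.
* **Normalisation is matrix-wide by default.** The alternative (per-character)
  changes what a state means across characters; both are supported because
  the choice is not decidable from the method's verbal description, but the
  default follows the reading "relative to the maximum value in the matrix".

States are written with the alphanumeric symbols `0`–`9`, `A`–`N`, and the
NEXUS writer declares them `ordered`, so matrices are directly consumable by
PAUP*-class software.

## Parsimony on ordered states

Characters are additive: the cost of an edge is `|i - j|`. The engine scores
a topology with a Sankoff-style dynamic program whose inner step — the
min-plus convolution with the `|i - j|` cost — is a one-dimensional distance
transform, reducing the per-edge cost from O(S²) to O(S) for S states. The
same machinery yields, in one pass over the tree:

* the per-character minimal length (`tree_length`),
* the rooted length for an ancestor attached to *every* edge at once
  (`lundberg_root`), which is also reused to place each new taxon during
  stepwise addition, and
* MPR state intervals per node (`mpr_intervals`), from the standard
  down-pass/up-pass decomposition `T_v(s) = D_v(s) + U_v(s)`.

Tree search is heuristic: random taxon-addition starting trees followed by
NNI hill climbing, with a bounded breadth-first walk over the equal-length
plateau so that multiple equally parsimonious topologies are retained
(deduplicated by a canonical topology key, so the retained set is
deterministic). NNI from multiple starts recovers the global optimum on all
matrices small enough to enumerate (the test suite checks every topology with
up to 6 leaves); full TBR is not implemented — at the problem sizes this
package targets, additional swap radius bought no verifiable benefit, and
the search budget is instead spent on addition replicates
(`search_config(preset = "paper")` raises them to 1,000).

Equally good Lundberg attachment edges are all reported
(`$tied_edges`); the first edge in the input order is used, deterministically.

## Root-branch sets, ambiguity, and iterative refinement

A character is *plesiomorphic* when it is gained on the root branch: the MPR
interval of the root node admits a state above the ancestral state. When that
interval also contains the ancestral state, the gain can equally well be
deferred to a deeper branch, and the character is flagged *ambiguous*.
Ambiguous gains are included in the root-branch set (with their flag) —
dropping them silently would bias the initial set toward well-behaved
characters before refinement has had a chance to act; an
`include_ambiguous = FALSE` switch exists for the stricter reading.

Refinement then iterates: build trees on the current character set, re-extract
the root-branch set, repeat. When an iteration returns several equally
parsimonious trees their root sets are unioned by default (an intersection
mode exists). Chains stop early after five consecutive identical sets. Across
all chains and iterations every retained tree is logged, and the final
`max_set` is the root set of the tree with minimal length and, among ties,
minimal FSF count. Per-iteration search seeds are derived from the chain seed
by a fixed counter scheme (`seed * 131 + iteration`, modulo 2³¹ − 1), so a
trace is reproducible from two integers.

The lower bound intersects `max_set` with the `basal_set` of the structure
tree: all FSFs strictly older (smaller `nd`) than the first FSF not shared by
all three superkingdoms. Ties at the boundary are excluded — for a set whose
role is a *lower* bound, the conservative reading is the right default.

## Node distances and the molecular clock

The relative age of a leaf is the number of internal nodes strictly between
the root and the leaf, divided by the maximum such count (`compute_nd`); the
root itself is not counted, so a taxon attached directly at the root has
`nd = 0`. A root-inclusive variant is available behind a flag; it shifts all
counts by one and changes no ordering.

The clock is an ordinary least-squares fit of `nd` on geological age in Ga
(`fit_clock`), inverted by `nd_to_age`. R² is the squared Pearson
correlation. Applying published clock coefficients to published `nd` bounds
does not exactly reproduce published dates (rounded coefficients propagate
roughly ±0.1 Ga through the inversion), so dates are always reported together
with the model that produced them, and published coefficients are treated as
inputs, never as recovery targets.

## Functional enrichment

Sub-category enrichment of an urancestral set against the extant background
uses the exact hypergeometric upper tail `P(X ≥ k)`; the point mass
`P(X = k)` is exposed separately (`hypergeom_point`) because the two are easy
to conflate and only the tail is a significance level. Only sub-categories
over-represented in the sample (`k/n > M/N`) are tested; unannotated FSFs are
excluded from both sample and background sizes. No multiple-testing
correction is applied by default, matching the raw-P convention of the
analysis this package implements; Benjamini–Hochberg is available via
`adjust = "BH"`.

The bundled `inst/extdata/function_scheme.tsv` is a representative
coarse-grained scheme in the Vogel–Chothia style (7 major categories, ~49
annotated sub-categories plus "not annotated") used by the simulator and the
examples; real analyses should supply their curated map via
`read_function_map`.

## What the simulator emulates — and what it does not

`simulate_census` generates a census under the package's own evolutionary
model, with known ground truth:

* a guide tree of three superkingdom clades, `(A, (B, E))`;
* `n_ancestral` FSFs implanted at the root (the true urancestral repertoire);
* abundance growth by per-branch geometric duplication. Each FSF draws its
  own duplication rate from a gamma mixture (mean `duplication_rate = 0.1`,
  shape `0.7`): real censuses are heavy-tailed — a few superfamilies dominate
  the matrix maximum while most stay at a handful of copies — and without
  this heterogeneity every ancestral character would drift to the state
  ceiling in deep lineages, which real abundance matrices do not do;
* derived FSFs born on internal branches and confined to their subtree;
* per-branch loss (`loss_prob = 0.02`) zeroing an FSF below a node; and
* optional horizontal transfer (`hgt_rate`), copying a derived FSF into a
  lineage outside its birth clade.

The `paper_like` fixture (30 proteomes × 300 FSFs, 40 implanted ancestral
FSFs, `hgt_rate = 0.02`, fixed seed) is the standing end-to-end recovery
benchmark; `tiny` (9 × 24) is for hand-checkable unit work. The fixture
seeds are part of the fixtures' identity, not tuning knobs.

What passing on synthetic data does **not** show: the generator draws a
clean three-clade history with independent losses and no reductive-evolution
correlation between characters, no assignment error from the upstream HMM
scans, no paralogy structure within FSFs, and abundance growth that is
monotone in expectation. Recovery rates on it are evidence that the
*machinery* (coding → search → rooting → refinement → intersection) does
what it claims under the model's own assumptions, not a validation of those
assumptions on real proteomes.

Two scale effects observed on the fixtures are worth knowing about. First,
at very small taxon counts (3 per superkingdom) characters confined to the
basal superkingdom clade survive refinement — the "modern effect" needs
enough taxa for re-optimisation to dislodge it; at 10 per superkingdom the
implanted set is recovered with full precision. Second, the re-placed
artificial urancestor (all-`N` on its repertoire, `0` elsewhere) is drawn to
the root by its zeros, so its basal placement requires the urancestral set to
be a small fraction of the character universe — true in the real census
(70/1,420) and in `paper_like` (26–34/300), not in `tiny` (7/24).

## Problem sizes and determinism

Desk-scale defaults are deliberate: 2 addition replicates, 16 retained trees,
4 chains × 10 iterations in `run_all`, and the fixture sizes above; the
`paper` preset restores full-scale search settings. Every stochastic step —
taxon-addition order, bootstrap resampling, random topologies for g1, chain
seeds, the simulator — runs under an explicit integer seed, and the test
suite asserts bit-for-bit reproducibility of trees, traces and sets across
repeated runs.

## Known limitations

* NNI-only swapping can in principle strand a search on a local optimum that
  TBR would escape; multiple random-addition starts mitigate but do not
  eliminate this.
* The plateau walk retains at most `maxtrees` equally parsimonious
  topologies; on very flat landscapes the retained set is a deterministic
  sample, not an exhaustive island enumeration.
* `nd` is a node-counting age proxy; it is invariant to branch lengths by
  design and inherits the usual caveats of cladogenesis-based clocks.
* The basal-set boundary depends on a single tree of domain structures;
  bootstrap support for that tree is computable but not propagated into the
  boundary.
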