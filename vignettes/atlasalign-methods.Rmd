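---
title: "Cross-species atlas alignment: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species atlas alignment: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Homologous cell types in distantly related species express homologous —
but rarely one-to-one orthologous — gene complements. Aligning two
single-cell atlases across such distances therefore cannot rely on a
fixed ortholog table: gene duplication, loss, and expression-role
hand-off between paralogs mean the correct gene-to-gene translation is
itself unknown, and is best inferred *jointly* with the cell-level
alignment. `atlasalign` implements this joint inference: a weighted
bipartite gene-homology graph translates expression between species,
cells are matched through mutual nearest cross-species neighborhoods,
and the expression correlations measured over the resulting joint
manifold are fed back to reweight the homology graph. The loop runs for
a fixed number of rounds (three by default).

# The model, step by step

## Gene homology graph

Reciprocal BLAST tables (tabular `outfmt 6`) provide directional bit
scores. Per (query, subject) pair only the highest-bit-score HSP is
kept, and hits with E-value $\ge 10^{-6}$ are discarded (strict
inequality). Edges present in only one direction are removed; the
combined edge score is the average of the two directional bit scores.
Per gene, edges scoring below $0.25\times$ the gene's best edge are
dropped — checked in both directions, so the two directed weight
matrices always carry mirrored support. Surviving scores $s$ are mapped
through the saturating transform

$$ w = 0.5 + 0.5\tanh\!\left(\frac{10\,s}{\max_b s} - 5\right), $$

which compresses weights into $(0.0033, 0.99991]$ and spreads apart
edges whose bit scores are close to the per-gene maximum. Because the
row-wise maximum normalization is inherently directional, the package
stores two directed weight matrices ($H_1$ with species-1 genes as
rows, $H_2$ with species-2 genes as rows) rather than one symmetric
matrix.

## Per-species manifolds

Each atlas is library-size normalized to the median cell total,
transformed as $\log_2(x+1)$, and stripped of near-ubiquitous genes
(expressed above $\log_2 > 1$ in more than 96% of cells). The manifold
builder is a self-assembling-manifold (SAM) style iteration: standardize
genes (zero mean, unit *population* variance, the StandardScaler
convention), weight genes, run PCA on the 3000 top-weighted genes
(`npcs = 150`), build a directed k-nearest-neighbor graph (`k = 20`,
correlation distance), and recompute gene weights as the max-normalized
dispersion (variance over mean) of kNN-averaged expression. Iteration
stops when the RMS change of the weight vector drops below $10^{-2}$
(at most 10 rounds; the tolerance is exposed as a parameter rather than
hard-coded). A final PCA over *all* genes
yields the 300-row loading matrix each species contributes to the joint
space; when the data have lower rank the loading matrix is zero-padded
so downstream dimensions are invariant.

The builder is a documented variant rather than a port of the original
SAM package: the weight rule above is simpler than the published one,
but reproduces the property that matters here — genes with spatially
coherent expression on the cell graph receive high weight. The function
boundary (`build_manifold`) is the natural place to swap in a faithful
port.

## Joint projection and mutual neighborhoods

Expression is standardized and genes without homology edges are zeroed.
Each species is projected twice: onto its own 300 loadings and — after
translating its expression into the partner's gene space — onto the
partner's loadings, giving 600 joint coordinates. Translation computes
each partner gene's expression as the weighted average of its homologs:
the partner gene's homology weights (restricted to source genes present
in the matrix) are normalized to sum to one. Note the averaging is over
the *target* gene's edges; normalizing the source side instead would
not produce an average and breaks the single-homolog identity (a gene
with one homolog must inherit exactly that homolog's expression). Both
species' 600-dimensional coordinates are assembled in the same global
block order (species-1 PC block first) so that cosine similarities
compare like with like.

Cross-species kNN (`k = 20`, cosine, negatives clipped to zero) gives
two directed cell-level graphs. Because single-cell kNN assignments are
stochastic, mutuality is evaluated at the neighborhood level: each
cell's local neighborhood is the set of cells within $t$ hops of its
within-species kNN graph ($t = 2$ below 20,000 cells, else 3), pruned
to the size of the cell's Leiden community (modularity objective,
resolution 3) keeping the geodesically closest cells — ascending hop
count, ties by descending path count, then ascending index, a
deterministic rule. Hop expansion uses $(I + N)^t$ so every cell within
$1..t$ hops is reachable, and a cell counts as a member of its own
neighborhood. The coarsening kernel replaces cell-to-cell edges by the
fraction of each cell's outgoing edge mass landing inside each partner
cell's neighborhood (rows L1-normalized so entries are true fractions
in $[0,1]$); entries below 0.1 are removed, and the element-wise
geometric mean of the two directions keeps only mutual edges. Each cell
then retains its `k` strongest neighborhoods per direction.

## Stitching and scores

Within-species edges are reweighted by the one-mode projection of the
two cross-species graphs (L1 row normalization; the norm choice is a
config option), restricted to original kNN edges, floored at 0.3 — the
floor keeps cells without cross-species support connected to their
local manifold — and attenuated per cell by $1 - \frac1k\sum_j C_{ij}$.
The four blocks form one $(n_1+n_2)^2$ graph. The floor is applied as
`max(0.3, w)` — a *minimum* edge weight that keeps poorly aligned cells
connected to their local manifold; capping from above would do the
opposite and disconnect exactly the cells that need their
within-species topology most.

The overall alignment score is the total cross-species edge mass per
cell, divided by `k` so it lands on a $[0,1]$ scale; the per-cell-type
score $s_{ab}$ divides the edge mass between two types by their
combined cell count and by `k`. All score thresholds (0.1 for mapping
tables, 0.05 for cell-type network analyses) act on this scale. The
identity $\sum_{ab} s_{ab}(|c_a|+|c_b|) = (n_1+n_2)\,S$ holds exactly
and is asserted in the test suite at $10^{-9}$.

## Refinement

Cross-species expression is imputed as the C-weighted average of
partner cells' log-normalized expression; within-species expression is
kNN-smoothed. Correlations are computed on the log-normalized scale
(the refinement formulas reference the expression matrix, not its
standardized form) over every pair of the *initial unpruned* reciprocal
support — refinement can therefore resurrect edges the bit-score filter
removed, but never invent new ones. Negative correlations prune the
edge; survivors are re-normalized with the same tanh transform.
Imputation and correlation run in gene blocks (2000 pairs by default)
and are bit-identical for any block size, which the suite asserts.

# Downstream statistics

**Enriched gene pairs.** For a mapped type pair, each homology-graph
gene pair is scored by $h_g = T(S(Y_1)) \cdot T(S(Y_2))$ — the product
of the two genes' standardized mean expression over the mapping's
participating cells, negatives truncated to zero. $h_g$ is exactly the
pair's contribution to the cross-species expression correlation, so
pairs with $h_g = 0$ contribute nothing and are excluded before the
top-1000 cut. Filters: both genes rank-sum *enriched* in their type
($p \le 10^{-2}$, one-sided — the two-sided test would also pass genes
significantly depleted in the type), gene weight $\ge 0.2$, expressed
in $\ge 5\%$ of the cluster. The rank-sum test uses the tie-corrected
normal approximation without continuity correction, matching the
standard single-cell implementations.

**Paralog substitutions.** Linked pairs are classified by their most
recent shared orthology group: shared at the species pair's MRCA level
→ ortholog; shared only more ancestrally → paralog; no shared group →
unannotated. A gene whose best paralog correlation exceeds its best
ortholog correlation by more than 0.3 (strict) marks its ortholog as
substituted; when several orthologs exist the maximum correlation is
used (the conservative choice), and a gene with no scored ortholog is
flagged rather than silently treated differently. Every paralog
exceeding the margin is listed with the best one flagged. Events enter
cell-type-level statistics only after assignment to the cell types in
whose mapping the pair is enriched; unassigned events — in practice
chance correlations around 0.3–0.4 between background-expressed genes,
whose effective sample size is reduced by neighborhood smoothing — stay
out of cell-type scores. The per-type score is
$S_k = \sum_{i\in P_k}(1-n_i)/m_k$ with $n_i$ the max-normalized
paralog count and $m_k$ the type's DE gene count; age-level rates
divide substituting paralog pairs by total paralog pairs per level.

**Transitivity.** A triad is a connected three-node set; edge
transitivity is the fraction of triads containing the edge that close
into triangles, node transitivity the same per node. A second reading
of the edge denominator (triads through either endpoint) sits behind
the `denominator` flag. The bootstrap null resamples node subsets of
the observed group's size and reports an add-one-smoothed upper-tail
p-value, so $p \ge 1/(\text{reps}+1)$.

**One-to-one orthologs** are selected by maximum-weight bipartite
matching (igraph); equal-weight optima are broken toward
lexicographically smaller gene pairs via an infinitesimal rank
perturbation, which keeps results deterministic. Tests verify
optimality against exhaustive enumeration on small graphs.

# The synthetic generator

`generate_species_pair()` emits everything the pipeline consumes, with
ground truth. Cell identity is modeled as per-type gene programs (40
genes of 1200 ortholog groups by default, 8 types × 150 cells):
program genes draw negative-binomial counts at mean 8, background at
0.2, dispersion 2, lognormal library-size factors (sd 0.3) and 10%
independent dropout — a standard scRNA-seq noise model sufficient for
recovery testing, chosen once. Homology structure is configurable:
one-to-many and many-to-many groups, species-specific genes with no
homologs, paralog families at sampled ancestral levels, one-directional
decoy BLAST hits, program divergence between species, and planted
substitutions (the species-2 ortholog silenced, its family partner
adopting the program). Bit scores are `200 × identity` plus Gaussian
noise (sd 10) floored at 30, with orthologs near 85% identity and
paralogs near 55%.

What the generator does *not* emulate — batch effects, ambient RNA,
doublets, continuous trajectories, realistic sequence evolution — means
passing recovery tests demonstrates the machinery is correct on
block-structured identity signal, not that mappings of real atlases are
guaranteed at these scores.

# Numerical choices and degenerate inputs

- Standardization uses the population (1/n) variance; zero-variance
  genes become all-zero columns, never NaN.
- PCA is computed from the Gram matrix of the smaller dimension;
  results match a direct SVD up to sign, asserted via pairwise-distance
  comparison in the tests.
- Cells with zero counts are dropped with a warning; identical-cell
  atlases, empty kNN rows, unmapped cells and empty correlation tables
  all degrade gracefully (zero rows/empty tables, no errors).
- All top-k selections break ties toward the smaller index; every
  stochastic step (Leiden, bootstrap) takes an explicit seed.
- Problem sizes throughout the test suite (up to 1200 cells × ~1500
  genes per species) were chosen as the smallest at which all recovery
  properties are comfortably expressed.

# Known limitations

- Exact dense kNN search: fine at desk scale, quadratic in cells; an
  approximate backend can be slotted behind `cross_species_knn`.
- Two species per run; multi-species atlases are aligned pairwise.
- The manifold builder is a SAM-style variant, not the published SAM
  algorithm; gene weights correlate with but do not equal SAM weights.
- The raw substitution detector inherits the correlation noise floor of
  lowly expressed genes; interpret unassigned events with caution.
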