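# atlasalign

Cross-species alignment of single-cell transcriptomic atlases through an
iteratively refined gene-homology graph.

Homologous cell types in distantly related animals rarely express
one-to-one orthologs: genes duplicate, get lost, and paralogs take over
expression roles. Mapping cell types between, say, a frog and a
zebrafish atlas therefore requires inferring the right gene-to-gene
translation *together with* the cell-to-cell alignment. `atlasalign`
does both, for computational biologists comparing whole-organism or
whole-embryo atlases across large evolutionary distances.

## The method

1. **Homology graph.** Reciprocal BLAST bit scores (tabular `outfmt 6`,
   best HSP per pair, E-value < 10⁻⁶) form a bipartite gene graph
   restricted to reciprocal hits, scored `(A + Bᵀ)/2`. Per gene, edges
   below `0.25 × rowmax` are dropped and the rest get weights
   `0.5 + 0.5·tanh(10·s/rowmax − 5)`.
2. **Per-species manifolds.** Each atlas is median-library normalized,
   `log2(x+1)` transformed, and embedded by an iterative
   feature-weighted PCA (k = 20 neighbors, 150 PCs, 3000 top genes); a
   final all-gene PCA gives each species a 300-row loading matrix
   `L_i`.
3. **Joint projection and mutual neighborhoods.** Standardized
   expression `Z̃_i` and its homology-translated counterpart `Z̃_ij`
   are projected as `[Z̃_i L_iᵀ | Z̃_ij L_jᵀ]` into one 600-dimensional
   space. Cross-species cosine kNN edges are coarsened into
   neighborhood-level fractions (hop-expanded, Leiden-sized
   neighborhoods), combined by an element-wise geometric mean
   `C̃ = √(C̃₁ ∘ C̃₂ᵀ)` so only mutual edges survive, and stitched with
   the within-species graphs into one combined manifold.
4. **Refinement.** Expression imputed across the mutual edges yields a
   Pearson correlation for every initially reciprocal gene pair;
   negative correlations prune the edge, positive ones become the new
   weights. Alignment and refinement alternate for three rounds.
5. **Downstream statistics.** Cell-type alignment scores
   `s_ab = (edge mass between a and b) / ((|c_a|+|c_b|)·k)`, enriched
   gene pairs ranked by `h_g = T(S(Y₁))·T(S(Y₂))`, paralog-substitution
   detection (paralog beats ortholog correlation by > 0.3),
   age-stratified substitution rates, cell-type-graph transitivity with
   a bootstrap null, hypergeometric term enrichment, and one-to-one
   ortholog selection by maximum-weight bipartite matching.

A synthetic paired-species generator with ground-truth homology,
cell-type correspondence and planted substitutions makes every stage
testable without downloads.

## Worked example

```r
library(atlasalign)

cfg <- sim_config(n_celltypes = 4, cells_per_type = 50,
                  n_ortholog_groups = 300, program_size = 20,
                  divergence = 0.2, frac_one_to_many = 0.2, seed = 42)
sim <- generate_species_pair(cfg)

hits_12 <- parse_blast_table(sim$blast_12, "sp1", "sp2")
hits_21 <- parse_blast_table(sim$blast_21, "sp2", "sp1")
res <- run_samap(sim$atlas_1, sim$atlas_2, hits_12, hits_21, seed = 1)
res
#> samap_result: sp1 <-> sp2, 3 iteration(s), alignment score 0.990
#>   adjacent-iteration RMSE: 0.0032, 0.0005

celltype_alignment_scores(res$combined$C_1, res$combined$C_2,
                          res$labels[[1]], res$labels[[2]], k = 20, z = 0.1)
#>   type_a type_b     score n_cells_a n_cells_b
#> 1     T2     T2 0.9989247        50        50
#> 2     T3     T3 0.9978163        50        50
#> 3     T1     T1 0.9879499        50        50
#> 4     T4     T4 0.9772190        50        50
```

Two simulated species share four cell types whose gene programs diverge
by 20%, with 20% one-to-many homologs. The overall alignment score
(0.990) is the average mutual-neighborhood mass per cell on a [0, 1]
scale; the falling RMSE between rounds shows the homology-graph
refinement converging. The table lists every cell-type pair scoring at
least `z = 0.1`: each type maps to its true counterpart and nothing
else.

For paralog analysis on a finished run:

```r
pa <- paralog_substitution_analysis(res, sim$orthology)
pa$events        # detected substitutions with correlations and margins
pa$assignments   # events assigned to the cell types where the pair is enriched
```

A thin command-line driver covers the same workflow
(`inst/scripts/atlasalign` with subcommands `simulate`, `map`,
`scores`, `paralogs`).

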