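# Outer refinement loop: cross-species expression imputation, gene-gene
# correlation, and homology-graph reweighting.

#' Impute cross-species expression and smooth within-species expression
#'
#' For every gene, builds one expression vector over the cells of *both*
#' species: partner cells receive the gene's expression imputed as the
#' weighted average over their cross-species neighbors (rows of C are
#' L1-normalized), while same-species cells receive kNN-averaged
#' (smoothed) expression from the within-species graph. Cell order is
#' species-1 cells followed by species-2 cells.
#'
#' @param c1,c2 Cross-species biadjacency matrices (n1 x n2, n2 x n1).
#' @param n1_graph,n2_graph Within-species kNN graphs.
#' @param z1,z2 Log-normalized expression matrices (cells x genes).
#' @return An `imputed_expression` list with `expr_1` ((n1+n2) x m1) and
#'   `expr_2` ((n1+n2) x m2).
#' @export
impute_and_smooth <- function(c1, c2, n1_graph, n2_graph, z1, z2) {
  c1n <- row_l1_normalize(c1); c2n <- row_l1_normalize(c2)
  n1n <- row_l1_normalize(n1_graph); n2n <- row_l1_normalize(n2_graph)
  expr_1 <- rbind(as.matrix(n1n %*% z1),  # species-1 cells, smoothed
                  as.matrix(c2n %*% z1))  # species-2 cells, imputed
  expr_2 <- rbind(as.matrix(c1n %*% z2),  # species-1 cells, imputed
                  as.matrix(n2n %*% z2))  # species-2 cells, smoothed
  colnames(expr_1) <- colnames(z1); colnames(expr_2) <- colnames(z2)
  structure(list(expr_1 = expr_1, expr_2 = expr_2),
            class = "imputed_expression")
}

#' Pearson correlations for homologous gene pairs
#'
#' Correlates, over the concatenated cells of both species, the imputed/
#' smoothed expression vectors of each listed gene pair. Pairs where
#' either vector is constant get `r = 0`. Computation is chunked over
#' gene-pair blocks; results are bit-identical for any block size.
#'
#' @param imputed An `imputed_expression`.
#' @param pairs Data.frame with columns `gene_a` (species 1) and `gene_b`
#'   (species 2), typically the initial unpruned homology support.
#' @param block_size Pairs per block (default 2000).
#' @return The `pairs` data.frame with an `r` column appended.
#' @export
gene_pair_correlations <- function(imputed, pairs, block_size = 2000) {
  stopifnot(inherits(imputed, "imputed_expression"))
  x1 <- imputed$expr_1; x2 <- imputed$expr_2
  n <- nrow(x1)
  ia <- match(pairs$gene_a, colnames(x1))
  ib <- match(pairs$gene_b, colnames(x2))
  if (anyNA(ia) || anyNA(ib))
    stop("gene pair refers to genes absent from the imputed matrices")
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  sd1 <- apply(x1, 2, stats::sd); sd2 <- apply(x2, 2, stats::sd)
  r <- numeric(nrow(pairs))
  np <- nrow(pairs)
  for (start in seq(1L, max(np, 1L), by = block_size)) {
    if (np == 0L) break
    idx <- start:min(start + block_size - 1L, np)
    a <- ia[idx]; b <- ib[idx]
    cross <- colSums(x1[, a, drop = FALSE] * x2[, b, drop = FALSE])
    num <- cross - n * mu1[a] * mu2[b]
    den <- (n - 1) * sd1[a] * sd2[b]
    ri <- ifelse(sd1[a] > 1e-12 & sd2[b] > 1e-12, num / den, 0)
    r[idx] <- pmin(1, pmax(-1, ri))
  }
  pairs$r <- r
  pairs
}

#' Run the full iterative cross-species mapping pipeline
#'
#' Preprocesses both atlases, builds their manifolds, constructs the
#' reciprocal homology graph, and then alternates manifold alignment with
#' correlation-based homology-graph refinement for `num_iters` rounds
#' (alignment runs every round; refinement between rounds). Per-round
#' cell-type alignment-score matrices are recorded and the RMSE between
#' adjacent rounds tracks convergence.
#'
#' @param atlas_1,atlas_2 `expression_atlas` objects (raw counts).
#' @param hits_12,hits_21 `blast_hits` in the two directions (from
#'   [parse_blast_table()]).
#' @param num_iters Alignment-refinement rounds (default 3).
#' @param k Cross- and within-species neighbor count (default 20).
#' @param npcs Manifold PCs (default 150).
#' @param n_top_genes Genes used in the iterative manifold PCA
#'   (default 3000).
#' @param resolution Leiden resolution for neighborhood sizing
#'   (default 3).
#' @param seed Random seed.
#' @param block_size Gene-pair block size for correlation chunking.
#' @param coarsen_prune,within_floor,evalue_cutoff Remaining pipeline
#'   thresholds (defaults 0.1, 0.3, 1e-6).
#' @return A `samap_result` list: `combined` (the stitched
#'   `combined_graph`), `homology` (refined `homology_graph`), `trace`
#'   (per-round score matrices and adjacent-round RMSE), `manifolds`,
#'   `score` (overall alignment score in [0, 1]) and `labels`.
#' @export
run_samap <- function(atlas_1, atlas_2, hits_12, hits_21, num_iters = 3,
                      k = 20, npcs = 150, n_top_genes = 3000,
                      resolution = 3, seed = 0, block_size = 2000,
                      coarsen_prune = 0.1, within_floor = 0.3,
                      evalue_cutoff = 1e-6) {
  hom <- build_reciprocal_graph(hits_12, hits_21)
  hom <- filter_and_normalize(hom)
  support_pairs <- {
    s <- Matrix::summary(hom$support)
    data.frame(gene_a = hom$gene_ids_1[s$i], gene_b = hom$gene_ids_2[s$j],
               stringsAsFactors = FALSE)
  }
  a1 <- preprocess_atlas(atlas_1)
  a2 <- preprocess_atlas(atlas_2)
  m1 <- build_manifold(a1, k = k, npcs = npcs, n_top_genes = n_top_genes,
                       seed = seed)
  m2 <- build_manifold(a2, k = k, npcs = npcs, n_top_genes = n_top_genes,
                       seed = seed + 1)
  nb1 <- expand_neighborhoods(m1$knn_graph, resolution = resolution,
                              seed = seed)
  nb2 <- expand_neighborhoods(m2$knn_graph, resolution = resolution,
                              seed = seed + 1)
  labels_1 <- if (!is.null(a1$cell_types)) a1$cell_types
              else paste0("cl", nb1$clusters)
  labels_2 <- if (!is.null(a2$cell_types)) a2$cell_types
              else paste0("cl", nb2$clusters)

  score_trace <- vector("list", num_iters)
  c1 <- c2 <- NULL
  for (it in seq_len(num_iters)) {
    zt1 <- standardize_and_mask(m1, hom)
    zt2 <- standardize_and_mask(m2, hom)
    zt12 <- translate_features(zt1, hom, from = 1,
                               target_gene_ids = colnames(zt2))
    zt21 <- translate_features(zt2, hom, from = 2,
                               target_gene_ids = colnames(zt1))
    p1 <- joint_projection(zt1, zt12, m1$loadings, m2$loadings)
    p2 <- joint_projection(zt2, zt21, m2$loadings, m1$loadings,
                           own_first = FALSE)
    cx <- cross_species_knn(p1, p2, k = k)
    ct1 <- coarsen_edges(cx$C_1, nb2, prune = coarsen_prune)
    ct2 <- coarsen_edges(cx$C_2, nb1, prune = coarsen_prune)
    ctilde <- mutual_neighborhoods(ct1, ct2)
    sel <- select_knn_neighborhoods(ctilde, k = k)
    c1 <- sel$C_1; c2 <- sel$C_2
    score_trace[[it]] <- attr(
      celltype_alignment_scores(c1, c2, labels_1, labels_2, k = k, z = 0),
      "matrix")
    if (it < num_iters) {
      imp <- impute_and_smooth(c1, c2, m1$knn_graph, m2$knn_graph,
                               m1$lognorm, m2$lognorm)
      cors <- gene_pair_correlations(imp, support_pairs,
                                     block_size = block_size)
      hom <- update_weights_from_correlation(hom, cors)
    }
  }
  rmse <- if (num_iters > 1)
    vapply(seq_len(num_iters - 1), function(it)
      .score_matrix_rmse(score_trace[[it]], score_trace[[it + 1]]),
      numeric(1))
  else numeric(0)
  combined <- stitch_manifolds(
    m1$knn_graph, m2$knn_graph, c1, c2, k = k, within_floor = within_floor,
    cell_ids = c(a1$cell_ids, a2$cell_ids),
    species = c(a1$species, a2$species),
    cell_types = c(labels_1, labels_2))
  structure(list(
    combined = combined, homology = hom,
    trace = list(scores = score_trace, rmse = rmse, iterations = num_iters),
    manifolds = list(m1, m2),
    labels = list(labels_1, labels_2),
    score = overall_alignment_score(c1, c2, k)
  ), class = "samap_result")
}

# RMSE between two cell-type score matrices over the union of their
# type pairs; missing pairs count as zero.
.score_matrix_rmse <- function(a, b) {
  rn <- union(rownames(a), rownames(b))
  cn <- union(colnames(a), colnames(b))
  fa <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  fb <- fa
  fa[rownames(a), colnames(a)] <- a
  fb[rownames(b), colnames(b)] <- b
  sqrt(mean((fa - fb)^2))
}

#' Gene pairs of the initial unpruned homology support
#' @param homology A `homology_graph`.
#' @return Data.frame with `gene_a`, `gene_b`.
#' @export
homology_support_pairs <- function(homology) {
  s <- Matrix::summary(homology$support)
  data.frame(gene_a = homology$gene_ids_1[s$i],
             gene_b = homology$gene_ids_2[s$j], stringsAsFactors = FALSE)
}

#' Gene-pair expression correlations over the final combined manifold
#'
#' Imputes cross-species expression through the final mutual-neighborhood
#' graphs and correlates every gene pair of the initial unpruned homology
#' support over the cells of both species — the quantity downstream
#' paralog-substitution analysis consumes.
#'
#' @param result A `samap_result`.
#' @param block_size Gene-pair chunk size (default 2000).
#' @return Data.frame with `gene_a`, `gene_b`, `r`.
#' @export
map_gene_correlations <- function(result, block_size = 2000) {
  stopifnot(inherits(result, "samap_result"))
  m1 <- result$manifolds[[1]]; m2 <- result$manifolds[[2]]
  imp <- impute_and_smooth(result$combined$C_1, result$combined$C_2,
                           m1$knn_graph, m2$knn_graph,
                           m1$lognorm, m2$lognorm)
  pairs <- homology_support_pairs(result$homology)
  keep <- pairs$gene_a %in% colnames(imp$expr_1) &
    pairs$gene_b %in% colnames(imp$expr_2)
  gene_pair_correlations(imp, pairs[keep, , drop = FALSE],
                         block_size = block_size)
}

#' @exportS3Method base::print
print.samap_result <- function(x, ...) {
  cat(sprintf(
    "samap_result: %s <-> %s, %d iteration(s), alignment score %.3f\n",
    x$combined$species[1], x$combined$species[2], x$trace$iterations,
    x$score))
  if (length(x$trace$rmse))
    cat("  adjacent-iteration RMSE:",
        paste(sprintf("%.4f", x$trace$rmse), collapse = ", "), "\n")
  invisible(x)
}
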