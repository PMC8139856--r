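# One round of cross-species manifold alignment: feature translation,
# joint PC projection, cross-species kNN, graph-coarsening mutual
# neighborhoods, and manifold stitching.

#' Translate expression features into the partner species' gene space
#'
#' Each partner-species gene's imputed expression is the weighted average
#' of the expression of its homologs: the partner gene's homology-edge
#' weights (over the source genes present in the expression matrix) are
#' normalized to sum to one (`SumNorm`) and used as averaging weights.
#' Genes without homologs get a zero column.
#'
#' @param zt Standardized expression of the source species (cells x
#'   genes, from [standardize_and_mask()]).
#' @param homology A `homology_graph`.
#' @param from Which side of the graph the source species is (1 or 2).
#' @param target_gene_ids Gene identifiers (and order) of the partner
#'   species' expression matrix.
#' @return Dense cells x `length(target_gene_ids)` matrix.
#' @export
translate_features <- function(zt, homology, from, target_gene_ids) {
  stopifnot(inherits(homology, "homology_graph"), from %in% c(1, 2))
  # rows of w are the *target* species' genes: each target gene averages
  # over its own homologs
  w <- if (from == 1) homology$weights_21 else homology$weights_12
  if (is.null(w)) stop("homology graph has no weights")
  s <- Matrix::summary(w)
  tgt_genes <- rownames(w)[s$i]
  src_genes <- colnames(w)[s$j]
  i <- match(tgt_genes, target_gene_ids)
  j <- match(src_genes, colnames(zt))
  ok <- !is.na(i) & !is.na(j)
  h <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = s$x[ok],
                            dims = c(length(target_gene_ids), ncol(zt)),
                            dimnames = list(target_gene_ids, colnames(zt)))
  h <- row_l1_normalize(h)
  out <- as.matrix(zt %*% Matrix::t(h))
  dimnames(out) <- list(rownames(zt), target_gene_ids)
  out
}

#' Project a species into the joint principal-component space
#'
#' Concatenates the projection of a species' own standardized expression
#' onto its loadings with the projection of its translated expression
#' onto the partner's loadings, yielding one joint coordinate system for
#' both species (600 columns with the default 300-PC loadings). So that
#' the two species' coordinates are comparable, the column blocks are
#' ordered the same way for both: set `own_first = FALSE` for the second
#' species, putting the partner-space block first.
#'
#' @param zt_own Standardized expression (cells x own genes).
#' @param zt_translated Translated expression (cells x partner genes),
#'   from [translate_features()].
#' @param loadings_own,loadings_partner Loading matrices (300 x genes).
#' @param own_first Put the own-space block in columns 1..300 (default);
#'   both species must use the same global block order.
#' @return Dense cells x (2 * 300) matrix.
#' @export
joint_projection <- function(zt_own, zt_translated, loadings_own,
                             loadings_partner, own_first = TRUE) {
  if (ncol(zt_own) != ncol(loadings_own))
    stop("own expression and loadings disagree on gene count")
  if (ncol(zt_translated) != ncol(loadings_partner))
    stop("translated expression and partner loadings disagree on gene count")
  own <- zt_own %*% t(loadings_own)
  tra <- zt_translated %*% t(loadings_partner)
  if (own_first) cbind(own, tra) else cbind(tra, own)
}

#' Cross-species k-nearest neighbors in the joint PC space
#'
#' For each cell, finds the `k` most cosine-similar cells in the other
#' dataset; negative similarities are clipped to zero.
#'
#' @param p1,p2 Joint projections of the two species (same column count).
#' @param k Neighbors per cell (default 20); if the partner has fewer
#'   than `k` cells, all are kept with a warning.
#' @return A `cross_neighbors` list with sparse biadjacency matrices
#'   `C_1` (n1 x n2), `C_2` (n2 x n1) and `k`.
#' @export
cross_species_knn <- function(p1, p2, k = 20) {
  if (ncol(p1) != ncol(p2)) stop("projections must share a common space")
  structure(list(C_1 = cosine_knn(p1, p2, k),
                 C_2 = cosine_knn(p2, p1, k), k = k),
            class = "cross_neighbors")
}

#' Expand and prune within-species neighborhoods
#'
#' Computes each cell's local neighborhood by walking `hops` steps along
#' the directed kNN graph (path counts within `hops` hops), then prunes
#' each cell's neighborhood to the size of its community: communities are
#' found by modularity-based Leiden clustering at the given resolution,
#' and for a cell in community `c` only the `|c|` geodesically closest
#' cells are kept (ascending hop count, then descending path count, then
#' ascending index).
#'
#' @param knn Directed kNN adjacency (n x n).
#' @param resolution Leiden resolution parameter (default 3).
#' @param seed Seed for the community detection.
#' @param hops Number of hops; default 2 for datasets under
#'   `size_threshold` cells and 3 otherwise.
#' @param size_threshold Dataset size above which 3 hops are used
#'   (default 20000).
#' @return A `neighborhood_structure` with `expanded` (path counts),
#'   `pruned`, `cluster_sizes`, `clusters` and `hops`.
#' @export
expand_neighborhoods <- function(knn, resolution = 3, seed = 0, hops = NULL,
                                 size_threshold = 20000) {
  n <- nrow(knn)
  if (is.null(hops)) hops <- if (n < size_threshold) 2L else 3L
  m <- binarize(knn) + Matrix::Diagonal(n)
  # path counts within `hops` hops; reach_s tracks hop distance
  pow <- m
  reach_sum <- binarize(m)
  if (hops > 1) for (s in 2:hops) {
    pow <- pow %*% m
    reach_sum <- reach_sum + binarize(pow)
  }
  expanded <- .as_dgc(pow)
  Matrix::diag(expanded) <- 0
  expanded <- Matrix::drop0(expanded)
  # hop distance: reach_sum counts how many cumulative powers contain an
  # edge; nested reachability makes hop = hops + 1 - count
  hop_of <- reach_sum
  hop_of@x <- hops + 1 - hop_of@x

  und <- binarize(binarize(knn) + Matrix::t(binarize(knn)))
  g <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution))
  sizes <- as.integer(table(memb)[as.character(memb)])

  # prune each row to its community size, closest first
  te <- Matrix::t(expanded)   # columns = rows of expanded
  th <- Matrix::t(.as_dgc(hop_of))
  p <- te@p
  keep <- logical(length(te@x))
  hop_lookup <- function(row, cols) {
    idx <- if (th@p[row + 1] > th@p[row]) seq.int(th@p[row] + 1L, th@p[row + 1L]) else integer(0)
    v <- stats::setNames(th@x[idx], th@i[idx])
    v[as.character(cols)]
  }
  for (row in seq_len(n)) {
    idx <- if (p[row + 1] > p[row]) seq.int(p[row] + 1L, p[row + 1L]) else integer(0)
    if (!length(idx)) next
    la <- sizes[row]
    if (length(idx) <= la) { keep[idx] <- TRUE; next }
    cols <- te@i[idx]
    hp <- hop_lookup(row, cols)
    ord <- order(hp, -te@x[idx], cols)
    keep[idx[ord[seq_len(la)]]] <- TRUE
  }
  te@x[!keep] <- 0
  pruned <- Matrix::t(Matrix::drop0(te))
  structure(list(hops = hops, expanded = expanded, pruned = pruned,
                 cluster_sizes = sizes, clusters = as.integer(memb), n = n),
            class = "neighborhood_structure")
}

#' Coarsen cross-species edges over target neighborhoods
#'
#' Replaces single-cell cross-species edges by the fraction of each
#' cell's outgoing edge mass that lands inside the local neighborhood of
#' each partner cell (the cell itself plus its pruned neighborhood),
#' making mutual connectivity robust to kNN stochasticity. Edges with
#' coarsened weight below `prune` are removed.
#'
#' @param c_raw Raw directed cross-species kNN matrix (rows = source
#'   cells, columns = target cells); rows are L1-normalized internally.
#' @param nbhd `neighborhood_structure` of the *target* species.
#' @param prune Minimum retained weight (default 0.1).
#' @return Sparse matrix of neighborhood-level edge fractions in [0, 1].
#' @export
coarsen_edges <- function(c_raw, nbhd, prune = 0.1) {
  stopifnot(inherits(nbhd, "neighborhood_structure"))
  cn <- row_l1_normalize(c_raw)
  membership <- binarize(nbhd$pruned + Matrix::Diagonal(nbhd$n))
  out <- .as_dgc(cn %*% Matrix::t(membership))
  out@x[out@x < prune] <- 0
  Matrix::drop0(out)
}

#' Mutual nearest neighborhoods by element-wise geometric mean
#'
#' Combines the two directed coarsened graphs into one undirected
#' bipartite graph: `C(a,b) = sqrt(C1(a,b) * C2(b,a))`, so only
#' bidirectional (mutual) edges survive.
#'
#' @param ct1 Coarsened species-1 -> species-2 matrix (n1 x n2).
#' @param ct2 Coarsened species-2 -> species-1 matrix (n2 x n1).
#' @return Sparse n1 x n2 matrix.
#' @export
mutual_neighborhoods <- function(ct1, ct2) {
  prod <- .as_dgc(ct1 * Matrix::t(ct2))
  prod@x <- sqrt(prod@x)
  Matrix::drop0(prod)
}

#' Select the k nearest neighborhoods per cell in both directions
#'
#' @param ctilde Mutual-neighborhood matrix (n1 x n2).
#' @param k Neighborhoods to keep per cell (default 20); rows with fewer
#'   nonzeros keep all. Ties are broken toward the smaller column index.
#' @return A `cross_neighbors` list with the updated `C_1`, `C_2`.
#' @export
select_knn_neighborhoods <- function(ctilde, k = 20) {
  structure(list(C_1 = topk_rows(ctilde, k),
                 C_2 = topk_rows(Matrix::t(ctilde), k), k = k),
            class = "cross_neighbors")
}

#' Stitch the two manifolds into one combined graph
#'
#' Within-species edges are reweighted by the one-mode projection of the
#' cross-species graphs (shared cross-species neighbors), restricted to
#' edges present in the original kNN graphs and floored at `within_floor`
#' so cells without cross-species support keep their local topology. Each
#' cell's within-species edges are then attenuated by its total
#' cross-species edge mass, and the four blocks are assembled into one
#' `(n1+n2) x (n1+n2)` graph.
#'
#' @param n1_graph,n2_graph Directed within-species kNN graphs.
#' @param c1,c2 Final cross-species biadjacency matrices.
#' @param k Cross-species neighbor count used for attenuation.
#' @param within_floor Minimum within-species edge weight (default 0.3).
#' @param cell_ids Optional combined cell identifiers.
#' @param species Length-2 species tags.
#' @param cell_types Optional combined cell-type labels.
#' @return A `combined_graph` with the sparse block matrix `graph`.
#' @export
stitch_manifolds <- function(n1_graph, n2_graph, c1, c2, k,
                             within_floor = 0.3, cell_ids = NULL,
                             species = c("sp1", "sp2"), cell_types = NULL) {
  .one_side <- function(nmat, cthis, cother) {
    proj <- row_l1_normalize(cthis) %*% row_l1_normalize(cother)
    mask <- binarize(nmat)
    s <- Matrix::summary(mask)
    vals <- pmax(within_floor, .as_dgc(proj)[cbind(s$i, s$j)])
    tilde <- Matrix::sparseMatrix(i = s$i, j = s$j, x = vals, dims = dim(nmat))
    scale <- 1 - Matrix::rowSums(cthis) / k
    scale[scale < 0] <- 0
    .as_dgc(Matrix::Diagonal(x = scale) %*% tilde)
  }
  nt1 <- .one_side(n1_graph, c1, c2)
  nt2 <- .one_side(n2_graph, c2, c1)
  graph <- block_matrix(nt1, c1, c2, nt2)
  n1 <- nrow(c1); n2 <- nrow(c2)
  if (!is.null(cell_ids)) dimnames(graph) <- list(cell_ids, cell_ids)
  structure(list(graph = graph, n1 = n1, n2 = n2, C_1 = .as_dgc(c1),
                 C_2 = .as_dgc(c2), k = k, within_floor = within_floor,
                 species = species, cell_ids = cell_ids,
                 cell_types = cell_types),
            class = "combined_graph")
}

#' @exportS3Method base::print
print.combined_graph <- function(x, ...) {
  cat(sprintf(
    "combined_graph: %s (%d cells) + %s (%d cells), alignment score %.3f\n",
    x$species[1], x$n1, x$species[2], x$n2,
    overall_alignment_score(x$C_1, x$C_2, x$k)))
  invisible(x)
}

#' Overall cross-species alignment score
#'
#' Total mutual-neighborhood edge mass per cell, `(sum(C1) + sum(C2)) /
#' (n1 + n2)`, divided by `k` so the score lies in [0, 1] relative to
#' the maximum possible number of cross-species neighbors.
#'
#' @param c1,c2 Cross-species biadjacency matrices.
#' @param k Maximum neighbors per cell used for the [0, 1] scaling.
#' @return A scalar in [0, 1].
#' @export
overall_alignment_score <- function(c1, c2, k) {
  (sum(c1) + sum(c2)) / ((nrow(c1) + nrow(c2)) * k)
}

#' Export a combined graph as Matrix Market plus cell metadata
#'
#' @param cg A `combined_graph`.
#' @param prefix Output path prefix; writes `<prefix>_graph.mtx` and
#'   `<prefix>_cells.tsv` (species, cell_id, cell_type).
#' @return Invisibly, the paths written.
#' @export
write_combined_graph <- function(cg, prefix) {
  stopifnot(inherits(cg, "combined_graph"))
  mtx <- paste0(prefix, "_graph.mtx")
  tsv <- paste0(prefix, "_cells.tsv")
  Matrix::writeMM(cg$graph, mtx)
  meta <- data.frame(
    species = rep(cg$species, c(cg$n1, cg$n2)),
    cell_id = if (!is.null(cg$cell_ids)) cg$cell_ids
              else paste0(rep(cg$species, c(cg$n1, cg$n2)), "_cell",
                          c(seq_len(cg$n1), seq_len(cg$n2))),
    cell_type = if (!is.null(cg$cell_types)) cg$cell_types else NA
  )
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, tsv))
}
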