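# Downstream cell-type statistics on the stitched cross-species map.

#' Cell-type alignment scores
#'
#' For every pair of cell types (a, b) across the two species, the score
#' is the total cross-species edge mass between their cells divided by
#' their combined cell count and by `k`, landing on a [0, 1] scale where
#' 1 means every cell carries its full complement of maximal-weight
#' mutual cross-species neighbors in the partner type.
#'
#' @param c1,c2 Final cross-species biadjacency matrices.
#' @param labels_1,labels_2 Per-cell type labels (no NAs).
#' @param k Maximum neighbors per cell (scale factor).
#' @param z Minimum score retained in the table (default 0.1); the full
#'   unthresholded score matrix is attached as attribute `"matrix"`.
#' @return A `celltype_mapping` data.frame with columns `type_a`,
#'   `type_b`, `score`, `n_cells_a`, `n_cells_b`, sorted by descending
#'   score.
#' @export
celltype_alignment_scores <- function(c1, c2, labels_1, labels_2, k,
                                      z = 0.1) {
  .check_labels <- function(lab, n, ids) {
    if (length(lab) != n) stop("label vector has wrong length")
    bad <- which(is.na(lab) | !nzchar(lab))
    if (length(bad))
      stop("unlabeled cells: ", paste(utils::head(ids[bad], 10), collapse = ", "))
  }
  ids1 <- rownames(c1) %||% paste0("cell1_", seq_len(nrow(c1)))
  ids2 <- rownames(c2) %||% paste0("cell2_", seq_len(nrow(c2)))
  .check_labels(labels_1, nrow(c1), ids1)
  .check_labels(labels_2, nrow(c2), ids2)
  t1 <- sort(unique(labels_1)); t2 <- sort(unique(labels_2))
  m1 <- Matrix::sparseMatrix(i = seq_along(labels_1),
                             j = match(labels_1, t1), x = 1,
                             dims = c(length(labels_1), length(t1)))
  m2 <- Matrix::sparseMatrix(i = seq_along(labels_2),
                             j = match(labels_2, t2), x = 1,
                             dims = c(length(labels_2), length(t2)))
  mass <- as.matrix(Matrix::t(m1) %*% c1 %*% m2) +
          t(as.matrix(Matrix::t(m2) %*% c2 %*% m1))
  sizes1 <- Matrix::colSums(m1); sizes2 <- Matrix::colSums(m2)
  denom <- outer(sizes1, sizes2, "+") * k
  smat <- mass / denom
  dimnames(smat) <- list(t1, t2)
  idx <- which(smat >= z & smat > 0, arr.ind = TRUE)
  tab <- data.frame(
    type_a = t1[idx[, 1]], type_b = t2[idx[, 2]],
    score = smat[idx],
    n_cells_a = sizes1[idx[, 1]], n_cells_b = sizes2[idx[, 2]],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$score, tab$type_a, tab$type_b), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "matrix") <- smat
  class(tab) <- c("celltype_mapping", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vectorized Wilcoxon rank-sum differential expression
#'
#' One-vs-rest rank-sum test per gene with the tie-corrected normal
#' approximation (no continuity correction), the behavior of the
#' standard single-cell implementations at cluster sizes where the exact
#' test is unnecessary.
#'
#' @param expr Cells x genes matrix.
#' @param in_group Logical vector marking the cells of the cluster.
#' @param alternative `"two.sided"` or `"greater"` (gene enriched in the
#'   cluster).
#' @return P-values, one per gene.
#' @export
wilcoxon_de <- function(expr, in_group,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  expr <- as.matrix(expr)
  n <- nrow(expr)
  n1 <- sum(in_group); n2 <- n - n1
  if (n1 == 0 || n2 == 0) return(rep(NA_real_, ncol(expr)))
  p <- numeric(ncol(expr))
  for (g in seq_len(ncol(expr))) {
    rk <- rank(expr[, g])
    r1 <- sum(rk[in_group])
    u <- r1 - n1 * (n1 + 1) / 2
    ties <- table(expr[, g])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p[g] <- 1; next }
    zstat <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p[g] <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(zstat))
            else stats::pnorm(zstat, lower.tail = FALSE)
  }
  p
}

#' Homologous gene pairs driving a cell-type mapping
#'
#' Scores every current homology-graph gene pair by the product of the
#' two genes' (positively truncated, standardized) mean expression over
#' the cells participating in the mapping between the two cell types --
#' the per-pair contribution to the cross-species expression correlation.
#' The top `top_n` pairs are then filtered: both genes must be
#' differentially expressed in their cell type (rank-sum p <= `de_p`),
#' carry at least `min_weight` manifold gene weight, and be expressed in
#' at least `min_frac` of the cluster's cells.
#'
#' @param type_a,type_b Cell-type labels in species 1 and 2.
#' @param c1,c2 Cross-species biadjacency matrices.
#' @param zt1,zt2 Standardized expression matrices.
#' @param labels_1,labels_2 Per-cell labels.
#' @param homology Current `homology_graph`.
#' @param weights_1,weights_2 Named per-gene manifold weights.
#' @param lognorm_1,lognorm_2 Log-normalized expression (for the
#'   expressed-fraction filter).
#' @param top_n,de_p,min_weight,min_frac Filter thresholds (defaults
#'   1000, 1e-2, 0.2, 0.05).
#' @return A `gene_pair_enrichment` data.frame ranked by descending
#'   `h_g`, with per-gene diagnostics and a `passed` flag.
#' @export
enriched_gene_pairs <- function(type_a, type_b, c1, c2, zt1, zt2,
                                labels_1, labels_2, homology,
                                weights_1, weights_2,
                                lognorm_1, lognorm_2,
                                top_n = 1000, de_p = 1e-2,
                                min_weight = 0.2, min_frac = 0.05) {
  ca <- which(labels_1 == type_a)
  cb <- which(labels_2 == type_b)
  if (!length(ca) || !length(cb))
    stop("unknown cell type: ", type_a, " / ", type_b)
  sub1 <- c1[ca, cb, drop = FALSE]
  sub2 <- c2[cb, ca, drop = FALSE]
  x1 <- ca[Matrix::rowSums(sub1) + Matrix::colSums(sub2) > 0]
  x2 <- cb[Matrix::colSums(sub1) + Matrix::rowSums(sub2) > 0]
  empty <- data.frame(gene_1 = character(0), gene_2 = character(0),
                      h_g = numeric(0), de_p_1 = numeric(0),
                      de_p_2 = numeric(0), frac_expr_1 = numeric(0),
                      frac_expr_2 = numeric(0), sam_weight_1 = numeric(0),
                      sam_weight_2 = numeric(0), passed = logical(0))
  if (!length(x1) || !length(x2)) {
    warning("cell types ", type_a, " and ", type_b, " are not mapped")
    class(empty) <- c("gene_pair_enrichment", "data.frame")
    return(empty)
  }
  s <- Matrix::summary(homology$weights_12)
  g1 <- homology$gene_ids_1[s$i]
  g2 <- homology$gene_ids_2[s$j]
  ok <- g1 %in% colnames(zt1) & g2 %in% colnames(zt2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (!length(g1)) {
    class(empty) <- c("gene_pair_enrichment", "data.frame")
    return(empty)
  }
  y1 <- colMeans(zt1[x1, , drop = FALSE])
  y2 <- colMeans(zt2[x2, , drop = FALSE])
  .std <- function(v) {
    sdv <- stats::sd(v)
    if (!is.finite(sdv) || sdv < 1e-12) rep(0, length(v))
    else (v - mean(v)) / sdv
  }
  s1 <- pmax(.std(y1[g1]), 0)
  s2 <- pmax(.std(y2[g2]), 0)
  h <- s1 * s2
  # pairs with zero score contribute nothing to the correlation and are
  # never candidates
  pos <- h > 0
  g1 <- g1[pos]; g2 <- g2[pos]; h <- h[pos]
  if (!length(g1)) {
    class(empty) <- c("gene_pair_enrichment", "data.frame")
    return(empty)
  }
  ord <- order(-h, g1, g2)[seq_len(min(top_n, length(h)))]
  g1 <- g1[ord]; g2 <- g2[ord]; h <- h[ord]

  ug1 <- unique(g1); ug2 <- unique(g2)
  in1 <- seq_along(labels_1) %in% ca
  in2 <- seq_along(labels_2) %in% cb
  p1 <- stats::setNames(
    wilcoxon_de(lognorm_1[, ug1, drop = FALSE], in1, "greater"), ug1)
  p2 <- stats::setNames(
    wilcoxon_de(lognorm_2[, ug2, drop = FALSE], in2, "greater"), ug2)
  f1 <- stats::setNames(
    colMeans(lognorm_1[ca, ug1, drop = FALSE] > 0), ug1)
  f2 <- stats::setNames(
    colMeans(lognorm_2[cb, ug2, drop = FALSE] > 0), ug2)
  w1 <- weights_1[g1]; w2 <- weights_2[g2]
  tab <- data.frame(
    gene_1 = g1, gene_2 = g2, h_g = h,
    de_p_1 = p1[g1], de_p_2 = p2[g2],
    frac_expr_1 = f1[g1], frac_expr_2 = f2[g2],
    sam_weight_1 = unname(w1), sam_weight_2 = unname(w2),
    stringsAsFactors = FALSE
  )
  tab$passed <- tab$de_p_1 <= de_p & tab$de_p_2 <= de_p &
    tab$sam_weight_1 >= min_weight & tab$sam_weight_2 >= min_weight &
    tab$frac_expr_1 >= min_frac & tab$frac_expr_2 >= min_frac
  rownames(tab) <- NULL
  class(tab) <- c("gene_pair_enrichment", "data.frame")
  tab
}

#' Edge and node transitivity of a cell-type graph
#'
#' A triad is a set of three nodes whose induced subgraph is connected;
#' a closed triad is a triangle. Edge transitivity of (u, v) is the
#' fraction of triads containing the edge that are closed, i.e. the
#' number of common neighbors of u and v over all third nodes adjacent
#' to u or v. Node transitivity is the fraction of triads containing the
#' node that are closed. With `denominator = "either"` the edge
#' denominator instead counts triads through either endpoint.
#'
#' @param edges Data.frame with columns `node_a`, `node_b` and optionally
#'   `score`; edges with `score < edge_threshold` are dropped first.
#' @param edge_threshold Minimum edge score (default 0.05).
#' @param denominator Edge-transitivity denominator variant.
#' @return A list with data.frames `edges` (`node_a`, `node_b`, `score`,
#'   `transitivity`) and `nodes` (`node`, `transitivity`, `n_triads`,
#'   `n_closed`); nodes in no triad have `NA` transitivity.
#' @export
transitivity <- function(edges, edge_threshold = 0.05,
                         denominator = c("edge", "either")) {
  denominator <- match.arg(denominator)
  if (!is.null(edges$score))
    edges <- edges[edges$score >= edge_threshold, , drop = FALSE]
  nodes <- sort(unique(c(as.character(edges$node_a),
                         as.character(edges$node_b))))
  nn <- length(nodes)
  adj <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
  ia <- match(as.character(edges$node_a), nodes)
  ib <- match(as.character(edges$node_b), nodes)
  self <- ia == ib
  adj[cbind(ia[!self], ib[!self])] <- TRUE
  adj <- adj | t(adj)
  common <- adj %*% adj            # common-neighbor counts
  deg <- rowSums(adj)

  et <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    u <- ia[e]; v <- ib[e]
    if (u == v) { et[e] <- NA_real_; next }
    cm <- sum(adj[u, ] & adj[v, ])
    if (denominator == "edge") {
      un <- sum((adj[u, ] | adj[v, ])[-c(u, v)])
    } else {
      # triads through either endpoint, closed or not
      un <- .node_triads(adj, u) + .node_triads(adj, v) -
        sum((adj[u, ] | adj[v, ])[-c(u, v)])
    }
    et[e] <- if (un > 0) cm / un else NA_real_
  }
  tri_per_node <- diag(common %*% adj) / 2    # triangles containing node
  triads_node <- vapply(seq_len(nn), function(v) .node_triads(adj, v),
                        numeric(1))
  nt <- ifelse(triads_node > 0, tri_per_node / triads_node, NA_real_)
  out_edges <- data.frame(node_a = as.character(edges$node_a),
                          node_b = as.character(edges$node_b),
                          score = if (!is.null(edges$score)) edges$score
                                  else NA_real_,
                          transitivity = et, stringsAsFactors = FALSE)
  out_nodes <- data.frame(node = nodes, transitivity = nt,
                          n_triads = triads_node, n_closed = tri_per_node,
                          stringsAsFactors = FALSE)
  list(edges = out_edges, nodes = out_nodes)
}

# Number of connected 3-node sets containing node v:
# pairs of v's neighbors, plus third nodes reached through a neighbor
# but not adjacent to v.
.node_triads <- function(adj, v) {
  nb <- which(adj[v, ])
  choose(length(nb), 2) +
    sum(vapply(nb, function(u) sum(adj[u, ] & !adj[v, ] &
                                     seq_len(ncol(adj)) != v), numeric(1)))
}

#' Bootstrap null for group transitivity
#'
#' Compares the mean node transitivity of an observed node group against
#' groups of the same size sampled uniformly from the graph, returning an
#' add-one-smoothed upper-tail p-value (`p >= 1 / (reps + 1)`).
#'
#' @param trans Output of [transitivity()] (or any data.frame with
#'   `node`, `transitivity`).
#' @param observed_nodes Node names of the observed group.
#' @param reps Bootstrap replicates (default 1e5).
#' @param seed Random seed.
#' @return List with `p_value`, `observed` mean transitivity, and the
#'   null sample mean.
#' @export
bootstrap_transitivity_null <- function(trans, observed_nodes,
                                        reps = 100000, seed = 0) {
  nodes <- if (is.data.frame(trans)) trans else trans$nodes
  tv <- stats::setNames(nodes$transitivity, nodes$node)
  g <- length(observed_nodes)
  if (g > length(tv)) stop("group_size exceeds number of nodes")
  missing <- setdiff(observed_nodes, names(tv))
  if (length(missing)) stop("nodes not in graph: ",
                            paste(missing, collapse = ", "))
  obs <- mean(tv[observed_nodes], na.rm = TRUE)
  set.seed(seed)
  vals <- unname(tv)
  hits <- 0L
  samp_mean <- 0
  for (r in seq_len(reps)) {
    m <- mean(vals[sample.int(length(vals), g)], na.rm = TRUE)
    if (!is.nan(m)) {
      if (m >= obs) hits <- hits + 1L
      samp_mean <- samp_mean + m / reps
    }
  }
  list(p_value = (hits + 1) / (reps + 1), observed = obs,
       null_mean = samp_mean)
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of each annotation term in a target
#' gene set against a background population.
#'
#' @param target_genes Character vector, must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector (the population).
#' @param term_table Data.frame with columns `gene_id` and `term`.
#' @return Data.frame with per-term `count` (annotated target genes),
#'   `expected` count under the null, and `p` (P(X >= count)).
#' @export
hypergeometric_enrichment <- function(target_genes, background_genes,
                                      term_table) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  extra <- setdiff(target_genes, background_genes)
  if (length(extra))
    stop("target genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  tt <- term_table[term_table$gene_id %in% background_genes, , drop = FALSE]
  terms <- sort(unique(as.character(tt$term)))
  n_bg <- length(background_genes)
  n_tg <- length(target_genes)
  res <- lapply(terms, function(tm) {
    ann <- unique(tt$gene_id[tt$term == tm])
    k_ann <- length(ann)
    x <- length(intersect(ann, target_genes))
    data.frame(term = tm, count = x,
               expected = n_tg * k_ann / n_bg,
               p = stats::phyper(x - 1, k_ann, n_bg - k_ann, n_tg,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p, out$term), , drop = FALSE]
}

#' One-to-one ortholog selection by maximum-weight bipartite matching
#'
#' Selects a matching (each gene used at most once) maximizing the total
#' pair weight. Ties between equal-weight optima are broken
#' deterministically toward lexicographically smaller gene-ID pairs via
#' an infinitesimal rank perturbation of the weights.
#'
#' @param pairs Data.frame with columns `gene_1`, `gene_2`, `weight`.
#' @return The subset of `pairs` forming the matching, sorted by
#'   `gene_1`.
#' @export
max_weight_one_to_one <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  pairs <- pairs[order(pairs$gene_1, pairs$gene_2), , drop = FALSE]
  g1 <- unique(pairs$gene_1); g2 <- unique(pairs$gene_2)
  verts <- c(paste0("L\r", g1), paste0("R\r", g2))
  el <- rbind(match(paste0("L\r", pairs$gene_1), verts),
              match(paste0("R\r", pairs$gene_2), verts))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  igraph::V(g)$type <- c(rep(FALSE, length(g1)), rep(TRUE, length(g2)))
  np <- nrow(pairs)
  delta <- 1e-9 * max(1, max(pairs$weight)) / (np + 1)
  wts <- pairs$weight + (np - seq_len(np)) * delta
  mt <- igraph::max_bipartite_match(g, weights = wts)
  matched <- as.integer(mt$matching)[seq_along(g1)]
  sel1 <- g1[!is.na(matched)]
  sel2 <- sub("^R\r", "", verts[matched[!is.na(matched)]])
  keep_key <- paste(sel1, sel2, sep = "\r")
  out <- pairs[paste(pairs$gene_1, pairs$gene_2, sep = "\r") %in% keep_key,
               , drop = FALSE]
  rownames(out) <- NULL
  out
}
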