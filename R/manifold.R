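# SAM-style manifold construction: iterative feature weighting, PCA and
# directed kNN graph per species.

# Truncated PCA via the Gram matrix of the smaller dimension.
# Returns scores (n x d), rotation (m x d) and singular values; d may be
# smaller than npcs when the matrix has lower rank.
.pca <- function(x, npcs, tol = 1e-10) {
  n <- nrow(x); m <- ncol(x)
  npcs <- min(npcs, n, m)
  if (n <= m) {
    gram <- tcrossprod(x)            # n x n
    eig <- eigen(gram, symmetric = TRUE)
    d2 <- pmax(eig$values[seq_len(npcs)], 0)
    d <- sqrt(d2)
    u <- eig$vectors[, seq_len(npcs), drop = FALSE]
    pos <- d > tol * max(d, 1e-300)
    v <- matrix(0, m, npcs)
    if (any(pos))
      v[, pos] <- crossprod(x, sweep(u[, pos, drop = FALSE], 2, d[pos], "/"))
    scores <- sweep(u, 2, d, "*")
  } else {
    gram <- crossprod(x)             # m x m
    eig <- eigen(gram, symmetric = TRUE)
    d2 <- pmax(eig$values[seq_len(npcs)], 0)
    d <- sqrt(d2)
    v <- eig$vectors[, seq_len(npcs), drop = FALSE]
    scores <- x %*% v
  }
  list(scores = scores, rotation = v, d = d)
}

# Directed kNN graph (binary adjacency, k out-edges per row, self excluded)
# under correlation distance between rows of `emb`. Rows with zero variance
# fall back to index order so degenerate inputs never crash.
.corr_knn_graph <- function(emb, k, chunk = 1024L) {
  n <- nrow(emb)
  if (n <= k) stop("number of cells (", n, ") must exceed k = ", k,
                   "; use a smaller k")
  cen <- emb - rowMeans(emb)
  cen <- row_l2_normalize(cen)
  ii <- integer(0); jj <- integer(0)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    sim <- cen[rows, , drop = FALSE] %*% t(cen)
    for (r in seq_along(rows)) {
      a <- rows[r]
      s <- sim[r, ]
      s[a] <- -Inf
      ord <- order(-s, seq_len(n))[seq_len(k)]
      ii <- c(ii, rep.int(a, k)); jj <- c(jj, ord)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

# Per-gene weight: dispersion (variance / mean) of kNN-averaged
# expression, max-normalized to [0, 1]. Spatially structured genes have
# high dispersion after neighborhood averaging; noise averages out.
.sam_gene_weights <- function(lognorm, knn, k) {
  avg <- as.matrix((knn %*% lognorm) / k)
  mu <- colMeans(avg)
  v <- apply(avg, 2, stats::var)
  disp <- ifelse(mu > 1e-12, v / mu, 0)
  mx <- max(disp)
  if (mx <= 0) rep(1, length(disp)) else disp / mx
}

#' Build a per-species manifold by iterative feature-weighted PCA
#'
#' Implements a self-assembling-manifold style iteration: standardize
#' genes, weight them, run PCA on the top-weighted genes, build a
#' directed kNN graph in PC space (correlation distance), recompute gene
#' weights as the max-normalized dispersion of kNN-averaged expression,
#' and repeat until the RMS change of the weights drops below `tol`. A
#' final PCA over *all* genes yields the 300-row loading matrix used to
#' project partner-species expression into this species' PC space.
#'
#' @param atlas A preprocessed `expression_atlas`.
#' @param k Number of nearest neighbors per cell (default 20).
#' @param npcs Number of principal components for the manifold
#'   (default 150).
#' @param n_top_genes Number of top-weighted genes used in the iterative
#'   PCA (default 3000).
#' @param n_final_pcs Rows of the final all-gene loading matrix
#'   (default 300; zero-padded if the data have lower rank).
#' @param seed Random seed (the default exact pipeline is deterministic;
#'   the seed is stored for provenance and for pluggable approximate
#'   backends).
#' @param tol RMS gene-weight change below which iteration stops
#'   (default 1e-2).
#' @param max_iter Maximum weight iterations (default 10).
#' @return An `atlas_manifold` with the directed `knn_graph`, final
#'   `gene_weights`, all-gene `loadings` (`n_final_pcs` x m) and
#'   `pc_scores`.
#' @export
build_manifold <- function(atlas, k = 20, npcs = 150, n_top_genes = 3000,
                           n_final_pcs = 300, seed = 0, tol = 1e-2,
                           max_iter = 10) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (is.null(atlas$lognorm)) stop("run preprocess_atlas() first")
  set.seed(seed)
  E <- atlas$lognorm
  n <- nrow(E); m <- ncol(E)
  w <- rep(1, m)
  Xs <- standardize_cols(E)
  knn <- NULL; pcs <- NULL; iters <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    top <- order(-w, seq_len(m))[seq_len(min(n_top_genes, m))]
    Xw <- sweep(Xs[, top, drop = FALSE], 2, w[top], "*")
    fit <- .pca(Xw, npcs)
    pcs <- fit$scores
    knn <- .corr_knn_graph(pcs, k)
    w_new <- .sam_gene_weights(E, knn, k)
    rms <- sqrt(mean((w_new - w)^2))
    w <- w_new
    if (rms < tol) { converged <- TRUE; break }
  }
  # final all-gene PCA for the cross-species loading matrix
  Xw_all <- sweep(Xs, 2, w, "*")
  fit_all <- .pca(Xw_all, n_final_pcs)
  loadings <- matrix(0, n_final_pcs, m,
                     dimnames = list(NULL, atlas$gene_ids))
  loadings[seq_len(ncol(fit_all$rotation)), ] <- t(fit_all$rotation)
  dimnames(knn) <- list(atlas$cell_ids, atlas$cell_ids)
  structure(list(
    atlas = atlas,
    lognorm = E,
    knn_graph = .as_dgc(knn),
    gene_weights = stats::setNames(w, atlas$gene_ids),
    loadings = loadings,
    pc_scores = pcs,
    k = k, npcs = npcs, iterations = iters, converged = converged,
    seed = seed
  ), class = "atlas_manifold")
}

#' @exportS3Method base::print
print.atlas_manifold <- function(x, ...) {
  cat(sprintf(
    "atlas_manifold '%s': %d cells, %d genes, k=%d, %d iteration(s)%s\n",
    x$atlas$species, nrow(x$lognorm), ncol(x$lognorm), x$k, x$iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Standardize expression and mask genes without homology edges
#'
#' Produces the standardized expression matrix used for cross-species
#' translation: genes absent from the current homology-graph support are
#' zeroed, the remaining genes are z-scored to zero mean and unit
#' variance, and zero-variance genes are set to all-zero rather than NaN.
#'
#' @param manifold An `atlas_manifold`.
#' @param homology A `homology_graph` involving this species (matched by
#'   species tag).
#' @return Dense cells x genes matrix; the `"masked"` attribute lists the
#'   zeroed genes.
#' @export
standardize_and_mask <- function(manifold, homology) {
  stopifnot(inherits(manifold, "atlas_manifold"),
            inherits(homology, "homology_graph"))
  sp <- manifold$atlas$species
  side <- match(sp, homology$species)
  if (is.na(side)) stop("species '", sp, "' not present in homology graph")
  w <- if (side == 1) homology$weights_12 else homology$weights_21
  if (is.null(w)) stop("homology graph has no weights; run filter_and_normalize()")
  with_edges <- rownames(w)[Matrix::rowSums(w) > 0]
  genes <- colnames(manifold$lognorm)
  keep <- genes %in% with_edges
  z <- standardize_cols(manifold$lognorm)
  z[, !keep] <- 0
  attr(z, "masked") <- genes[!keep]
  z
}
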