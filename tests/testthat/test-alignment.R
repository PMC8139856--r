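# Toy standardized matrix with named genes.
.zt <- function(m, genes, cells = NULL) {
  dimnames(m) <- list(cells %||% paste0("c", seq_len(nrow(m))), genes)
  m
}

test_that("feature translation averages homolog expression with SumNorm weights", {
  h12 <- .mk_hits(data.frame(q = c("g1", "g2", "g2"),
                             s = c("h1", "h2", "h3"),
                             b = c(40, 10, 30)), "sp1", "sp2")
  h21 <- .mk_hits(data.frame(q = c("h1", "h2", "h3"),
                             s = c("g1", "g2", "g2"),
                             b = c(40, 10, 30)), "sp2", "sp1")
  hom <- build_reciprocal_graph(h12, h21)
  # hand-set weights 1 and 3 for h4's two homologs
  hom$weights_12 <- Matrix::sparseMatrix(
    i = c(1, 2, 2), j = c(1, 2, 3), x = c(1, 1, 3), dims = c(2, 3),
    dimnames = list(c("sp1_g1", "sp1_g2"), c("sp2_h1", "sp2_h2", "sp2_h3")))
  hom$weights_21 <- Matrix::t(hom$weights_12)
  zt <- .zt(cbind(c(1, -1, 0), c(2, 0, -2)), c("sp1_g1", "sp1_g2"))
  out <- translate_features(zt, hom, from = 1,
                            target_gene_ids = c("sp2_h1", "sp2_h2",
                                                "sp2_h3", "sp2_h4"))
  expect_equal(unname(out[, "sp2_h1"]), zt[, "sp1_g1"] |> unname())  # single homolog
  expect_equal(unname(out[, "sp2_h2"]), unname(zt[, "sp1_g2"]))
  expect_equal(unname(out[, "sp2_h4"]), c(0, 0, 0))                  # no homolog
  # from species 2: h-genes at weights 1 and 3 mix as 0.25 / 0.75
  zt2 <- .zt(cbind(c(4, 0), c(0, 8), c(8, 0)),
             c("sp2_h1", "sp2_h2", "sp2_h3"))
  out2 <- translate_features(zt2, hom, from = 2,
                             target_gene_ids = c("sp1_g1", "sp1_g2"))
  expect_equal(unname(out2[, "sp1_g2"]),
               unname(0.25 * zt2[, "sp2_h2"] + 0.75 * zt2[, "sp2_h3"]))
})

test_that("joint projection concatenates consistently ordered 300-PC blocks", {
  set.seed(1)
  z <- matrix(rnorm(5 * 8), 5, 8)
  L <- matrix(rnorm(300 * 8), 300, 8)
  p_own <- joint_projection(z, z, L, L)
  expect_equal(ncol(p_own), 600)
  # identity self-translation: the two halves coincide
  expect_equal(p_own[, 1:300], p_own[, 301:600])
  # swapped ordering for the partner species mirrors the blocks
  p_sw <- joint_projection(z, z, L, L, own_first = FALSE)
  expect_equal(p_sw[, 301:600], p_own[, 1:300])
  expect_equal(joint_projection(matrix(0, 5, 8), matrix(0, 5, 8), L, L),
               matrix(0, 5, 600))
  expect_error(joint_projection(z, z, L[, 1:5], L), "disagree")
})

test_that("cross-species kNN matches an exhaustive cosine search", {
  p1 <- rbind(c(1, 0), c(0, 1), c(2, 0))
  p2 <- rbind(c(3, 0), c(0, -1))
  cx <- cross_species_knn(p1, p2, k = 1)
  expect_equal(unname(cx$C_1[1, ]), c(1, 0))   # collinear: similarity 1
  expect_equal(unname(cx$C_1[2, ]), c(0, 0))   # orthogonal / negative clipped
  set.seed(5)
  a <- matrix(rnorm(50 * 12), 50, 12); b <- matrix(rnorm(50 * 12), 50, 12)
  cx <- cross_species_knn(a, b, k = 7)
  an <- a / sqrt(rowSums(a^2)); bn <- b / sqrt(rowSums(b^2))
  sim <- pmax(an %*% t(bn), 0)
  for (i in seq_len(50)) {
    oracle <- order(-sim[i, ], seq_len(50))[1:7]
    expect_equal(sort(which(cx$C_1[i, ] > 0)), sort(oracle))
    expect_equal(unname(cx$C_1[i, oracle]), unname(sim[i, oracle]))
  }
  expect_warning(cross_species_knn(a, b[1:3, ], k = 7), "keeping all")
})

test_that("neighborhood expansion counts paths and hop rule switches at 20000 cells", {
  chain <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = 1,
                                dims = c(3, 3))
  nb <- expand_neighborhoods(chain, resolution = 1, seed = 1, hops = 2)
  expect_equal(sort(which(nb$expanded[1, ] > 0)), c(2, 3))
  expect_equal(unname(nb$expanded[1, 3]), 1)     # single a->b->c path

  ring <- function(n) Matrix::sparseMatrix(i = seq_len(n),
                                           j = c(2:n, 1), x = 1,
                                           dims = c(n, n))
  expect_equal(expand_neighborhoods(ring(19999), seed = 1)$hops, 2L)
  expect_equal(expand_neighborhoods(ring(20000), seed = 1)$hops, 3L)
})

test_that("hop expansion reachability equals breadth-first search", {
  for (seed in 1:20) {
    n <- sample(10:60, 1)
    g <- random_knn_graph(n, k = min(3, n - 1), seed = seed)
    t_i <- sample(2:3, 1)
    nb <- expand_neighborhoods(g, seed = seed, hops = t_i)
    ig <- igraph::graph_from_adjacency_matrix(g, mode = "directed")
    d <- igraph::distances(ig, mode = "out")
    reach <- d <= t_i & d > 0
    expect_equal(unname(as.matrix(nb$expanded > 0)), unname(reach))
  }
})

test_that("neighborhood pruning keeps the community-sized closest set", {
  # 5-clique: every neighborhood fits inside the community, nothing pruned
  cl <- methods::as(Matrix::Matrix(1, 5, 5) - Matrix::Diagonal(5),
                    "CsparseMatrix")
  nb <- expand_neighborhoods(cl, resolution = 1, seed = 1, hops = 2)
  expect_equal(Matrix::nnzero(nb$pruned), Matrix::nnzero(nb$expanded))
  expect_true(all(Matrix::rowSums(nb$pruned > 0) <= nb$cluster_sizes))
})

test_that("graph coarsening computes neighborhood edge fractions", {
  # species-2 neighborhood structure: cell 1's neighborhood = {1, 2}
  n2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(4, 4))
  nb2 <- expand_neighborhoods(n2, resolution = 1, seed = 1, hops = 2)
  # cell a sends both its edges into {1, 2}: fraction 1
  c_raw <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 2, 3),
                                x = c(0.5, 0.5, 0.5, 0.5), dims = c(2, 4))
  ct <- coarsen_edges(c_raw, nb2, prune = 0.1)
  expect_equal(unname(ct[1, 1]), 1)       # full containment
  expect_equal(unname(ct[2, 1]), 0.5)     # half the edge mass
  # a 0.09 fraction falls below the prune threshold and vanishes
  c_small <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 3), x = c(0.09, 0.91),
                                  dims = c(1, 4))
  ct2 <- coarsen_edges(c_small, nb2, prune = 0.1)
  expect_equal(unname(ct2[1, 1]), 0)
  expect_equal(unname(ct2[1, 3]), 0.91)
  # row-sum conservation against brute-force summation, random graphs
  for (seed in 1:5) {
    set.seed(seed)
    n_a <- 20; n_b <- 30
    craw <- Matrix::rsparsematrix(n_a, n_b, 0.2, rand.x = function(n) runif(n))
    g2 <- random_knn_graph(n_b, 3, seed)
    nbb <- expand_neighborhoods(g2, seed = seed, hops = 2)
    ct3 <- coarsen_edges(craw, nbb, prune = 0)
    cn <- as.matrix(craw / pmax(Matrix::rowSums(abs(craw)), 1e-300))
    memb <- as.matrix(nbb$pruned > 0) | diag(n_b) > 0
    oracle <- sapply(seq_len(n_b), function(b)
      rowSums(cn[, memb[b, ], drop = FALSE]))
    expect_equal(unname(as.matrix(ct3)), unname(oracle), tolerance = 1e-12)
  }
})

test_that("mutual neighborhoods are the element-wise geometric mean", {
  c1 <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2),
                             x = c(0.4, 0.8, 0.5), dims = c(2, 2))
  c2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2),
                             x = c(0.9, 0.5), dims = c(2, 2))
  ct <- mutual_neighborhoods(c1, c2)
  expect_equal(unname(ct[1, 1]), 0.6)   # sqrt(0.4 * 0.9)
  expect_equal(unname(ct[1, 2]), 0)     # one-directional edge dies
  expect_equal(unname(ct[2, 2]), 0.5)   # sqrt(x * x) = x
  # support containment
  expect_true(all(which(as.matrix(ct) > 0) %in%
                    intersect(which(as.matrix(c1) > 0),
                              which(as.matrix(Matrix::t(c2)) > 0))))
})

test_that("top-k neighborhood selection agrees with a full sort", {
  sparse_row <- Matrix::sparseMatrix(i = rep(1, 3), j = c(2, 5, 9),
                                     x = c(0.3, 0.2, 0.1), dims = c(1, 30))
  sel <- select_knn_neighborhoods(sparse_row, k = 20)
  expect_equal(Matrix::nnzero(sel$C_1), 3)          # fewer than k: keep all
  set.seed(3)
  dense_row <- Matrix::Matrix(matrix(round(runif(25), 2), 1, 25), sparse = TRUE)
  sel2 <- select_knn_neighborhoods(dense_row, k = 20)
  vals <- as.numeric(dense_row)
  oracle <- order(-vals, seq_along(vals))[1:20]      # ties to smaller index
  expect_equal(sort(which(sel2$C_1[1, ] > 0)), sort(oracle))
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(2, 5))
  sel3 <- select_knn_neighborhoods(empty, k = 3)
  expect_equal(Matrix::nnzero(sel3$C_1), 0)
})

test_that("stitching floors, attenuates, and assembles the block graph", {
  n1 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  n2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2))
  k <- 2
  # cell 1 has k cross edges of weight 1 -> its within edges scale by 0
  c1 <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = 1, dims = c(3, 2))
  c2 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(2, 3))
  cg <- stitch_manifolds(n1, n2, c1, c2, k = k)
  expect_equal(dim(cg$graph), c(5, 5))
  # block structure
  expect_equal(unname(as.matrix(cg$graph[1:3, 4:5])), unname(as.matrix(c1)))
  expect_equal(unname(as.matrix(cg$graph[4:5, 1:3])), unname(as.matrix(c2)))
  expect_equal(unname(cg$graph[1, 2]), 0)         # fully attenuated
  # cell 2 has no cross edges: floor 0.3, scale 1
  expect_equal(unname(cg$graph[2, 1]), 0.3)
  # within-species support never exceeds the original kNN support
  expect_true(all(which(as.matrix(cg$graph[1:3, 1:3]) > 0) %in%
                    which(as.matrix(n1) > 0)))
})

test_that("overall alignment score is total cross edge mass per cell over k", {
  c1 <- Matrix::sparseMatrix(i = 1, j = 1, x = 0.8, dims = c(2, 2))
  c2 <- Matrix::sparseMatrix(i = 1, j = 1, x = 0.4, dims = c(2, 2))
  expect_equal(overall_alignment_score(c1, c2, k = 2), 1.2 / (4 * 2))
  z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2, 2))
  expect_equal(overall_alignment_score(z, z, k = 20), 0)
})
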