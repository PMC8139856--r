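test_that("cell-type alignment scores follow the edge-mass formula", {
  # |c_a| = |c_b| = 2, four cross edges of weight 1, k = 1 -> s_ab = 1
  c1 <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = 1, dims = c(2, 2))
  c2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  tab <- celltype_alignment_scores(c1, c2, c("A", "A"), c("B", "B"),
                                   k = 1, z = 0.1)
  expect_equal(tab$score, 1)
  expect_equal(tab$n_cells_a, 2)

  # unconnected pair scores zero and is dropped from the table
  c0 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 2))
  z0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(2, 2))
  tab2 <- celltype_alignment_scores(c0, z0, c("A", "C"), c("B", "D"),
                                    k = 1, z = 0.1)
  expect_false(any(tab2$type_a == "C"))
  full <- attr(tab2, "matrix")
  expect_equal(unname(full["C", "D"]), 0)

  expect_error(
    celltype_alignment_scores(c1, c2, c("A", NA), c("B", "B"), k = 1),
    "unlabeled")
})

test_that("score conservation ties the type table to the overall score", {
  fx <- cached_small_run()
  cg <- fx$run$combined
  tab <- celltype_alignment_scores(cg$C_1, cg$C_2, fx$run$labels[[1]],
                                   fx$run$labels[[2]], k = cg$k, z = 0)
  sm <- attr(tab, "matrix")
  sizes1 <- table(fx$run$labels[[1]])[rownames(sm)]
  sizes2 <- table(fx$run$labels[[2]])[colnames(sm)]
  lhs <- sum(sm * outer(as.numeric(sizes1), as.numeric(sizes2), "+"))
  rhs <- (cg$n1 + cg$n2) * overall_alignment_score(cg$C_1, cg$C_2, cg$k)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("rank-sum DE matches wilcox.test normal approximation with ties", {
  set.seed(21)
  expr <- cbind(rnorm(40), rpois(40, 1), rep(2, 40))
  grp <- rep(c(TRUE, FALSE), each = 20)
  p <- wilcoxon_de(expr, grp)
  for (g in 1:2) {
    ref <- wilcox.test(expr[grp, g], expr[!grp, g], exact = FALSE,
                       correct = FALSE)$p.value
    expect_equal(p[g], ref, tolerance = 1e-12)
  }
  expect_equal(p[3], 1)      # all-tied gene is never significant
  pg <- wilcoxon_de(expr, grp, alternative = "greater")
  ref_g <- wilcox.test(expr[grp, 1], expr[!grp, 1], exact = FALSE,
                       correct = FALSE, alternative = "greater")$p.value
  expect_equal(pg[1], ref_g, tolerance = 1e-12)
})

test_that("enriched gene pairs rank planted markers first and filter the rest", {
  fx <- cached_small_run()
  res <- fx$run; sim <- fx$sim
  m1 <- res$manifolds[[1]]; m2 <- res$manifolds[[2]]
  zt1 <- standardize_and_mask(m1, res$homology)
  zt2 <- standardize_and_mask(m2, res$homology)
  tab <- enriched_gene_pairs("T1", "T1", res$combined$C_1, res$combined$C_2,
                             zt1, zt2, res$labels[[1]], res$labels[[2]],
                             res$homology, m1$gene_weights, m2$gene_weights,
                             m1$lognorm, m2$lognorm)
  expect_true(all(diff(tab$h_g) <= 1e-12))          # ranked by h_g
  passed <- tab[tab$passed, ]
  prog <- sim$truth$programs$sp1$`1`
  # passed species-1 genes are overwhelmingly the type's program genes
  expect_gte(mean(sub("^sp1_", "", passed$gene_1) %in% prog), 0.9)
  expect_true(all(passed$de_p_1 <= 1e-2 & passed$de_p_2 <= 1e-2))
  expect_true(all(passed$frac_expr_1 >= 0.05 & passed$frac_expr_2 >= 0.05))
  expect_true(all(passed$sam_weight_1 >= 0.2 & passed$sam_weight_2 >= 0.2))
  # an unmapped pair yields an empty table with a warning
  smat <- attr(celltype_alignment_scores(res$combined$C_1, res$combined$C_2,
               res$labels[[1]], res$labels[[2]], k = 20, z = 0), "matrix")
  unmapped <- which(smat == 0, arr.ind = TRUE)[1, ]
  expect_warning(
    e <- enriched_gene_pairs(rownames(smat)[unmapped[1]],
                             colnames(smat)[unmapped[2]],
                             res$combined$C_1, res$combined$C_2, zt1, zt2,
                             res$labels[[1]], res$labels[[2]], res$homology,
                             m1$gene_weights, m2$gene_weights,
                             m1$lognorm, m2$lognorm),
    "not mapped")
  expect_equal(nrow(e), 0)
})

test_that("transitivity matches closed-form toys", {
  k3 <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "a"),
                   score = 1)
  tr <- transitivity(k3)
  expect_equal(tr$edges$transitivity, rep(1, 3))
  expect_equal(tr$nodes$transitivity, rep(1, 3))
  path <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"), score = 1)
  trp <- transitivity(path)
  expect_equal(trp$edges$transitivity, c(0, 0))
  expect_equal(trp$nodes$transitivity[trp$nodes$node == "b"], 0)
  # thresholding removes weak edges before the census
  wk <- rbind(k3, data.frame(node_a = "a", node_b = "d", score = 0.01))
  expect_false("d" %in% transitivity(wk, edge_threshold = 0.05)$nodes$node)
})

test_that("transitivity equals exhaustive triad enumeration on random graphs", {
  for (seed in 1:25) {
    ed <- random_edges(n = sample(6:20, 1), p = 0.3, seed = seed)
    if (nrow(ed) < 2) next
    tr <- transitivity(ed, edge_threshold = 0)
    orc <- triad_oracle(ed)
    expect_equal(stats::setNames(tr$nodes$transitivity, tr$nodes$node),
                 orc$node[tr$nodes$node])
    key <- paste(pmin(tr$edges$node_a, tr$edges$node_b),
                 pmax(tr$edges$node_a, tr$edges$node_b))
    has_triads <- key %in% names(orc$edge)
    expect_equal(tr$edges$transitivity[has_triads],
                 unname(orc$edge[key[has_triads]]))
    expect_true(all(is.na(tr$edges$transitivity[!has_triads])))
  }
})

test_that("bootstrap transitivity null is reproducible and properly smoothed", {
  k4 <- expand.grid(a = 1:4, b = 1:4)
  k4 <- k4[k4$a < k4$b, ]
  ed <- data.frame(node_a = paste0("v", k4$a), node_b = paste0("v", k4$b),
                   score = 1)
  tr <- transitivity(ed)
  # complete graph: every subset has transitivity 1 -> p = 1
  out <- bootstrap_transitivity_null(tr, c("v1", "v2"), reps = 200, seed = 1)
  expect_equal(out$p_value, 1)
  # a graph where the observed pair is strictly best
  ed2 <- rbind(ed, data.frame(node_a = c("v1", "v5"), node_b = c("v5", "v6"),
                              score = 1))
  tr2 <- transitivity(ed2)
  o1 <- bootstrap_transitivity_null(tr2, c("v2", "v3"), reps = 500, seed = 9)
  o2 <- bootstrap_transitivity_null(tr2, c("v2", "v3"), reps = 500, seed = 9)
  expect_identical(o1$p_value, o2$p_value)       # fixed-seed reproducibility
  expect_gte(o1$p_value, 1 / 501)
  expect_error(bootstrap_transitivity_null(tr, paste0("v", 1:9), reps = 10),
               "group_size")
})

test_that("hypergeometric enrichment equals exact tail enumeration", {
  bg <- paste0("g", 1:10)
  terms <- data.frame(gene_id = paste0("g", 1:4), term = "T")
  out <- hypergeometric_enrichment(paste0("g", c(1:3, 9, 10)), bg, terms)
  expect_equal(out$p, 66 / 252, tolerance = 1e-12)   # P(X >= 3)
  expect_equal(out$count, 3)
  expect_equal(out$expected, 5 * 4 / 10)
  # observed 0 -> p = 1
  out0 <- hypergeometric_enrichment(paste0("g", 5:8), bg, terms)
  expect_equal(out0$p, 1)
  # random cases vs direct combinatorial sums, populations <= 30
  for (seed in 1:20) {
    set.seed(seed)
    nn <- sample(8:30, 1); kk <- sample(1:nn, 1); dr <- sample(1:nn, 1)
    bg2 <- paste0("g", 1:nn)
    ann <- sample(bg2, kk)
    tgt <- sample(bg2, dr)
    x <- length(intersect(ann, tgt))
    exact <- sum(vapply(x:min(kk, dr), function(i)
      choose(kk, i) * choose(nn - kk, dr - i), numeric(1))) / choose(nn, dr)
    got <- hypergeometric_enrichment(tgt, bg2,
                                     data.frame(gene_id = ann, term = "T"))
    expect_equal(got$p, exact, tolerance = 1e-10)
  }
  expect_error(hypergeometric_enrichment("zz", bg, terms), "missing")
})

test_that("maximum-weight matching is optimal and deterministically tie-broken", {
  pairs <- data.frame(gene_1 = c("a", "a", "b"), gene_2 = c("x", "y", "y"),
                      weight = c(5, 3, 4))
  out <- max_weight_one_to_one(pairs)
  expect_equal(out$gene_1, c("a", "b"))
  expect_equal(out$gene_2, c("x", "y"))
  expect_equal(sum(out$weight), 9)
  one <- data.frame(gene_1 = "a", gene_2 = "x", weight = 2)
  expect_equal(nrow(max_weight_one_to_one(one)), 1)
  tie <- data.frame(gene_1 = c("a", "b"), gene_2 = c("x", "x"),
                    weight = c(1, 1))
  got <- max_weight_one_to_one(tie)
  expect_equal(nrow(got), 1)
  expect_equal(got$gene_1, "a")        # lexicographic preference
  # brute-force oracle on random bipartite graphs up to 8 + 8 genes
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    all_pairs <- expand.grid(gene_1 = paste0("a", 1:n1),
                             gene_2 = paste0("b", 1:n2),
                             stringsAsFactors = FALSE)
    keep <- runif(nrow(all_pairs)) < 0.4
    if (!any(keep)) next
    pr <- all_pairs[keep, ]
    pr$weight <- round(runif(nrow(pr), 1, 10), 2)
    got <- max_weight_one_to_one(pr)
    expect_equal(sum(got$weight), brute_force_matching(pr)$weight,
                 tolerance = 1e-9)
    expect_false(any(duplicated(got$gene_1)))
    expect_false(any(duplicated(got$gene_2)))
  }
})
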