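# Shared fixtures: small synthetic species pairs and a cached default
# pipeline run reused across tests.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_celltypes = 4, cells_per_type = 50, n_ortholog_groups = 300,
         program_size = 20), list(...))
  do.call(sim_config, args)
}

small_sim <- function(seed = 7, ...) {
  generate_species_pair(small_config(seed = seed, ...))
}

sim_hits <- function(sim) {
  list(h12 = parse_blast_table(sim$blast_12, "sp1", "sp2"),
       h21 = parse_blast_table(sim$blast_21, "sp2", "sp1"))
}

# Hand-built blast_hits object from a (q, s, b) data.frame.
.mk_hits <- function(df, sq, ss) {
  out <- data.frame(query_gene = paste0(sq, "_", df$q),
                    subject_gene = paste0(ss, "_", df$s),
                    bit_score = df$b, e_value = 1e-50)
  attr(out, "species_query") <- sq
  attr(out, "species_subject") <- ss
  class(out) <- c("blast_hits", "data.frame")
  out
}

.fixture_cache <- new.env(parent = emptyenv())

# One small default-parameter pipeline run, computed once per session.
cached_small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- small_sim(seed = 7)
    h <- sim_hits(sim)
    .fixture_cache$sim <- sim
    .fixture_cache$run <- run_samap(sim$atlas_1, sim$atlas_2, h$h12, h$h21,
                                    seed = 1)
  }
  list(sim = .fixture_cache$sim, run = .fixture_cache$run)
}

# Random directed graph with out-degree k on n nodes (no self loops).
random_knn_graph <- function(n, k, seed) {
  set.seed(seed)
  ii <- rep(seq_len(n), each = k)
  jj <- unlist(lapply(seq_len(n), function(a)
    sample(setdiff(seq_len(n), a), k)))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

# Random undirected edge list on n nodes with edge probability p.
random_edges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(node_a = paste0("v", pairs[keep, 1]),
             node_b = paste0("v", pairs[keep, 2]),
             score = 1)
}

# Exhaustive triad enumeration oracle: per-node and per-edge fraction of
# connected 3-sets that are triangles.
triad_oracle <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  nn <- length(nodes)
  adj <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
  adj[cbind(match(edges$node_a, nodes), match(edges$node_b, nodes))] <- TRUE
  adj <- adj | t(adj)
  node_tot <- stats::setNames(numeric(nn), nodes)
  node_closed <- node_tot
  edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  etot <- list(); eclosed <- list()
  if (nn >= 3) {
    combs <- utils::combn(nn, 3)
    for (c_i in seq_len(ncol(combs))) {
      trip <- combs[, c_i]
      sub <- adj[trip, trip]
      ne <- sum(sub) / 2
      if (ne < 2) next                       # not connected
      closed <- ne == 3
      for (v in trip) {
        node_tot[v] <- node_tot[v] + 1
        if (closed) node_closed[v] <- node_closed[v] + 1
      }
      for (a in 1:2) for (b in (a + 1):3) {
        u <- trip[a]; v <- trip[b]
        if (!adj[u, v]) next
        k <- edge_key(nodes[u], nodes[v])
        etot[[k]] <- (etot[[k]] %||% 0) + 1
        if (closed) eclosed[[k]] <- (eclosed[[k]] %||% 0) + 1
      }
    }
  }
  list(
    node = ifelse(node_tot > 0, node_closed / node_tot, NA_real_),
    edge = vapply(names(etot), function(k)
      (eclosed[[k]] %||% 0) / etot[[k]], numeric(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force maximum-weight bipartite matching by recursion over the
# pair list (each gene used at most once).
brute_force_matching <- function(pairs) {
  best <- list(weight = -Inf, rows = integer(0))
  recurse <- function(i, used1, used2, rows, total) {
    if (i > nrow(pairs)) {
      if (total > best$weight + 1e-12) best <<- list(weight = total, rows = rows)
      return()
    }
    recurse(i + 1, used1, used2, rows, total)
    g1 <- pairs$gene_1[i]; g2 <- pairs$gene_2[i]
    if (!(g1 %in% used1) && !(g2 %in% used2))
      recurse(i + 1, c(used1, g1), c(used2, g2), c(rows, i),
              total + pairs$weight[i])
  }
  recurse(1L, character(0), character(0), integer(0), 0)
  best
}
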