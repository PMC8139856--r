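#' Parse a tabular BLAST report into best-HSP homology hits
#'
#' Reads a 12+ column BLAST tabular report (`outfmt 6`:
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), keeps hits with E-value strictly below
#' `evalue_cutoff`, and collapses multiple HSPs of the same
#' (query, subject) pair to the single HSP with the highest bit score.
#' Gene identifiers are prefixed with their species tag
#' (`"<tag>_<id>"`) so they are globally unique across species.
#'
#' @param path Path to a BLAST tabular file, or a data.frame with the same
#'   columns (column 1 = query id, 2 = subject id, 11 = E-value,
#'   12 = bit score).
#' @param species_query,species_subject Short species tags (e.g. `"zf"`,
#'   `"xe"`) used to prefix the query and subject gene identifiers.
#' @param evalue_cutoff Hits with `e_value >= evalue_cutoff` are discarded
#'   (strict `<`; default `1e-6`).
#' @return A data.frame of class `blast_hits` with columns `query_gene`,
#'   `subject_gene`, `bit_score`, `e_value`, one row per retained pair.
#' @export
parse_blast_table <- function(path, species_query, species_subject,
                              evalue_cutoff = 1e-6) {
  if (is.data.frame(path)) {
    tab <- path
    if (ncol(tab) < 12)
      stop("BLAST table must have at least 12 columns, got ", ncol(tab))
    qry <- as.character(tab[[1]]); sbj <- as.character(tab[[2]])
    ev <- suppressWarnings(as.numeric(tab[[11]]))
    bs <- suppressWarnings(as.numeric(tab[[12]]))
    bad <- which(is.na(ev) | is.na(bs))
    if (length(bad))
      stop("malformed BLAST table: non-numeric E-value/bit score at row ", bad[1])
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("empty BLAST table: ", path)
      return(.empty_hits(species_query, species_subject))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 12)
    if (length(bad))
      stop("malformed BLAST line ", bad[1], " in ", path,
           ": expected >= 12 columns, found ", nf[bad[1]])
    qry <- vapply(fields, `[[`, "", 1L)
    sbj <- vapply(fields, `[[`, "", 2L)
    ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
    bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
    bad <- which(is.na(ev) | is.na(bs))
    if (length(bad))
      stop("malformed BLAST line ", bad[1], " in ", path,
           ": non-numeric E-value or bit score")
  }
  keep <- ev < evalue_cutoff
  qry <- qry[keep]; sbj <- sbj[keep]; ev <- ev[keep]; bs <- bs[keep]
  if (!length(qry)) {
    warning("no BLAST hits below E-value cutoff ", evalue_cutoff)
    return(.empty_hits(species_query, species_subject))
  }
  qry <- prefix_gene_ids(qry, species_query)
  sbj <- prefix_gene_ids(sbj, species_subject)
  # best HSP per (query, subject) pair
  key <- paste(qry, sbj, sep = "\r")
  ord <- order(key, -bs, ev)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  sel <- sel[order(sel)]
  hits <- data.frame(
    query_gene = qry[sel], subject_gene = sbj[sel],
    bit_score = bs[sel], e_value = ev[sel],
    stringsAsFactors = FALSE
  )
  attr(hits, "species_query") <- species_query
  attr(hits, "species_subject") <- species_subject
  class(hits) <- c("blast_hits", "data.frame")
  hits
}

.empty_hits <- function(species_query, species_subject) {
  hits <- data.frame(query_gene = character(0), subject_gene = character(0),
                     bit_score = numeric(0), e_value = numeric(0),
                     stringsAsFactors = FALSE)
  attr(hits, "species_query") <- species_query
  attr(hits, "species_subject") <- species_subject
  class(hits) <- c("blast_hits", "data.frame")
  hits
}

#' @keywords internal
prefix_gene_ids <- function(ids, tag) {
  pre <- paste0(tag, "_")
  ifelse(startsWith(ids, pre), ids, paste0(pre, ids))
}

#' Build the reciprocal gene-homology graph from two BLAST directions
#'
#' Combines the two directional bit-score tables into a single bipartite
#' gene-gene graph, keeping only reciprocal edges (pairs hit in both BLAST
#' directions) with combined score `raw(a,b) = (A_ab + B_ba) / 2`, the
#' symmetrized average of the two directional bit scores.
#'
#' @param hits_12 `blast_hits` with species 1 queries against species 2.
#' @param hits_21 `blast_hits` in the opposite direction.
#' @return An object of class `homology_graph` with fields `gene_ids_1`,
#'   `gene_ids_2`, sparse `raw` score matrix (m1 x m2), the initial
#'   unpruned `support` pattern, and species tags. Normalized weights are
#'   filled in by [filter_and_normalize()].
#' @export
build_reciprocal_graph <- function(hits_12, hits_21) {
  sp1 <- attr(hits_12, "species_query")
  sp2 <- attr(hits_12, "species_subject")
  if (!is.null(attr(hits_21, "species_query")) &&
      !identical(attr(hits_21, "species_query"), sp2))
    stop("hits_21 must be the reverse BLAST direction of hits_12")
  key12 <- paste(hits_12$query_gene, hits_12$subject_gene, sep = "\r")
  key21 <- paste(hits_21$subject_gene, hits_21$query_gene, sep = "\r")
  common <- intersect(key12, key21)
  if (!length(common))
    stop("no homology between species: no reciprocal BLAST edges found")
  i12 <- match(common, key12)
  i21 <- match(common, key21)
  g1 <- hits_12$query_gene[i12]
  g2 <- hits_12$subject_gene[i12]
  score <- 0.5 * (hits_12$bit_score[i12] + hits_21$bit_score[i21])
  gene_ids_1 <- sort(unique(g1))
  gene_ids_2 <- sort(unique(g2))
  raw <- Matrix::sparseMatrix(
    i = match(g1, gene_ids_1), j = match(g2, gene_ids_2), x = score,
    dims = c(length(gene_ids_1), length(gene_ids_2)),
    dimnames = list(gene_ids_1, gene_ids_2)
  )
  structure(list(
    gene_ids_1 = gene_ids_1, gene_ids_2 = gene_ids_2,
    species = c(sp1, sp2),
    raw = .as_dgc(raw),
    support = binarize(raw),
    weights_12 = NULL, weights_21 = NULL
  ), class = "homology_graph")
}

# Per-row max over structurally nonzero entries of a CsparseMatrix.
.row_nz_max <- function(m) {
  m <- .as_dgc(m)
  s <- Matrix::summary(m)
  out <- numeric(nrow(m))
  if (nrow(s)) {
    agg <- tapply(s$x, s$i, max)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# Row-wise saturating tanh reweighting: w = 0.5 + 0.5*tanh(10*x/rowmax - 5),
# applied to the nonzero entries of a nonnegative sparse matrix.
.tanh_row_normalize <- function(m) {
  m <- .as_dgc(Matrix::drop0(m))
  s <- Matrix::summary(m)
  if (!nrow(s)) return(m)
  rm <- .row_nz_max(m)
  w <- 0.5 + 0.5 * tanh(10 * s$x / rm[s$i] - 5)
  Matrix::sparseMatrix(i = s$i, j = s$j, x = w, dims = dim(m),
                       dimnames = dimnames(m))
}

#' Filter weak homology edges and compute saturating edge weights
#'
#' Removes, per gene, edges whose combined bit score falls strictly below
#' a quarter of that gene's best edge (checked in both directions so the
#' two directed weight matrices keep mirrored support), then maps the
#' surviving scores through the saturating transform
#' `w = 0.5 + 0.5 * tanh(10 * s / rowmax(s) - 5)`, which spreads edge
#' weights of comparable bit score apart near the top of the range.
#'
#' @param graph A `homology_graph` from [build_reciprocal_graph()].
#' @param rel_cutoff Per-row relative score cutoff (default 0.25); edges
#'   with `raw < rel_cutoff * rowmax` are dropped (strict `<`, so ties at
#'   the boundary are kept).
#' @return The graph with sparse `weights_12` (rows = species-1 genes) and
#'   `weights_21` (rows = species-2 genes) filled in; weights lie in
#'   `(0.5 + 0.5*tanh(-5), 0.5 + 0.5*tanh(5)]`.
#' @export
filter_and_normalize <- function(graph, rel_cutoff = 0.25) {
  stopifnot(inherits(graph, "homology_graph"))
  raw <- graph$raw
  s <- Matrix::summary(raw)
  if (!nrow(s)) stop("homology graph has no edges")
  rm1 <- .row_nz_max(raw)
  rm2 <- .row_nz_max(Matrix::t(raw))
  keep <- !(s$x < rel_cutoff * rm1[s$i]) & !(s$x < rel_cutoff * rm2[s$j])
  pruned <- Matrix::sparseMatrix(i = s$i[keep], j = s$j[keep], x = s$x[keep],
                                 dims = dim(raw), dimnames = dimnames(raw))
  graph$weights_12 <- .tanh_row_normalize(pruned)
  graph$weights_21 <- .tanh_row_normalize(Matrix::t(pruned))
  graph
}

#' Reweight the homology graph with expression correlations
#'
#' Replaces homology-edge weights with cross-species expression
#' correlations: negative correlations are clamped to zero (pruning the
#' edge), and surviving weights are re-normalized per gene with the same
#' saturating tanh transform used for bit scores. Pairs outside the
#' initial unpruned support are ignored; refinement therefore never adds
#' edges.
#'
#' @param graph A `homology_graph` with `support` set.
#' @param correlations Data.frame with columns `gene_a` (species 1),
#'   `gene_b` (species 2) and `r` (Pearson correlation in `[-1, 1]`).
#' @return The graph with updated `weights_12` / `weights_21`.
#' @export
update_weights_from_correlation <- function(graph, correlations) {
  stopifnot(inherits(graph, "homology_graph"))
  r <- correlations$r
  if (any(!is.finite(r)) || any(r < -1 - 1e-9) || any(r > 1 + 1e-9))
    stop("correlations must be finite and lie in [-1, 1]")
  i <- match(correlations$gene_a, graph$gene_ids_1)
  j <- match(correlations$gene_b, graph$gene_ids_2)
  ok <- !is.na(i) & !is.na(j)
  w <- pmax(r[ok], 0)
  cw <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = w,
                             dims = dim(graph$raw),
                             dimnames = dimnames(graph$raw))
  cw <- Matrix::drop0(cw * graph$support)  # never add support
  graph$weights_12 <- .tanh_row_normalize(cw)
  graph$weights_21 <- .tanh_row_normalize(Matrix::t(cw))
  graph
}

#' @exportS3Method base::print
print.homology_graph <- function(x, ...) {
  ne <- if (is.null(x$weights_12)) Matrix::nnzero(x$raw) else Matrix::nnzero(x$weights_12)
  cat(sprintf("homology_graph: %s (%d genes) <-> %s (%d genes), %d edges%s\n",
              x$species[1], length(x$gene_ids_1),
              x$species[2], length(x$gene_ids_2), ne,
              if (is.null(x$weights_12)) " (raw only)" else ""))
  invisible(x)
}

#' Write a homology graph as TSV and Matrix Market files
#'
#' Writes `<prefix>_edges.tsv` with columns gene_1, gene_2, raw_score,
#' weight, plus `<prefix>_weights12.mtx` with the directed species-1 ->
#' species-2 weight matrix.
#'
#' @param graph A `homology_graph` with weights computed.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_homology_graph <- function(graph, prefix) {
  stopifnot(!is.null(graph$weights_12))
  s <- Matrix::summary(graph$weights_12)
  raw <- graph$raw[cbind(s$i, s$j)]
  tab <- data.frame(gene_1 = graph$gene_ids_1[s$i],
                    gene_2 = graph$gene_ids_2[s$j],
                    raw_score = raw, weight = s$x)
  tsv <- paste0(prefix, "_edges.tsv")
  mtx <- paste0(prefix, "_weights12.mtx")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(graph$weights_12, mtx)
  invisible(c(tsv, mtx))
}
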