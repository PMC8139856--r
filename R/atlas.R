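#' Construct a single-species expression atlas
#'
#' Bundles a raw count matrix with gene/cell identifiers, a species tag
#' and optional per-cell type labels. Gene and cell identifiers are
#' prefixed with the species tag so they remain unique when two atlases
#' are combined.
#'
#' @param counts Cells x genes matrix of nonnegative counts (dense or
#'   sparse; stored sparse).
#' @param gene_ids,cell_ids Character vectors naming columns and rows.
#' @param species Short species tag used as identifier prefix.
#' @param cell_types Optional character vector of per-cell labels.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(counts, gene_ids, cell_ids, species,
                             cell_types = NULL) {
  counts <- .as_dgc(counts)
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length must equal ncol(counts)")
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length must equal nrow(counts)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (any(counts@x < 0) || any(!is.finite(counts@x)))
    stop("counts must be finite and nonnegative")
  if (!is.null(cell_types) && length(cell_types) != nrow(counts))
    stop("cell_types length must equal the number of cells")
  gene_ids <- prefix_gene_ids(as.character(gene_ids), species)
  cell_ids <- prefix_gene_ids(as.character(cell_ids), species)
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(
    counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
    species = species, cell_types = cell_types, lognorm = NULL,
    median_size = NULL
  ), class = "expression_atlas")
}

#' @exportS3Method base::print
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas '%s': %d cells x %d genes%s%s\n",
              x$species, nrow(x$counts), ncol(x$counts),
              if (!is.null(x$cell_types)) sprintf(", %d cell types",
                length(unique(x$cell_types))) else "",
              if (!is.null(x$lognorm)) ", preprocessed" else ""))
  invisible(x)
}

#' Library-size normalize, log-transform, and drop ubiquitous genes
#'
#' Cells are rescaled so every library totals the median library size,
#' expression is transformed as `log2(x + 1)`, and genes expressed
#' (`log2 > 1`) in strictly more than `max_expressed_frac` of cells are
#' removed, since near-ubiquitous genes carry no cell-type signal.
#' Cells with zero total counts are dropped with a warning.
#'
#' @param atlas An `expression_atlas` with raw counts.
#' @param max_expressed_frac Ubiquity cutoff (default 0.96; strict `>`).
#' @return The atlas with normalized `counts`, a dense `lognorm` matrix,
#'   and filtered gene set.
#' @export
preprocess_atlas <- function(atlas, max_expressed_frac = 0.96) {
  stopifnot(inherits(atlas, "expression_atlas"))
  sizes <- Matrix::rowSums(atlas$counts)
  empty <- sizes == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total counts dropped: ",
            paste(utils::head(atlas$cell_ids[empty], 5), collapse = ", "))
    atlas$counts <- atlas$counts[!empty, , drop = FALSE]
    atlas$cell_ids <- atlas$cell_ids[!empty]
    if (!is.null(atlas$cell_types)) atlas$cell_types <- atlas$cell_types[!empty]
    sizes <- sizes[!empty]
  }
  med <- stats::median(sizes)
  scaled <- .as_dgc(Matrix::Diagonal(x = med / sizes) %*% atlas$counts)
  lognorm <- scaled
  lognorm@x <- log2(lognorm@x + 1)
  frac_on <- Matrix::colSums(lognorm > 1) / nrow(lognorm)
  keep <- frac_on <= max_expressed_frac  # strict > removal
  atlas$counts <- scaled[, keep, drop = FALSE]
  atlas$lognorm <- as.matrix(lognorm[, keep, drop = FALSE])
  atlas$gene_ids <- atlas$gene_ids[keep]
  atlas$median_size <- med
  atlas
}
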