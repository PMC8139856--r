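# Readers and writers for the standard on-disk formats: Matrix Market
# expression matrices with gene/barcode lists, dense TSV matrices,
# BLAST tabular files, orthology tables and simulator output.

#' Read an expression atlas from disk
#'
#' Accepts either a Matrix Market triplet file with companion gene and
#' barcode lists, or a dense TSV with genes as columns and cells as rows
#' (first column = cell id).
#'
#' @param counts_path `.mtx` file (cells x genes or genes x cells with
#'   `transpose = TRUE`) or dense `.tsv`.
#' @param species Species tag.
#' @param genes_path,barcodes_path One-identifier-per-line files
#'   (required for `.mtx` input).
#' @param celltypes_path Optional TSV with columns `cell_id`, `label`.
#' @param transpose Set TRUE when the Matrix Market file is genes x
#'   cells.
#' @return An `expression_atlas`.
#' @export
read_atlas <- function(counts_path, species, genes_path = NULL,
                       barcodes_path = NULL, celltypes_path = NULL,
                       transpose = FALSE) {
  if (!file.exists(counts_path)) stop("file not found: ", counts_path)
  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(genes_path) || is.null(barcodes_path))
      stop("mtx input requires genes_path and barcodes_path")
    counts <- .as_dgc(Matrix::readMM(counts_path))
    if (transpose) counts <- Matrix::t(counts)
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
  } else {
    tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1)
    counts <- .as_dgc(as.matrix(tab))
    genes <- colnames(tab)
    cells <- rownames(tab)
  }
  cell_types <- NULL
  if (!is.null(celltypes_path)) {
    ct <- utils::read.table(celltypes_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    idx <- match(cells, ct[[1]])
    if (anyNA(idx))
      stop("cells missing from cell-type table: ",
           paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
    cell_types <- as.character(ct[[2]][idx])
  }
  expression_atlas(counts, genes, cells, species, cell_types)
}

#' Write an expression atlas as Matrix Market plus identifier lists
#'
#' @param atlas An `expression_atlas`.
#' @param prefix Output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>_genes.tsv`, `<prefix>_barcodes.tsv`, and
#'   `<prefix>_celltypes.tsv` when labels are present.
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "expression_atlas"))
  paths <- c(paste0(prefix, ".mtx"), paste0(prefix, "_genes.tsv"),
             paste0(prefix, "_barcodes.tsv"))
  Matrix::writeMM(atlas$counts, paths[1])
  writeLines(atlas$gene_ids, paths[2])
  writeLines(atlas$cell_ids, paths[3])
  if (!is.null(atlas$cell_types)) {
    p <- paste0(prefix, "_celltypes.tsv")
    utils::write.table(
      data.frame(cell_id = atlas$cell_ids, label = atlas$cell_types),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a BLAST-like table in tabular (outfmt-6) form
#' @param tab 12-column data.frame.
#' @param path Output path.
#' @export
write_blast_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an orthology-group table
#' @param path TSV with columns `gene_id`, `level`, `group_id` (header
#'   optional but recommended).
#' @export
read_orthology_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "level", "group_id")
  if (!all(need %in% names(tab)))
    stop("orthology table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Write a simulated species pair to a directory
#'
#' Emits the exact file formats the pipeline consumes: per-species
#' Matrix Market atlases with identifier lists and cell-type labels,
#' two BLAST tabular files, the orthology TSV, and the ground truth as
#' JSON.
#'
#' @param sim Output of [generate_species_pair()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_species_pair <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(sim$atlas_1, file.path(dir, "sp1"))
  write_atlas(sim$atlas_2, file.path(dir, "sp2"))
  write_blast_table(sim$blast_12, file.path(dir, "blast_12.tsv"))
  write_blast_table(sim$blast_21, file.path(dir, "blast_21.tsv"))
  utils::write.table(sim$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
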