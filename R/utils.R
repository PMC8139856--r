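# Internal sparse-matrix and linear-algebra helpers shared across modules.

.as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' @keywords internal
row_l1_normalize <- function(m) {
  rs <- Matrix::rowSums(abs(m))
  rs[rs == 0] <- 1
  .as_dgc(Matrix::Diagonal(x = 1 / rs) %*% m)
}

#' @keywords internal
row_l2_normalize <- function(m) {
  rs <- sqrt(Matrix::rowSums(m^2))
  rs[rs == 0] <- 1
  m / rs
}

# Keep the k largest entries of each row of a sparse matrix.
# Ties are broken in favour of the smaller column index so the
# selection is deterministic.
#' @keywords internal
topk_rows <- function(m, k) {
  m <- .as_dgc(m)
  tm <- Matrix::t(m)  # CsparseMatrix: columns of tm are rows of m
  p <- tm@p
  keep <- logical(length(tm@x))
  for (row in seq_len(ncol(tm))) {
    idx <- if (p[row + 1] > p[row]) seq.int(p[row] + 1L, p[row + 1L]) else integer(0)
    if (length(idx) <= k) {
      keep[idx] <- TRUE
    } else {
      vals <- tm@x[idx]
      cols <- tm@i[idx]
      ord <- order(-vals, cols)
      keep[idx[ord[seq_len(k)]]] <- TRUE
    }
  }
  tm@x[!keep] <- 0
  Matrix::t(Matrix::drop0(tm))
}

# Column-wise standardization to zero mean / unit variance with the
# population (1/n) variance, matching StandardScaler semantics; columns
# with near-zero variance become all-zero, never NaN.
#' @keywords internal
standardize_cols <- function(x, eps = 1e-12) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  cen <- sweep(x, 2, mu, "-")
  sdv <- sqrt(colSums(cen^2) / n)
  ok <- sdv > eps
  cen[, ok] <- sweep(cen[, ok, drop = FALSE], 2, sdv[ok], "/")
  cen[, !ok] <- 0
  cen
}

#' @keywords internal
binarize <- function(m) {
  m <- .as_dgc(Matrix::drop0(m))
  m@x[] <- 1
  m
}

# Dense cosine-similarity top-k search, chunked over query rows.
# Returns a sparse nq x nr matrix with the k best matches per query row,
# negative similarities clipped at zero.
#' @keywords internal
cosine_knn <- function(query, ref, k, chunk = 1024L) {
  nq <- nrow(query); nr <- nrow(ref)
  if (nr < k) {
    warning(sprintf("reference has only %d rows < k = %d; keeping all", nr, k))
    k <- nr
  }
  qn <- row_l2_normalize(as.matrix(query))
  rn <- row_l2_normalize(as.matrix(ref))
  ii <- vector("list", 0L); jj <- vector("list", 0L); xx <- vector("list", 0L)
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nq)
    sim <- qn[rows, , drop = FALSE] %*% t(rn)
    sim[sim < 0] <- 0
    for (r in seq_along(rows)) {
      s <- sim[r, ]
      ord <- order(-s, seq_len(nr))[seq_len(k)]
      ii[[length(ii) + 1L]] <- rep.int(rows[r], k)
      jj[[length(jj) + 1L]] <- ord
      xx[[length(xx) + 1L]] <- s[ord]
    }
  }
  Matrix::drop0(Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(nq, nr)
  ))
}

#' @keywords internal
block_matrix <- function(tl, tr, bl, br) {
  .as_dgc(rbind(
    cbind(.as_dgc(tl), .as_dgc(tr)),
    cbind(.as_dgc(bl), .as_dgc(br))
  ))
}
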