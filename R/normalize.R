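#' Per-cell normalization of UMI counts
#'
#' Divides each cell's counts by its total UMI count and multiplies by a
#' scale factor (default 1000), so every non-empty cell row sums to the
#' scale factor. All-zero cells stay all-zero.
#'
#' @param m a \code{\link{cell_matrix}}.
#' @param scale_factor positive scalar, default 1000.
#' @return An object of class \code{normalized_matrix}: list with sparse
#'   \code{values} (cells x genes), \code{scale_factor},
#'   \code{log_transformed}, \code{pseudocount}, \code{species}.
#' @export
normalize_counts <- function(m, scale_factor = 1000) {
  stopifnot(inherits(m, "cell_matrix"))
  if (length(scale_factor) != 1 || !is.finite(scale_factor) ||
      scale_factor <= 0)
    stop("scale_factor must be a positive number", call. = FALSE)
  totals <- Matrix::rowSums(m$counts)
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  values <- Matrix::Diagonal(x = inv) %*% m$counts
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(m$counts)
  structure(list(values = values, scale_factor = scale_factor,
                 log_transformed = FALSE, pseudocount = NA_real_,
                 species = m$species),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "<normalized_matrix> %d cells x %d genes, scale %g%s\n",
    nrow(x$values), ncol(x$values), x$scale_factor,
    if (x$log_transformed) sprintf(", log2(x + %g)", x$pseudocount) else ""))
  invisible(x)
}

#' Log2-transform a normalized matrix
#'
#' Applies \code{v -> log2(v + pseudocount)} entry-wise; with the default
#' pseudocount of 1 zeros map to zero and sparsity is preserved.
#'
#' @param nm a \code{normalized_matrix} that is not yet log-transformed.
#' @param pseudocount positive scalar added before taking log2.
#' @return The transformed \code{normalized_matrix}.
#' @export
log_transform <- function(nm, pseudocount = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (isTRUE(nm$log_transformed))
    stop("matrix is already log-transformed", call. = FALSE)
  if (length(pseudocount) != 1 || !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a positive number", call. = FALSE)
  if (pseudocount == 1) {
    nm$values@x <- log2(nm$values@x + 1)
  } else {
    dense <- log2(as.matrix(nm$values) + pseudocount)
    nm$values <- methods::as(Matrix::Matrix(dense, sparse = TRUE),
                             "CsparseMatrix")
  }
  nm$log_transformed <- TRUE
  nm$pseudocount <- pseudocount
  nm
}
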