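#' Gaussian-kernel local transcript abundance
#'
#' For each gene, the local abundance at a cell is the kernel-weighted
#' average of the normalized counts of all cells (self included), with
#' Gaussian weights on Euclidean distances in a low-dimensional space
#' (typically the top 10 principal components):
#' \code{L_ic = sum_j K(||x_c - x_j|| / h) v_ij / sum_j K(.)}.
#' Each smoothed value is a convex combination of observed values.
#'
#' @param nm a \code{normalized_matrix} (cells x genes).
#' @param coords numeric cells x d matrix of finite coordinates aligned
#'   with the rows of \code{nm}.
#' @param bandwidth positive kernel bandwidth h; default is the median over
#'   cells of the distance to the 30th nearest neighbour (a scale that
#'   adapts to embedding density).
#' @param genes optional gene subset (ids or indices).
#' @return A list with \code{L} (cells x genes smoothed matrix),
#'   \code{bandwidth}.
#' @export
local_abundance <- function(nm, coords, bandwidth = NULL, genes = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  coords <- as.matrix(coords)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  if (nrow(coords) != nrow(nm$values))
    stop("coordinate rows must align with cells", call. = FALSE)
  v <- nm$values
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  v <- as.matrix(v)
  d <- as.matrix(stats::dist(coords))
  if (is.null(bandwidth)) bandwidth <- default_knn_bandwidth(d)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  w <- exp(-0.5 * (d / bandwidth)^2)
  L <- (w %*% v) / rowSums(w)
  dimnames(L) <- dimnames(v)
  list(L = L, bandwidth = bandwidth)
}

# Median distance to the k-th nearest neighbour (excluding self).
default_knn_bandwidth <- function(dist_matrix, k = 30) {
  n <- nrow(dist_matrix)
  k <- min(k, n - 1)
  kth <- apply(dist_matrix, 1, function(row) sort(row)[k + 1])
  h <- stats::median(kth)
  if (!is.finite(h) || h <= 0) 1 else h
}

#' Mean relative abundance of a gene set per cell
#'
#' Smooths each gene of the set with \code{\link{local_abundance}}, divides
#' by the gene's mean local abundance over cells (so each gene's relative
#' abundance r_ic averages to exactly 1), and averages over the set. Genes
#' absent from the matrix are reported; duplicated ids are deduplicated
#' with a warning. Genes whose local abundance is identically zero have no
#' defined relative abundance and are dropped from the set mean.
#'
#' @param nm a \code{normalized_matrix}.
#' @param coords cells x d coordinate matrix (see
#'   \code{\link{local_abundance}}).
#' @param gene_set character vector of gene ids.
#' @param bandwidth kernel bandwidth (default as in
#'   \code{\link{local_abundance}}).
#' @return An object of class \code{gene_set_score}: list with
#'   \code{score} (per-cell mean relative abundance), \code{r} (cells x
#'   set-genes relative abundances), \code{bandwidth},
#'   \code{missing_genes}.
#' @export
geneset_relative_abundance <- function(nm, coords, gene_set,
                                       bandwidth = NULL) {
  gene_set <- as.character(gene_set)
  if (anyDuplicated(gene_set)) {
    warning("duplicated genes in the set were deduplicated", call. = FALSE)
    gene_set <- unique(gene_set)
  }
  present <- intersect(gene_set, colnames(nm$values))
  if (length(present) == 0)
    stop("no genes of the set are present in the matrix", call. = FALSE)
  la <- local_abundance(nm, coords, bandwidth, genes = present)
  means <- colMeans(la$L)
  usable <- means > 0
  r <- sweep(la$L[, usable, drop = FALSE], 2, means[usable], "/")
  structure(list(score = rowMeans(r), r = r, bandwidth = la$bandwidth,
                 missing_genes = setdiff(gene_set, present)),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("<gene_set_score> %d cells, %d set genes (h = %.3g)%s\n",
              length(x$score), ncol(x$r), x$bandwidth,
              if (length(x$missing_genes))
                sprintf(", %d missing", length(x$missing_genes)) else ""))
  invisible(x)
}

#' Nadaraya-Watson kernel regression
#'
#' Gaussian-kernel regression of a response on pseudotime:
#' \code{yhat(q) = sum_j K((q - t_j)/h) y_j / sum_j K(.)}. Queries where
#' every kernel weight underflows fall back to the nearest observation,
#' with a warning.
#'
#' @param pseudotime numeric explanatory vector (>= 2 observations).
#' @param values numeric response vector, same length.
#' @param query numeric vector of evaluation points.
#' @param bandwidth positive bandwidth; default Silverman's rule of thumb
#'   on the pseudotime values.
#' @return Numeric vector of fitted values at \code{query}.
#' @export
nw_regression <- function(pseudotime, values, query, bandwidth = NULL) {
  if (length(pseudotime) < 2)
    stop("need at least 2 observations", call. = FALSE)
  if (length(pseudotime) != length(values))
    stop("pseudotime and values must have equal length", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(pseudotime)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  w <- stats::dnorm(outer(query, pseudotime, "-") / bandwidth)
  tot <- rowSums(w)
  fit <- drop(w %*% values) / tot
  dead <- tot == 0 | !is.finite(fit)
  if (any(dead)) {
    warning("kernel weights underflowed at some queries; ",
            "nearest-neighbour fallback used", call. = FALSE)
    nearest <- vapply(query[dead],
                      function(q) values[which.min(abs(pseudotime - q))],
                      numeric(1))
    fit[dead] <- nearest
  }
  fit
}

#' Sliding-window expression profiles along pseudotime
#'
#' Orders cells by pseudotime (ties broken by original cell order) and
#' computes, per feature, the moving average over windows of \code{window}
#' cells slid one cell at a time; the union of the window means is the
#' profile. The per-feature maximum and mean over the lineage are emitted
#' alongside for display rescaling.
#'
#' @param values cells x features matrix (e.g. normalized ortholog
#'   abundance restricted to one lineage's cells).
#' @param pseudotime numeric vector, one value per cell.
#' @param window window size in cells (default 21).
#' @return An object of class \code{lineage_profile}: list with
#'   \code{profiles} ((n - window + 1) x features matrix of window means),
#'   \code{order} (cell ordering used), \code{window}, \code{feature_max},
#'   \code{feature_mean}.
#' @export
moving_average_profiles <- function(values, pseudotime, window = 21) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(pseudotime) != n)
    stop("one pseudotime per cell required", call. = FALSE)
  if (window < 1 || window > n)
    stop("window must be between 1 and the number of cells", call. = FALSE)
  ord <- order(pseudotime)  # stable: ties keep original cell order
  v <- values[ord, , drop = FALSE]
  cs <- apply(v, 2, cumsum)
  cs <- rbind(0, cs)
  idx <- seq_len(n - window + 1)
  prof <- (cs[idx + window, , drop = FALSE] - cs[idx, , drop = FALSE]) /
    window
  rownames(prof) <- NULL
  structure(list(profiles = prof, order = ord, window = window,
                 feature_max = apply(v, 2, max),
                 feature_mean = colMeans(v)),
            class = "lineage_profile")
}

#' @export
print.lineage_profile <- function(x, ...) {
  cat(sprintf("<lineage_profile> %d windows (size %d) x %d features\n",
              nrow(x$profiles), x$window, ncol(x$profiles)))
  invisible(x)
}
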