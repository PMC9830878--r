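#' Construct a single-cell UMI count matrix
#'
#' The basic container of the pipeline: a sparse cells x genes matrix of
#' unique molecular identifier (UMI) counts with a species tag. Counts must
#' be non-negative integers; cell and gene identifiers must be unique.
#' Identifiers are case-sensitive and never normalized; the species tag is
#' supplied by the caller, never inferred from identifiers.
#'
#' @param counts cells x genes matrix-like of non-negative integer counts
#'   (coerced to a sparse \code{dgCMatrix}).
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param species single string tagging the source species.
#' @param batch optional single string tagging the batch.
#' @return An object of class \code{cell_matrix}.
#' @export
cell_matrix <- function(counts, cell_ids = rownames(counts),
                        gene_ids = colnames(counts), species = "unknown",
                        batch = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required", call. = FALSE)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop("count matrix dimensions do not match id lists", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicated cell_ids", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene_ids", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers", call. = FALSE)
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, species = as.character(species)[1],
                 batch = batch),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, species '%s'%s\n",
              nrow(x$counts), ncol(x$counts), x$species,
              if (is.null(x$batch)) "" else sprintf(", batch '%s'", x$batch)))
  invisible(x)
}

#' @rdname cell_matrix
#' @param m a \code{cell_matrix}.
#' @export
n_cells <- function(m) nrow(m$counts)

#' @rdname cell_matrix
#' @export
n_genes <- function(m) ncol(m$counts)

#' @rdname cell_matrix
#' @export
cell_ids <- function(m) rownames(m$counts)

#' @rdname cell_matrix
#' @export
gene_ids <- function(m) colnames(m$counts)

#' Remove low-coverage cells
#'
#' Retains cells whose total UMI count is at least \code{min_umi}
#' (inclusive threshold). The gene set and the cell order are preserved.
#' The default of 500 is the conventional droplet (10x) cutoff; plate-based
#' assays typically use 100.
#'
#' @param m a \code{cell_matrix}.
#' @param min_umi positive integer; minimum total UMI per retained cell.
#' @return A filtered \code{cell_matrix}. If no cell passes, an empty matrix
#'   is returned with a warning.
#' @export
filter_cells <- function(m, min_umi = 500) {
  stopifnot(inherits(m, "cell_matrix"))
  if (length(min_umi) != 1 || is.na(min_umi) || min_umi < 1)
    stop("min_umi must be a positive integer", call. = FALSE)
  totals <- Matrix::rowSums(m$counts)
  keep <- totals >= min_umi
  if (!any(keep))
    warning("no cells pass the UMI threshold; returning an empty matrix",
            call. = FALSE)
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}

#' Construct a labeled low-dimensional embedding
#'
#' Per-cell coordinates (2D UMAP-like or top-PC space) with species and
#' cluster labels, used by the overlap statistic and the kernel smoothers.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param coordinates numeric matrix (cells x d) of finite coordinates.
#' @param species character vector (length 1 or n cells) of species labels.
#' @param cluster optional character vector of cluster labels.
#' @return An object of class \code{labeled_embedding}.
#' @export
labeled_embedding <- function(cell_ids, coordinates, species, cluster = NULL) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  cell_ids <- as.character(cell_ids)
  if (nrow(coordinates) != length(cell_ids))
    stop("coordinate rows must align 1:1 with cell_ids", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicated cell_ids", call. = FALSE)
  if (!all(is.finite(coordinates)))
    stop("all coordinates must be finite", call. = FALSE)
  species <- rep_len(as.character(species), length(cell_ids))
  if (!is.null(cluster)) cluster <- rep_len(as.character(cluster),
                                            length(cell_ids))
  rownames(coordinates) <- cell_ids
  structure(list(cell_ids = cell_ids, coordinates = coordinates,
                 species = species, cluster = cluster),
            class = "labeled_embedding")
}

#' @export
print.labeled_embedding <- function(x, ...) {
  cat(sprintf("<labeled_embedding> %d cells, %d dims, species: %s\n",
              length(x$cell_ids), ncol(x$coordinates),
              paste(unique(x$species), collapse = ", ")))
  invisible(x)
}

#' Construct an LCM bulk cell-type profile
#'
#' Laser capture microdissection (LCM) bulk RNA-seq profiles: a genes x
#' replicates TPM table per morphologically identified cell type, plus the
#' per-type mean TPM used for all downstream comparisons.
#'
#' @param tpm numeric genes x replicates matrix of TPM values (>= 0) with
#'   gene ids as row names.
#' @param cell_type character vector, one entry per replicate column, naming
#'   the cell type each replicate belongs to.
#' @return An object of class \code{lcm_profile} with elements \code{tpm},
#'   \code{cell_type} (per replicate), \code{types}, \code{mean_tpm}
#'   (genes x types).
#' @export
lcm_profile <- function(tpm, cell_type) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm needs gene row names", call. = FALSE)
  if (ncol(tpm) != length(cell_type))
    stop("one cell_type per replicate column required", call. = FALSE)
  if (any(tpm < 0) || !all(is.finite(tpm)))
    stop("TPM values must be finite and non-negative", call. = FALSE)
  cell_type <- as.character(cell_type)
  types <- unique(cell_type)
  mean_tpm <- vapply(types, function(ct)
    rowMeans(tpm[, cell_type == ct, drop = FALSE]), numeric(nrow(tpm)))
  dimnames(mean_tpm) <- list(rownames(tpm), types)
  structure(list(tpm = tpm, cell_type = cell_type, types = types,
                 mean_tpm = mean_tpm),
            class = "lcm_profile")
}

#' @export
print.lcm_profile <- function(x, ...) {
  cat(sprintf("<lcm_profile> %d genes, %d replicates, types: %s\n",
              nrow(x$tpm), ncol(x$tpm), paste(x$types, collapse = ", ")))
  invisible(x)
}
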