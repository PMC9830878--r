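#' Correlate single cells with LCM bulk cell types
#'
#' Pearson correlation between each cell's normalized UMI vector and each
#' LCM cell type's mean TPM vector, computed over the genes shared by the
#' two datasets. By default both vectors enter on the linear scale
#' (normalized UMI vs mean TPM); set \code{log_space = TRUE} to correlate
#' \code{log2(x + 1)} values instead.
#'
#' @param nm a \code{\link{normalize_counts}} result (not log-transformed
#'   unless \code{log_space}).
#' @param lcm an \code{\link{lcm_profile}}.
#' @param log_space correlate on log2(x + 1) scale (default FALSE).
#' @return An object of class \code{cell_type_correlation}: list with
#'   \code{r} (cells x types Pearson matrix, NaN rows flagged),
#'   \code{shared_genes}, \code{constant_cells} (cell ids with zero
#'   variance over shared genes).
#' @export
correlate_cells_to_types <- function(nm, lcm, log_space = FALSE) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(lcm, "lcm_profile"))
  shared <- intersect(colnames(nm$values), rownames(lcm$mean_tpm))
  if (length(shared) == 0)
    stop("no shared genes between the two datasets", call. = FALSE)
  if (length(shared) < 3)
    stop("fewer than 3 shared genes; correlation is meaningless",
         call. = FALSE)
  x <- as.matrix(nm$values[, shared, drop = FALSE])
  y <- lcm$mean_tpm[shared, , drop = FALSE]
  if (log_space) {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  sds <- apply(x, 1, stats::sd)
  constant <- rownames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(t(x), y))  # cells x types
  structure(list(r = r, shared_genes = shared, constant_cells = constant),
            class = "cell_type_correlation")
}

#' @export
print.cell_type_correlation <- function(x, ...) {
  cat(sprintf("<cell_type_correlation> %d cells x %d types, %d shared genes\n",
              nrow(x$r), ncol(x$r), length(x$shared_genes)))
  invisible(x)
}

#' Annotate clusters by their best-correlated LCM cell type
#'
#' Averages per-cell correlations within each cluster and assigns the cell
#' type with the highest mean correlation. Exact ties are broken by the
#' declared column order of the correlation matrix and flagged. A cluster
#' with no defined correlations is annotated "undetermined".
#'
#' @param corr a \code{\link{correlate_cells_to_types}} result.
#' @param clusters cluster label per cell (aligned with the rows of
#'   \code{corr$r}).
#' @return A data.frame with one row per cluster: \code{cluster},
#'   \code{cell_type}, \code{mean_r} (of the winning type), \code{tie},
#'   plus one \code{mean_r_<type>} column per type.
#' @export
annotate_clusters <- function(corr, clusters) {
  stopifnot(inherits(corr, "cell_type_correlation"))
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(corr$r))
    stop("one cluster label per cell required", call. = FALSE)
  labs <- sort(unique(clusters))
  types <- colnames(corr$r)
  rows <- lapply(labs, function(lab) {
    sub <- corr$r[clusters == lab, , drop = FALSE]
    mean_r <- colMeans(sub, na.rm = TRUE)
    if (all(!is.finite(mean_r))) {
      return(data.frame(cluster = lab, cell_type = "undetermined",
                        mean_r = NA_real_, tie = FALSE,
                        t(stats::setNames(mean_r, paste0("mean_r_", types))),
                        stringsAsFactors = FALSE))
    }
    best <- which(mean_r == max(mean_r, na.rm = TRUE))
    data.frame(cluster = lab, cell_type = types[best[1]],
               mean_r = mean_r[best[1]], tie = length(best) > 1,
               t(stats::setNames(mean_r, paste0("mean_r_", types))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes upregulated in one LCM cell type over all others
#'
#' A gene belongs to the focal type's up set iff its mean TPM in the focal
#' type exceeds \code{min_tpm} and its log2 fold-change (on mean TPM with a
#' pseudocount) against every other cell type is at least \code{min_lfc}.
#' When an externally computed adjusted p-value per gene is supplied (e.g.
#' from a bulk differential analysis), genes with adjusted p >= 0.05 are
#' additionally removed.
#'
#' @param lcm an \code{\link{lcm_profile}} with at least 3 cell types.
#' @param focal name of the focal cell type.
#' @param min_tpm mean-TPM floor for the focal type (default 4).
#' @param min_lfc minimum log2 fold-change against each other type
#'   (default 1).
#' @param pseudocount pseudocount for the TPM fold-change (default 1).
#' @param adj_p optional named numeric vector of adjusted p-values by gene.
#' @return An object of class \code{lcm_up_set}: list with \code{genes},
#'   \code{focal}, \code{min_tpm}, \code{min_lfc}, and per-contrast log2FC
#'   matrix \code{lfc}.
#' @export
lcm_up_genes <- function(lcm, focal, min_tpm = 4, min_lfc = 1,
                         pseudocount = 1, adj_p = NULL) {
  stopifnot(inherits(lcm, "lcm_profile"))
  if (!focal %in% lcm$types)
    stop(sprintf("cell type '%s' not present", focal), call. = FALSE)
  if (length(lcm$types) < 3)
    stop("at least 3 cell types required", call. = FALSE)
  others <- setdiff(lcm$types, focal)
  mt <- lcm$mean_tpm
  lfc <- vapply(others, function(o)
    log2(mt[, focal] + pseudocount) - log2(mt[, o] + pseudocount),
    numeric(nrow(mt)))
  dimnames(lfc) <- list(rownames(mt), others)
  pass <- mt[, focal] > min_tpm &
    apply(lfc >= min_lfc, 1, all)
  if (!is.null(adj_p)) {
    pv <- adj_p[rownames(mt)]
    pass <- pass & !is.na(pv) & pv < 0.05
  }
  structure(list(genes = rownames(mt)[pass], focal = focal,
                 min_tpm = min_tpm, min_lfc = min_lfc, lfc = lfc),
            class = "lcm_up_set")
}

#' @export
print.lcm_up_set <- function(x, ...) {
  cat(sprintf("<lcm_up_set> %s: %d genes (TPM > %g, log2FC >= %g vs %s)\n",
              x$focal, length(x$genes), x$min_tpm, x$min_lfc,
              paste(colnames(x$lfc), collapse = ", ")))
  invisible(x)
}

#' Intersect cluster up-DEGs with LCM up genes
#'
#' For each annotated cluster, intersects the genes upregulated in the
#' single-cell cluster with the genes upregulated in its matched LCM cell
#' type — the genes supported by both transcriptome assays. Clusters absent
#' from the mapping are skipped with a warning.
#'
#' @param sc_up named list of \code{\link{call_degs}} results (or plain
#'   gene-id vectors) per cluster.
#' @param lcm_up named list of \code{\link{lcm_up_genes}} results (or plain
#'   gene-id vectors) per cell type.
#' @param mapping named character vector: cluster -> cell type.
#' @return Named list (by cluster) of character vectors of shared genes.
#' @export
scup_lcmup_intersect <- function(sc_up, lcm_up, mapping) {
  get_genes <- function(x, up = TRUE) {
    if (inherits(x, "deg_call")) x$up
    else if (inherits(x, "lcm_up_set")) x$genes
    else as.character(x)
  }
  out <- list()
  for (cl in names(sc_up)) {
    if (!cl %in% names(mapping) || is.na(mapping[[cl]])) {
      warning(sprintf("cluster '%s' has no cell-type mapping; skipped", cl),
              call. = FALSE)
      next
    }
    ct <- mapping[[cl]]
    if (!ct %in% names(lcm_up)) {
      warning(sprintf("no LCM up set for type '%s'; cluster '%s' skipped",
                      ct, cl), call. = FALSE)
      next
    }
    out[[cl]] <- intersect(get_genes(sc_up[[cl]]), get_genes(lcm_up[[ct]]))
  }
  out
}
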