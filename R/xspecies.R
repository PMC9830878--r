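#' Aggregate gene counts into ortholog-group counts
#'
#' Sums the counts of all member genes of each ortholog group (all gene
#' copies are summed; no best-copy selection), producing a cells x groups
#' matrix for cross-species comparison. Genes of the matrix's species that
#' are absent from the mapping are dropped and reported.
#'
#' @param m a \code{\link{cell_matrix}} whose \code{species} tag matches the
#'   species labels used in \code{map}.
#' @param map an \code{\link{read_ortholog_groups}} result.
#' @return An object of class \code{c("ortho_matrix", "cell_matrix")} whose
#'   columns are ortholog groups (only groups with at least one member gene
#'   present); attribute \code{unmapped_genes} lists dropped genes.
#' @export
aggregate_orthogroups <- function(m, map) {
  stopifnot(inherits(m, "cell_matrix"), inherits(map, "ortho_group_map"))
  sp <- m$species
  memb <- do.call(rbind, lapply(names(map), function(gid) {
    g <- map[[gid]]
    g <- g[g$species == sp, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    data.frame(group_id = gid, gene_id = g$gene_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(memb) || nrow(memb) == 0)
    stop(sprintf("no genes of species '%s' in the ortholog map", sp),
         call. = FALSE)
  gi <- match(memb$gene_id, gene_ids(m))
  memb <- memb[!is.na(gi), , drop = FALSE]
  gi <- gi[!is.na(gi)]
  if (length(gi) == 0)
    stop("no mapped genes present in the count matrix", call. = FALSE)
  groups <- unique(memb$group_id)
  ind <- Matrix::sparseMatrix(i = gi, j = match(memb$group_id, groups),
                              x = 1, dims = c(n_genes(m), length(groups)))
  agg <- m$counts %*% ind
  agg <- methods::as(agg, "CsparseMatrix")
  dimnames(agg) <- list(cell_ids(m), groups)
  unmapped <- setdiff(gene_ids(m), memb$gene_id)
  structure(list(counts = agg, species = m$species, batch = m$batch),
            class = c("ortho_matrix", "cell_matrix"),
            unmapped_genes = unmapped)
}

#' Cross-species cluster correlation on ortholog profiles
#'
#' Normalizes each species' ortholog counts per cell (total ortholog
#' abundance, scale factor 1000), averages the normalized abundance within
#' each cluster over the ortholog groups shared by the two species, and
#' computes all-against-all Pearson correlations between cluster mean
#' profiles. Clusters named in \code{exclude} or holding fewer than
#' \code{min_cells} cells are dropped and recorded.
#'
#' @param a,b \code{ortho_matrix} objects for the two species.
#' @param clusters_a,clusters_b cluster label per cell of each matrix.
#' @param exclude character vector of cluster names to drop (either species).
#' @param min_cells cluster eligibility threshold (default 5).
#' @param scale_factor per-cell normalization scale (default 1000).
#' @return An object of class \code{cluster_correlation}: list with \code{r}
#'   (A-clusters x B-clusters Pearson matrix), \code{shared_groups},
#'   \code{excluded} (named list per species), \code{n_cells} per cluster.
#' @export
cluster_profile_correlation <- function(a, b, clusters_a, clusters_b,
                                        exclude = character(0),
                                        min_cells = 5, scale_factor = 1000) {
  stopifnot(inherits(a, "ortho_matrix"), inherits(b, "ortho_matrix"))
  shared <- intersect(colnames(a$counts), colnames(b$counts))
  if (length(shared) < 3)
    stop("fewer than 3 shared ortholog groups", call. = FALSE)
  prof <- function(m, clusters) {
    clusters <- as.character(clusters)
    stopifnot(length(clusters) == nrow(m$counts))
    nm <- normalize_counts(m, scale_factor)
    labs <- sort(unique(clusters))
    sizes <- table(clusters)[labs]
    small <- labs[sizes < min_cells]
    keep <- setdiff(setdiff(labs, small), exclude)
    p <- vapply(keep, function(lab)
      Matrix::colMeans(nm$values[clusters == lab, shared, drop = FALSE]),
      numeric(length(shared)))
    list(profiles = p, excluded = union(intersect(labs, exclude), small),
         sizes = sizes)
  }
  pa <- prof(a, clusters_a)
  pb <- prof(b, clusters_b)
  r <- suppressWarnings(stats::cor(pa$profiles, pb$profiles))
  structure(list(r = r, shared_groups = shared,
                 excluded = stats::setNames(list(pa$excluded, pb$excluded),
                                            c(a$species, b$species)),
                 n_cells = list(pa$sizes, pb$sizes)),
            class = "cluster_correlation")
}

#' @export
print.cluster_correlation <- function(x, ...) {
  cat(sprintf(
    "<cluster_correlation> %d x %d clusters on %d shared ortholog groups\n",
    nrow(x$r), ncol(x$r), length(x$shared_groups)))
  invisible(x)
}

#' Best-hit and mutual-best-hit cluster pairs
#'
#' For every cluster of each species, finds the cluster of the other
#' species with the highest Pearson correlation; a pair is a mutual best
#' hit when the two argmaxes are reciprocal. Exact ties are broken by label
#' order and flagged.
#'
#' @param cc a \code{\link{cluster_profile_correlation}} result, or a plain
#'   numeric correlation matrix with dimnames.
#' @return A list with data.frames \code{best_a} (per row cluster),
#'   \code{best_b} (per column cluster), and \code{mutual} (the reciprocal
#'   pairs with their correlation).
#' @export
mutual_best_hits <- function(cc) {
  r <- if (inherits(cc, "cluster_correlation")) cc$r else as.matrix(cc)
  if (nrow(r) == 0 || ncol(r) == 0)
    stop("empty correlation matrix", call. = FALSE)
  argmax1 <- function(v) {
    best <- which(v == max(v, na.rm = TRUE))
    c(idx = unname(best[1]), tie = length(best) > 1)
  }
  ba <- t(apply(r, 1, argmax1))
  bb <- t(apply(r, 2, argmax1))
  best_a <- data.frame(cluster_a = rownames(r),
                       best_b = colnames(r)[ba[, "idx"]],
                       r = r[cbind(seq_len(nrow(r)), ba[, "idx"])],
                       tie = as.logical(ba[, "tie"]),
                       stringsAsFactors = FALSE)
  best_b <- data.frame(cluster_b = colnames(r),
                       best_a = rownames(r)[bb[, "idx"]],
                       r = r[cbind(bb[, "idx"], seq_len(ncol(r)))],
                       tie = as.logical(bb[, "tie"]),
                       stringsAsFactors = FALSE)
  mutual_rows <- which(best_b$best_a[match(best_a$best_b,
                                           best_b$cluster_b)] ==
                         best_a$cluster_a)
  mutual <- best_a[mutual_rows, c("cluster_a", "best_b", "r", "tie")]
  names(mutual)[2] <- "cluster_b"
  rownames(mutual) <- NULL
  list(best_a = best_a, best_b = best_b, mutual = mutual)
}

#' Assign differentially expressed ortholog groups to modules
#'
#' Each cluster's differentially expressed ortholog groups (DEOs) define a
#' module; a DEO appearing in several clusters is assigned to the cluster
#' where its log2 fold-change is largest. Multi-cluster DEOs without
#' fold-change information are flagged unresolved.
#'
#' @param deo named list (by cluster) of either data.frames with columns
#'   \code{group_id} and \code{log2_fc}, or plain group-id vectors (no
#'   fold-change information).
#' @param modules named vector mapping cluster name to module id; defaults
#'   to 1..n in list order.
#' @return A data.frame with \code{group_id}, \code{cluster},
#'   \code{module}, \code{unresolved}.
#' @export
assign_deo_modules <- function(deo, modules = NULL) {
  if (is.null(names(deo))) stop("deo list must be named by cluster",
                                call. = FALSE)
  if (is.null(modules))
    modules <- stats::setNames(seq_along(deo), names(deo))
  if (!all(names(deo) %in% names(modules)))
    stop("every cluster needs a module id", call. = FALSE)
  long <- do.call(rbind, lapply(names(deo), function(cl) {
    x <- deo[[cl]]
    if (is.data.frame(x)) {
      data.frame(group_id = as.character(x$group_id), cluster = cl,
                 log2_fc = as.numeric(x$log2_fc), stringsAsFactors = FALSE)
    } else {
      data.frame(group_id = as.character(x), cluster = cl,
                 log2_fc = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  if (is.null(long) || nrow(long) == 0)
    return(data.frame(group_id = character(0), cluster = character(0),
                      module = integer(0), unresolved = logical(0)))
  out <- do.call(rbind, lapply(split(long, long$group_id), function(d) {
    if (nrow(d) == 1) {
      pick <- 1
      unresolved <- FALSE
    } else if (all(is.na(d$log2_fc))) {
      pick <- 1
      unresolved <- TRUE
    } else {
      pick <- which.max(d$log2_fc)
      unresolved <- FALSE
    }
    data.frame(group_id = d$group_id[pick], cluster = d$cluster[pick],
               module = modules[[d$cluster[pick]]],
               unresolved = unresolved, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
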