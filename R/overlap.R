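#' Configuration for the distribution-overlap statistic
#'
#' @param n_bins number of equal-width density bins on [0, 1] (default 500;
#'   the lowest bin is [0, 1/n_bins)).
#' @param mode \code{"self"} rescales densities by the pair's own maximum;
#'   \code{"reference"} divides by supplied scale constants from a
#'   designated reference pair so several pairs share one scale.
#' @param ref_scale list with elements \code{Z} and \code{max} (from the
#'   \code{scale} element of a reference pair's result); required when
#'   \code{mode = "reference"}.
#' @param reference_species species whose cells define the normalization
#'   total Z; defaults to the first species appearing in the embedding.
#' @param grid_size grid resolution per axis for exported density maps
#'   (default 250).
#' @param margin fractional margin added around the data range for the grid
#'   (default 0.05).
#' @return A list of class \code{overlap_config}.
#' @export
overlap_config <- function(n_bins = 500, mode = c("self", "reference"),
                           ref_scale = NULL, reference_species = NULL,
                           grid_size = 250, margin = 0.05) {
  mode <- match.arg(mode)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (mode == "reference" &&
      (is.null(ref_scale) || !all(c("Z", "max") %in% names(ref_scale))))
    stop("reference mode needs ref_scale = list(Z =, max =)", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), mode = mode,
                 ref_scale = ref_scale,
                 reference_species = reference_species,
                 grid_size = as.integer(grid_size), margin = margin),
            class = "overlap_config")
}

#' Euclidean minimum spanning tree of a point set
#'
#' Builds the MST of the complete Euclidean graph (Prim's algorithm on the
#' distance matrix via \code{vegan::spantree}); deterministic for a fixed
#' input order. Duplicate coordinates are legal (zero-weight edges).
#'
#' @param points numeric n x d matrix of finite coordinates, n >= 2.
#' @return A data.frame with columns \code{from}, \code{to} (1-based node
#'   indices) and \code{weight}; n - 1 rows.
#' @export
build_mst <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  if (!all(is.finite(points))) stop("coordinates must be finite",
                                    call. = FALSE)
  tr <- vegan::spantree(stats::dist(points))
  data.frame(from = 2:nrow(points), to = tr$kid, weight = tr$dist)
}

#' Split an MST into single-species subgraphs
#'
#' Deletes every tree edge whose endpoints carry different labels; the
#' remaining forest's components are the subgraphs. On a tree,
#' #components = #deleted edges + 1, always. A single-label tree is one
#' component with zero deletions; more than two labels is an error
#' (overlap is a pairwise comparison).
#'
#' @param mst edge list from \code{\link{build_mst}}.
#' @param labels per-node label vector with at most two distinct values.
#' @return A list with \code{membership} (component id per node),
#'   \code{n_components}, \code{removed} (deleted cross-label edge count),
#'   \code{kept} (edge list of the forest).
#' @export
split_subgraphs <- function(mst, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (length(unique(labels)) > 2)
    stop("at most two labels are supported", call. = FALSE)
  cross <- labels[mst$from] != labels[mst$to]
  kept <- mst[!cross, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  list(membership = comp$membership[as.character(seq_len(n))],
       n_components = comp$no, removed = sum(cross), kept = kept)
}

#' Center node of each subgraph by closeness centrality
#'
#' Within each component, the center is the node with the highest closeness
#' centrality under tree-path distances (edge weights = Euclidean lengths),
#' i.e. the node minimizing the summed path distance to all other nodes of
#' its component. Singleton components are their own center. Ties go to the
#' lowest node index and are flagged.
#'
#' @param sub result of \code{\link{split_subgraphs}}.
#' @param mst edge list from \code{\link{build_mst}} (for edge weights).
#' @return A data.frame with one row per component: \code{component},
#'   \code{center} (node index), \code{size}, \code{tie}.
#' @export
component_centers <- function(sub, mst) {
  n <- length(sub$membership)
  kept <- sub$kept
  g <- igraph::graph_from_data_frame(
    kept[c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- kept$weight
  comps <- split(seq_len(n), sub$membership)
  rows <- lapply(names(comps), function(cid) {
    nodes <- comps[[cid]]
    if (length(nodes) == 1)
      return(data.frame(component = as.integer(cid), center = nodes,
                        size = 1L, tie = FALSE))
    sg <- igraph::induced_subgraph(g, nodes)
    d <- igraph::distances(sg, weights = igraph::E(sg)$weight)
    tot <- rowSums(d)
    best <- which(tot == min(tot))
    data.frame(component = as.integer(cid),
               center = nodes[min(best)], size = length(nodes),
               tie = length(best) > 1)
  })
  out <- do.call(rbind, rows)
  out[order(out$component), , drop = FALSE]
}

# Robust spread estimate for the normal-reference rule: min(sd, IQR/1.349).
# NA when degenerate (fewer than 2 points or zero spread).
nr_spread <- function(v) {
  if (length(v) < 2) return(NA_real_)
  s <- min(stats::sd(v), stats::IQR(v) / 1.349)
  if (!is.finite(s) || s <= 0) NA_real_ else s
}

# Normal-reference bandwidth per axis: 1.06 * min(sd, IQR/1.349) * m^(-1/5),
# with m the KDE sample size.
nr_bandwidth <- function(v) {
  s <- nr_spread(v)
  1.06 * s * length(v)^(-1 / 5)
}

# Product-Gaussian KDE from centers, evaluated at points (chunked to bound
# memory). Integrates to 1 over the plane.
kde_eval <- function(centers, bw, at, chunk = 1024L) {
  m <- nrow(centers)
  out <- numeric(nrow(at))
  for (start in seq(1, nrow(at), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(at))
    kx <- stats::dnorm(outer(at[idx, 1], centers[, 1], "-") / bw[1]) / bw[1]
    ky <- stats::dnorm(outer(at[idx, 2], centers[, 2], "-") / bw[2]) / bw[2]
    out[idx] <- rowSums(kx * ky) / m
  }
  out
}

#' Weighted center-node density fields on a grid
#'
#' Computes each species' product-Gaussian kernel density from its subgraph
#' center nodes (normal-reference bandwidth per axis, with a fallback to a
#' bandwidth computed from all of that species' cells when the center set
#' is degenerate), weights it by the number of center nodes times the
#' species' cell proportion, and sums the two weighted fields into the
#' combined map D.
#'
#' @param centers named list (by species) of center coordinate matrices
#'   (k x 2).
#' @param n_cells named vector of cell counts per species.
#' @param config an \code{\link{overlap_config}} (grid settings).
#' @param all_points optional named list of each species' full cell
#'   coordinates, used for the bandwidth fallback.
#' @return A list with \code{x}, \code{y} (grid axes), \code{w} (named list
#'   of weighted per-species density matrices), \code{D} (their sum),
#'   \code{bandwidth} (named list), \code{weight} (named vector
#'   m_S * n_S / n).
#' @export
weighted_density_map <- function(centers, n_cells, config = overlap_config(),
                                 all_points = NULL) {
  species <- names(centers)
  stopifnot(!is.null(species), all(species %in% names(n_cells)))
  bws <- lapply(stats::setNames(species, species), function(sp)
    species_bandwidth(centers[[sp]],
                      if (!is.null(all_points)) all_points[[sp]] else NULL))
  pts <- do.call(rbind, centers)
  rng <- apply(pts, 2, range)
  # pad by the larger of the fractional margin and 4 bandwidths so the
  # kernel mass is held on the grid
  max_bw <- apply(do.call(rbind, bws), 2, max)
  pad <- pmax(config$margin * (rng[2, ] - rng[1, ]), 4 * max_bw,
              .Machine$double.eps)
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1],
            length.out = config$grid_size)
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2],
            length.out = config$grid_size)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  n_tot <- sum(n_cells[species])
  w <- list()
  wt <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    f <- kde_eval(centers[[sp]], bws[[sp]], grid)
    wt[sp] <- nrow(centers[[sp]]) * n_cells[[sp]] / n_tot
    w[[sp]] <- matrix(wt[sp] * f, nrow = length(gx))
  }
  list(x = gx, y = gy, w = w, D = Reduce(`+`, w), bandwidth = bws,
       weight = wt)
}

# Bandwidth for one species' center set. When the center set is degenerate
# (a single center, or zero spread), the spread estimate is borrowed from
# all cells of the species while the m^(-1/5) factor keeps the center count
# as the KDE sample size.
species_bandwidth <- function(centers, fallback_points = NULL) {
  m <- max(nrow(centers), 1)
  spread <- c(nr_spread(centers[, 1]), nr_spread(centers[, 2]))
  if (any(!is.finite(spread))) {
    if (!is.null(fallback_points)) {
      fb <- c(nr_spread(fallback_points[, 1]),
              nr_spread(fallback_points[, 2]))
      spread[!is.finite(spread)] <- fb[!is.finite(spread)]
      warning("degenerate center set; bandwidth fallback engaged",
              call. = FALSE)
    }
    spread[!is.finite(spread)] <- 1
  }
  1.06 * spread * m^(-1 / 5)
}

#' Distribution overlap between two labeled point clouds
#'
#' The full overlap pipeline: Euclidean MST of the integrated embedding,
#' removal of cross-species edges, closeness-centrality center per
#' subgraph, weighted kernel density of center nodes per species summed
#' into a combined field D, evaluation of D at every cell, normalization by
#' the total over the reference species' cells, rescaling to [0, 1] (by the
#' pair's own maximum in \code{self} mode, or by supplied reference
#' constants in \code{reference} mode), binning into \code{n_bins}
#' equal-width bins, and the overlap O = 1 - (proportion in the lowest
#' bin) — the fraction of cells outside the near-zero-density bin where the
#' two species barely co-localize.
#'
#' The removed-edge count k is the classic multivariate-runs interdigitation
#' count (for identical distributions its expectation is about
#' 2 n_A n_B / n), and #subgraphs = k + 1 exactly.
#'
#' @param embedding a \code{\link{labeled_embedding}} with exactly two
#'   species, 2D coordinates, and at least 2 cells per species.
#' @param config an \code{\link{overlap_config}}.
#' @return An object of class \code{overlap_result}: list with
#'   \code{edges}, \code{removed} (k), \code{membership}, \code{centers}
#'   (data.frame), \code{m} (center count per species), \code{density}
#'   (per-cell D), \code{v} (per-cell rescaled density in [0, 1]), \code{Z},
#'   \code{scale} (list(Z, max) for reuse as reference constants),
#'   \code{bins} (proportions p_1..p_n), \code{overlap} (fraction),
#'   \code{overlap_pct}, \code{reference_species}, \code{config}.
#' @export
overlap_statistic <- function(embedding, config = overlap_config()) {
  stopifnot(inherits(embedding, "labeled_embedding"))
  coords <- embedding$coordinates[, 1:2, drop = FALSE]
  labels <- embedding$species
  species <- unique(labels)
  if (length(species) != 2)
    stop("overlap requires exactly two species", call. = FALSE)
  if (any(table(labels) < 2))
    stop("each species needs at least 2 cells", call. = FALSE)

  mst <- build_mst(coords)
  sub <- split_subgraphs(mst, labels)
  centers <- component_centers(sub, mst)
  centers$species <- labels[centers$center]

  ref <- config$reference_species
  if (is.null(ref)) ref <- species[1]
  if (!ref %in% species)
    stop("reference species not present in the embedding", call. = FALSE)

  n_cells_sp <- stats::setNames(
    as.numeric(table(labels)[species]), species)
  n_tot <- sum(n_cells_sp)
  D <- numeric(nrow(coords))
  m_sp <- stats::setNames(integer(length(species)), species)
  bws <- list()
  for (sp in species) {
    ctr_idx <- centers$center[centers$species == sp]
    m_sp[sp] <- length(ctr_idx)
    ctr <- coords[ctr_idx, , drop = FALSE]
    bw <- species_bandwidth(ctr, coords[labels == sp, , drop = FALSE])
    bws[[sp]] <- bw
    f <- kde_eval(ctr, bw, coords)
    D <- D + m_sp[sp] * (n_cells_sp[sp] / n_tot) * f
  }

  Z <- sum(D[labels == ref])
  if (Z <= 0) stop("reference-species density total is zero", call. = FALSE)
  v <- D / Z
  own_max <- max(v)
  if (config$mode == "self") {
    v01 <- v / own_max
  } else {
    v01 <- (D / config$ref_scale$Z) / config$ref_scale$max
    v01 <- pmin(pmax(v01, 0), 1)
  }
  nb <- config$n_bins
  idx <- pmin(floor(v01 * nb) + 1L, nb)
  p <- tabulate(idx, nbins = nb) / length(idx)
  O <- 1 - p[1]

  structure(list(edges = mst, removed = sub$removed,
                 membership = sub$membership, centers = centers,
                 m = m_sp, density = D, v = v01, Z = Z,
                 scale = list(Z = Z, max = own_max), bins = p,
                 overlap = O, overlap_pct = 100 * O,
                 bandwidth = bws, reference_species = ref, config = config),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("<overlap_result> overlap = %.1f%% (%s mode)\n",
           "  removed cross-species edges k = %d, subgraphs = %d\n",
           "  centers: %s\n"),
    x$overlap_pct, x$config$mode, x$removed, max(x$membership),
    paste(sprintf("%s = %d", names(x$m), x$m), collapse = ", ")))
  invisible(x)
}
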