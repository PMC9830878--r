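#' Configuration for the two-species synthetic generator
#'
#' Defines a pair of wood-forming (stem-differentiating xylem) single-cell
#' datasets sharing a branching lineage: a ray branch (ray organizer ->
#' ray precursor -> ray parenchyma) and a fusiform branch (fusiform
#' organizer -> early -> intermediate precursor -> vessel element, with a
#' libriform-fiber side fate), eight clusters in all. Expression programs
#' are defined per ortholog group and shared between the species; the
#' divergence knob re-randomizes a fraction of the fusiform-branch programs
#' in species B and displaces its fusiform cells in the co-registered
#' embedding.
#'
#' @param seed integer RNG seed; every component draws from a derived
#'   substream so changing one component does not perturb the others.
#' @param n_per_cluster cells per cluster per species (default 120; must be
#'   >= 5 so every cluster is eligible for DEG calling).
#' @param n_orthogroups number of ortholog groups (default 600).
#' @param n_markers_per_cluster planted marker groups per cluster
#'   (default 15).
#' @param marker_fold expression fold of a marker in its home cluster
#'   (default 8).
#' @param copy_range integer range of gene copies per group per species
#'   (default 1..3; copy expression split by Dirichlet weights).
#' @param extra_gene_frac fraction of additional species-specific unmapped
#'   genes (default 0.05).
#' @param dispersion_range range of per-gene NB dispersions (default
#'   0.05..0.3).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters
#'   (default meanlog log(3000), sdlog 0.3).
#' @param divergence epsilon in [0, 1]: fraction of fusiform-program
#'   groups re-randomized in species B (default 0).
#' @param divergence_shift embedding displacement of species B fusiform
#'   cells at epsilon = 1, in embedding units (default 4).
#' @param embedding_noise per-cell Gaussian jitter around the branch curve
#'   (default 0.35).
#' @param lcm_replicates LCM replicates per terminal cell type (default 3).
#' @param lcm_noise_sd log-scale replicate noise of LCM TPM (default 0.15).
#' @param species two species tags (default c("ptr", "egr")).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_per_cluster = 120, n_orthogroups = 600,
                       n_markers_per_cluster = 15, marker_fold = 8,
                       copy_range = c(1, 3), extra_gene_frac = 0.05,
                       dispersion_range = c(0.05, 0.3),
                       libsize_meanlog = log(3000), libsize_sdlog = 0.3,
                       divergence = 0, divergence_shift = 4,
                       embedding_noise = 0.35, lcm_replicates = 3,
                       lcm_noise_sd = 0.15, species = c("ptr", "egr")) {
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]", call. = FALSE)
  if (n_per_cluster < 5)
    stop("n_per_cluster must be >= 5 (DEG eligibility rule)", call. = FALSE)
  if (8 * n_markers_per_cluster >= n_orthogroups)
    stop("too many marker groups for n_orthogroups", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic substream seed (kept below 2^31).
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}

# Cluster topology shared by both species.
sdx_clusters <- function() {
  list(
    names = c("ray_organizer", "ray_precursor", "ray_parenchyma",
              "fus_organizer", "fus_early", "fus_intermediate",
              "vessel_element", "libriform_fiber"),
    branches = list(
      ray = c("ray_organizer", "ray_precursor", "ray_parenchyma"),
      vessel = c("fus_organizer", "fus_early", "fus_intermediate",
                 "vessel_element"),
      fiber = c("fus_organizer", "fus_early", "fus_intermediate",
                "libriform_fiber")),
    fusiform = c("fus_organizer", "fus_early", "fus_intermediate",
                 "vessel_element", "libriform_fiber"),
    terminal = c(libriform_fiber = "libriform_fiber",
                 vessel_element = "vessel_element",
                 ray_parenchyma = "ray_parenchyma"),
    anchors = rbind(
      ray_organizer = c(-0.5, -1.2), ray_precursor = c(-2.5, -1.8),
      ray_parenchyma = c(-4.5, -2.6), fus_organizer = c(0, 0),
      fus_early = c(2, 0.8), fus_intermediate = c(4, 1.2),
      vessel_element = c(6, 2.2), libriform_fiber = c(6, -0.6)))
}

# Ortholog-group expression programs: a baseline per group, a planted
# marker fold in one home cluster for the first 8 * n_markers groups, and a
# smooth logistic ramp along one lineage path for the rest.
make_programs <- function(cfg, topo) {
  G <- cfg$n_orthogroups
  K <- length(topo$names)
  base <- stats::rgamma(G, shape = 2, scale = 1) + 0.2
  P <- matrix(rep(base, K), nrow = G)
  colnames(P) <- topo$names
  home <- rep(NA_character_, G)
  n_mark <- cfg$n_markers_per_cluster
  marker_idx <- seq_len(8 * n_mark)
  home[marker_idx] <- rep(topo$names, each = n_mark)
  P[cbind(marker_idx, match(home[marker_idx], topo$names))] <-
    cfg$marker_fold * base[marker_idx]
  ramp_path <- rep(NA_character_, G)
  for (g in setdiff(seq_len(G), marker_idx)) {
    path_name <- sample(names(topo$branches), 1)
    path <- topo$branches[[path_name]]
    u <- stats::runif(1)
    wdt <- stats::runif(1, 0.1, 0.4)
    amp <- stats::runif(1, 0.5, 3) * sample(c(-0.6, 1), 1)
    x <- seq(0, 1, length.out = length(path))
    mult <- pmax(0.05, 1 + amp * stats::plogis((x - u) / wdt))
    P[g, path] <- base[g] * mult
    ramp_path[g] <- path_name
  }
  list(P = P, base = base, home = home, ramp_path = ramp_path)
}

# Gene copies for one species: each group gets 1..copy_range genes whose
# Dirichlet weights split the group program.
make_copies <- function(cfg, sp, G) {
  n_copies <- sample(seq(cfg$copy_range[1], cfg$copy_range[2]),
                     G, replace = TRUE)
  group <- rep(seq_len(G), n_copies)
  w <- stats::rgamma(length(group), shape = 1.5, scale = 1)
  w <- w / stats::ave(w, group, FUN = sum)
  gene_id <- sprintf("%sG%04dc%d", sp, group,
                     unlist(lapply(n_copies, seq_len)))
  list(group = group, weight = w, gene_id = gene_id)
}

#' Simulate a two-species xylem single-cell dataset with ground truth
#'
#' Generates UMI count matrices for two species sharing the eight-cluster
#' branching lineage, a many-to-one gene-to-ortholog-group map per species,
#' a co-registered 2D embedding plus per-species 10-dimensional PC-like
#' coordinates, per-cell pseudotime, LCM-like bulk TPM profiles of the
#' three terminal cell types (species A), and the full ground truth.
#' Counts are negative binomial with gene-wise dispersion and log-normal
#' library sizes; cell expression interpolates the cluster-node programs
#' along each branch so profiles vary smoothly in pseudotime.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with \code{matrix_a}, \code{matrix_b}
#'   (\code{cell_matrix}), \code{ortho_map}, \code{embedding} (integrated
#'   2D), \code{pcs} (named list of per-species 10-D
#'   \code{labeled_embedding}), \code{clusters} (named list of per-cell
#'   labels), \code{pseudotime} (named list of data.frames cell_id,
#'   lineage, t), \code{lcm} (\code{lcm_profile}), and \code{truth}.
#' @export
simulate_two_species <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  topo <- sdx_clusters()
  K <- length(topo$names)
  G <- cfg$n_orthogroups

  set.seed(sub_seed(cfg$seed, 1))
  prog <- make_programs(cfg, topo)
  P_a <- prog$P
  rownames(P_a) <- sprintf("OG%04d", seq_len(G))

  # Species B: same programs except the re-randomized fusiform fraction.
  set.seed(sub_seed(cfg$seed, 2))
  fus_prog <- which(prog$home %in% topo$fusiform |
                      prog$ramp_path %in% c("vessel", "fiber"))
  n_div <- round(cfg$divergence * length(fus_prog))
  divergent <- sort(sample(fus_prog, n_div))
  P_b <- P_a
  for (g in divergent) {
    perm <- sample(topo$fusiform)
    P_b[g, topo$fusiform] <- P_a[g, perm] *
      exp(stats::rnorm(length(perm), 0, 0.5))
  }

  species_data <- list()
  copies <- list()
  for (si in 1:2) {
    sp <- cfg$species[si]
    P <- if (si == 1) P_a else P_b
    set.seed(sub_seed(cfg$seed, 10 + si))
    cp <- make_copies(cfg, sp, G)
    copies[[sp]] <- cp
    n_extra <- round(cfg$extra_gene_frac * length(cp$gene_id))
    extra_ids <- sprintf("%sX%04d", sp, seq_len(n_extra))
    extra_base <- stats::rgamma(n_extra, shape = 1, scale = 0.5) + 0.05

    # genes x clusters mean matrix
    M <- cp$weight * P[cp$group, , drop = FALSE]
    if (n_extra > 0)
      M <- rbind(M, matrix(rep(extra_base, K), nrow = n_extra))
    rownames(M) <- c(cp$gene_id, extra_ids)

    # cells: n_per_cluster per cluster, interpolated along branches
    cl <- rep(topo$names, each = cfg$n_per_cluster)
    n_cells_sp <- length(cl)
    branch <- character(n_cells_sp)
    seg1 <- integer(n_cells_sp)
    seg2 <- integer(n_cells_sp)
    frac <- numeric(n_cells_sp)
    t_rel <- numeric(n_cells_sp)
    alt <- 0L
    for (i in seq_len(n_cells_sp)) {
      cname <- cl[i]
      if (cname %in% topo$branches$ray) {
        br <- "ray"
      } else if (cname == "vessel_element") {
        br <- "vessel"
      } else if (cname == "libriform_fiber") {
        br <- "fiber"
      } else {
        alt <- alt + 1L
        br <- c("vessel", "fiber")[1 + alt %% 2L]
      }
      path <- topo$branches[[br]]
      pos <- match(cname, path) - 1
      tr <- min(max(pos + stats::runif(1, -0.5, 0.5), 0), length(path) - 1)
      branch[i] <- br
      seg1[i] <- match(path[floor(tr) + 1], topo$names)
      seg2[i] <- match(path[min(floor(tr) + 2, length(path))], topo$names)
      frac[i] <- tr - floor(tr)
      t_rel[i] <- tr / (length(path) - 1)
    }
    W <- Matrix::sparseMatrix(
      i = c(seq_len(n_cells_sp), seq_len(n_cells_sp)),
      j = c(seg1, seg2), x = c(1 - frac, frac),
      dims = c(n_cells_sp, K))
    E <- as.matrix(W %*% t(M))  # cells x genes
    E <- E / rowSums(E)
    lib <- stats::rlnorm(n_cells_sp, cfg$libsize_meanlog, cfg$libsize_sdlog)
    mu <- E * lib
    phi <- stats::runif(ncol(mu), cfg$dispersion_range[1],
                        cfg$dispersion_range[2])
    counts <- matrix(0L, n_cells_sp, ncol(mu))
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- if (phi[j] <= 1e-8) stats::rpois(n_cells_sp, mu[, j])
      else stats::rnbinom(n_cells_sp, mu = mu[, j], size = 1 / phi[j])
    }
    cell_names <- sprintf("%s_c%04d", sp, seq_len(n_cells_sp))
    cm <- cell_matrix(counts, cell_ids = cell_names,
                      gene_ids = rownames(M), species = sp)

    # embedding: branch-curve anchors + jitter; species B fusiform shift
    anchor1 <- topo$anchors[seg1, , drop = FALSE]
    anchor2 <- topo$anchors[seg2, , drop = FALSE]
    xy <- (1 - frac) * anchor1 + frac * anchor2 +
      matrix(stats::rnorm(2 * n_cells_sp, 0, cfg$embedding_noise),
             ncol = 2)
    if (si == 2 && cfg$divergence > 0) {
      fus_cell <- cl %in% topo$fusiform
      depth <- t_rel
      shift <- cfg$divergence * cfg$divergence_shift * depth
      xy[fus_cell, 1] <- xy[fus_cell, 1] + shift[fus_cell] * 0.6
      xy[fus_cell, 2] <- xy[fus_cell, 2] - shift[fus_cell] * 0.8
    }
    pcs <- cbind(xy, matrix(stats::rnorm(8 * n_cells_sp, 0, 0.3), ncol = 8))
    colnames(pcs) <- sprintf("PC%d", 1:10)

    species_data[[sp]] <- list(
      cm = cm, clusters = cl, xy = xy, pcs = pcs,
      pseudotime = data.frame(cell_id = cell_names, lineage = branch,
                              t = t_rel, stringsAsFactors = FALSE),
      dispersion = phi, gene_means = M)
  }

  sp_a <- cfg$species[1]
  sp_b <- cfg$species[2]
  A <- species_data[[sp_a]]
  B <- species_data[[sp_b]]

  # ortholog map over both species' mapped genes
  set.seed(sub_seed(cfg$seed, 20))
  group_ids <- sprintf("OG%04d", seq_len(G))
  map <- lapply(seq_len(G), function(j) {
    rbind(
      data.frame(species = sp_a,
                 gene_id = copies[[sp_a]]$gene_id[copies[[sp_a]]$group == j],
                 stringsAsFactors = FALSE),
      data.frame(species = sp_b,
                 gene_id = copies[[sp_b]]$gene_id[copies[[sp_b]]$group == j],
                 stringsAsFactors = FALSE))
  })
  names(map) <- group_ids
  ortho_map <- structure(map, class = "ortho_group_map",
                         n_members = lengths(lapply(map, `[[`, "gene_id")))

  embedding <- labeled_embedding(
    c(cell_ids(A$cm), cell_ids(B$cm)), rbind(A$xy, B$xy),
    c(rep(sp_a, n_cells(A$cm)), rep(sp_b, n_cells(B$cm))),
    c(A$clusters, B$clusters))

  # LCM bulk profiles of the terminal cell types (species A)
  set.seed(sub_seed(cfg$seed, 30))
  term <- topo$terminal
  tpm_cols <- list()
  col_types <- character(0)
  for (ct in names(term)) {
    base_prof <- A$gene_means[, term[[ct]]]
    base_tpm <- base_prof / sum(base_prof) * 1e6
    for (r in seq_len(cfg$lcm_replicates)) {
      tpm_cols[[length(tpm_cols) + 1]] <-
        base_tpm * exp(stats::rnorm(length(base_tpm), 0, cfg$lcm_noise_sd))
      col_types <- c(col_types, ct)
    }
  }
  tpm <- do.call(cbind, tpm_cols)
  rownames(tpm) <- rownames(A$gene_means)
  lcm <- lcm_profile(tpm, col_types)

  marker_groups <- split(group_ids[seq_len(8 * cfg$n_markers_per_cluster)],
                         rep(topo$names, each = cfg$n_markers_per_cluster))
  marker_genes <- lapply(marker_groups, function(gs) {
    lapply(stats::setNames(cfg$species, cfg$species), function(sp) {
      cp <- copies[[sp]]
      cp$gene_id[cp$group %in% match(gs, group_ids)]
    })
  })

  truth <- list(
    correspondence = stats::setNames(topo$names, topo$names),
    marker_groups = marker_groups,
    marker_genes = marker_genes,
    lcm_programs = lapply(topo$terminal, function(ct)
      marker_genes[[ct]][[sp_a]]),
    divergent_groups = group_ids[divergent],
    programs = list(P_a = P_a, P_b = P_b),
    topology = topo,
    expected_overlap_regime = if (cfg$divergence < 0.3) "high" else "reduced")

  list(matrix_a = A$cm, matrix_b = B$cm, ortho_map = ortho_map,
       embedding = embedding,
       pcs = stats::setNames(
         list(labeled_embedding(cell_ids(A$cm), A$pcs, sp_a, A$clusters),
              labeled_embedding(cell_ids(B$cm), B$pcs, sp_b, B$clusters)),
         cfg$species),
       clusters = stats::setNames(list(A$clusters, B$clusters), cfg$species),
       pseudotime = stats::setNames(list(A$pseudotime, B$pseudotime),
                                    cfg$species),
       lcm = lcm, truth = truth, config = cfg)
}

#' Simulate a labeled two-cloud embedding
#'
#' Fixture generator for the overlap statistic: both species are drawn from
#' the same three-component Gaussian mixture (unit component sd); species
#' B's component centers are displaced along x by \code{separation} blob
#' standard deviations. \code{interdigitation} scales the component sd of
#' both clouds.
#'
#' @param n cells per species (>= 10).
#' @param separation displacement of species B in units of component sd.
#' @param interdigitation component sd multiplier (default 1).
#' @param seed RNG seed.
#' @param species two species labels.
#' @return A \code{\link{labeled_embedding}} with 2 n cells.
#' @export
simulate_embedding_pair <- function(n, separation = 0, interdigitation = 1,
                                    seed = 1, species = c("ptr", "egr")) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  set.seed(sub_seed(seed, 40))
  centers <- rbind(c(0, 0), c(3, 1), c(-2, 2.5))
  wts <- c(0.4, 0.35, 0.25)
  draw <- function(shift) {
    comp <- sample(1:3, n, replace = TRUE, prob = wts)
    sweep(centers[comp, , drop = FALSE], 2, shift, "+") +
      matrix(stats::rnorm(2 * n, 0, interdigitation), ncol = 2)
  }
  xy_a <- draw(c(0, 0))
  xy_b <- draw(c(separation, 0))
  labeled_embedding(
    sprintf("cell%05d", seq_len(2 * n)), rbind(xy_a, xy_b),
    rep(species, each = n))
}
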