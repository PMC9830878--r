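test_that("the MST of forced geometries is exact", {
  pts <- rbind(c(0, 0), c(1, 0), c(3, 0))
  mst <- build_mst(pts)
  expect_equal(nrow(mst), 2)
  expect_equal(sum(mst$weight), 3)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(mst), c("1 2", "2 3"))

  two <- build_mst(rbind(c(0, 0), c(2, 1)))
  expect_equal(nrow(two), 1)
  expect_equal(two$weight, sqrt(5))

  expect_error(build_mst(rbind(c(0, 0))), "at least 2")
  expect_error(build_mst(rbind(c(0, 0), c(NA, 1))), "finite")
})

test_that("MST weight matches Kruskal and Prim brute-force oracles", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(rnorm(2 * 100), ncol = 2)
    mst <- build_mst(pts)
    expect_equal(sum(mst$weight), oracle_kruskal_weight(pts),
                 tolerance = 1e-9)
  }
  set.seed(99)
  pts <- matrix(rnorm(2 * 40), ncol = 2)
  expect_equal(sum(build_mst(pts)$weight), oracle_prim_weight(pts),
               tolerance = 1e-9)
})

test_that("cross-species edge removal yields removed + 1 components", {
  pts <- cbind(0:3, 0)
  mst <- build_mst(pts)
  sub <- split_subgraphs(mst, c("a", "b", "a", "b"))
  expect_equal(sub$removed, 3)
  expect_equal(sub$n_components, 4)
  expect_equal(length(unique(sub$membership)), 4)

  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    pts <- matrix(rnorm(2 * n), ncol = 2)
    labels <- sample(c("a", "b"), n, replace = TRUE)
    sub <- split_subgraphs(build_mst(pts), labels)
    expect_equal(sub$n_components, sub$removed + 1)
    # every component is single-species
    expect_true(all(tapply(labels, sub$membership,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("component centers maximize closeness centrality", {
  # 3-node path with unit edges: middle node wins
  pts <- cbind(c(0, 1, 2), 0)
  mst <- build_mst(pts)
  one <- split_subgraphs(mst, c("a", "a", "b"))
  ctr <- component_centers(one, mst)
  big <- ctr[ctr$size == 2, ]
  expect_equal(big$center, 1)  # path 0-1: both ends tie, lowest index
  expect_true(big$tie)
  singleton <- ctr[ctr$size == 1, ]
  expect_equal(singleton$center, 3)

  pts <- cbind(c(0, 1, 2, 5), 0)
  mst4 <- build_mst(pts)
  all_same <- split_subgraphs(mst4, c("a", "a", "a", "b"))
  ctr4 <- component_centers(all_same, mst4)
  expect_equal(ctr4$center[ctr4$size == 3], 2)  # middle of the 0-1-2 path

  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    pts <- matrix(rnorm(2 * n), ncol = 2)
    mst <- build_mst(pts)
    labels <- rep("a", n); labels[1] <- "b"
    sub <- split_subgraphs(mst, labels)
    ctr <- component_centers(sub, mst)
    for (r in seq_len(nrow(ctr))) {
      nodes <- which(sub$membership == ctr$component[r])
      if (length(nodes) < 2) next
      edges <- sub$kept[sub$kept$from %in% nodes & sub$kept$to %in% nodes, ]
      sums <- oracle_closeness_sums(nodes, edges)
      # the chosen center attains the minimal distance sum (ties legal)
      expect_lt(sums[as.character(ctr$center[r])] - min(sums), 1e-9)
    }
  }
})

test_that("split_subgraphs handles one label and rejects three", {
  set.seed(20)
  pts <- matrix(rnorm(20), ncol = 2)
  mst <- build_mst(pts)
  same <- split_subgraphs(mst, rep("a", 10))
  expect_equal(same$n_components, 1)
  expect_equal(same$removed, 0)
  expect_error(split_subgraphs(mst, rep(c("a", "b", "c"), length.out = 10)),
               "two labels")
})

test_that("the weighted density map has unit-mass components and scales", {
  cfg <- overlap_config(grid_size = 120, margin = 0.2)
  centers <- list(ptr = rbind(c(0, 0)),
                  egr = rbind(c(1, 1), c(-1, -1)))
  all_pts <- list(ptr = matrix(rnorm(200), ncol = 2),
                  egr = matrix(rnorm(200), ncol = 2))
  expect_warning(
    wdm <- weighted_density_map(centers, c(ptr = 100, egr = 100), cfg,
                                all_points = all_pts),
    "fallback")
  cell_area <- diff(wdm$x[1:2]) * diff(wdm$y[1:2])
  # f = w / weight must integrate to ~1 on the grid
  expect_equal(sum(wdm$w$ptr) * cell_area / wdm$weight["ptr"], 1,
               tolerance = 1e-3, ignore_attr = TRUE)

  # mirror-symmetric centers give a mirror-symmetric combined field
  sym <- suppressWarnings(weighted_density_map(
    list(a = rbind(c(-1, 0)), b = rbind(c(1, 0))),
    c(a = 50, b = 50), cfg,
    all_points = list(a = rbind(c(-1, -1), c(-1, 1)),
                      b = rbind(c(1, -1), c(1, 1)))))
  D <- sym$D
  expect_equal(D, D[rev(seq_len(nrow(D))), ], tolerance = 1e-9)

  # doubling the center count (same KDE shape) doubles the weighted field
  c1 <- list(a = rbind(c(0, 0), c(1, 0)), b = rbind(c(5, 5), c(6, 5)))
  c2 <- list(a = rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0)),
             b = c1$b)
  w1 <- suppressWarnings(weighted_density_map(c1, c(a = 10, b = 10), cfg))
  w2 <- suppressWarnings(weighted_density_map(c2, c(a = 10, b = 10), cfg))
  ratio <- w2$weight["a"] / w1$weight["a"]
  expect_equal(ratio, 2, ignore_attr = TRUE, tolerance = 0.3)
})

test_that("overlap is invariant to translation and uniform rescaling", {
  emb <- simulate_embedding_pair(150, separation = 2, seed = 5)
  base <- overlap_statistic(emb)
  shifted <- labeled_embedding(emb$cell_ids,
                               sweep(emb$coordinates, 2, c(13, -4), "+") * 2.5,
                               emb$species)
  moved <- overlap_statistic(shifted)
  # cells exactly on a bin edge may flip bins under rescaling round-off,
  # so the statistic is compared rather than the full bin vector
  expect_equal(moved$overlap, base$overlap, tolerance = 1e-6)
  expect_equal(moved$removed, base$removed)
})

test_that("overlap is stable under rigid rotation", {
  emb <- simulate_embedding_pair(150, separation = 2, seed = 6)
  base <- overlap_statistic(emb)
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- labeled_embedding(emb$cell_ids, emb$coordinates %*% R, emb$species)
  rotated <- overlap_statistic(rot)
  expect_equal(rotated$removed, base$removed)  # MST is rotation invariant
  # per-axis bandwidths make the density only approximately invariant
  expect_lt(abs(rotated$overlap_pct - base$overlap_pct), 3)
})

test_that("overlap bin proportions are a distribution over cells", {
  emb <- simulate_embedding_pair(200, separation = 3, seed = 7)
  ov <- overlap_statistic(emb)
  expect_equal(sum(ov$bins), 1, tolerance = 1e-12)
  expect_gte(ov$overlap, 0)
  expect_lte(ov$overlap, 1)
  expect_equal(max(ov$membership), ov$removed + 1)
  expect_length(ov$bins, 500)
  expect_equal(ov$overlap, 1 - ov$bins[1])
})

test_that("overlap rejects single-species embeddings", {
  emb <- labeled_embedding(paste0("c", 1:20), matrix(rnorm(40), ncol = 2),
                           "onlyone")
  expect_error(overlap_statistic(emb), "two species")
})

test_that("cross-edge counts match the interdigitation expectation", {
  n <- 1000
  ks <- vapply(1:10, function(seed) {
    emb <- simulate_embedding_pair(n / 2, separation = 0, seed = seed)
    sub <- split_subgraphs(build_mst(emb$coordinates), emb$species)
    sub$removed
  }, numeric(1))
  expected <- 2 * (n / 2) * (n / 2) / n
  expect_lt(abs(mean(ks) - expected) / expected, 0.2)
})
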