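tiny_map <- function() {
  f <- withr::local_tempfile(
    lines = c("OG1: ptr|g1 ptr|g2 egr|h1",
              "OG2: ptr|g3 egr|h2 egr|h3",
              "OG3: ptr|g5 egr|h5"),
    .local_envir = parent.frame())
  read_ortholog_groups(f)
}

test_that("ortholog aggregation sums member gene counts", {
  map <- tiny_map()
  m <- cell_matrix(rbind(c(2, 3, 7), c(1, 0, 4)), c("c1", "c2"),
                   c("g1", "g2", "g3"), species = "ptr")
  om <- aggregate_orthogroups(m, map)
  expect_equal(as.numeric(om$counts[, "OG1"]), c(5, 1))
  expect_equal(as.numeric(om$counts[, "OG2"]), c(7, 4))
})

test_that("unmapped genes are dropped, reported, and totals conserved", {
  map <- tiny_map()
  m <- cell_matrix(rbind(c(2, 3, 7, 9), c(1, 0, 4, 2)), c("c1", "c2"),
                   c("g1", "g2", "g3", "orphan"), species = "ptr")
  om <- aggregate_orthogroups(m, map)
  expect_false("orphan" %in% colnames(om$counts))
  expect_identical(attr(om, "unmapped_genes"), "orphan")
  mapped <- c("g1", "g2", "g3")
  expect_equal(sum(om$counts), sum(m$counts[, mapped]))

  set.seed(12)
  perm <- sample(4)
  mp <- cell_matrix(m$counts[, perm], cell_ids(m), gene_ids(m)[perm],
                    species = "ptr")
  omp <- aggregate_orthogroups(mp, map)
  expect_equal(as.matrix(omp$counts[, colnames(om$counts)]),
               as.matrix(om$counts))

  wrong <- cell_matrix(m$counts, cell_ids(m), gene_ids(m), species = "zzz")
  expect_error(aggregate_orthogroups(wrong, map), "no genes of species")
})

test_that("cluster correlations match direct Pearson on cluster means", {
  sim <- simulate_two_species(sim_config(seed = 2, n_per_cluster = 10,
                                         n_orthogroups = 80,
                                         n_markers_per_cluster = 5))
  oa <- aggregate_orthogroups(sim$matrix_a, sim$ortho_map)
  ob <- aggregate_orthogroups(sim$matrix_b, sim$ortho_map)
  cc <- cluster_profile_correlation(oa, ob, sim$clusters$ptr,
                                    sim$clusters$egr)
  expect_true(all(cc$r >= -1 & cc$r <= 1))

  shared <- cc$shared_groups
  mean_profile <- function(om, cl, lab) {
    nv <- normalize_counts(om)$values[, shared, drop = FALSE]
    Matrix::colMeans(nv[cl == lab, , drop = FALSE])
  }
  for (la in rownames(cc$r)[1:3]) for (lb in colnames(cc$r)[1:3]) {
    expect_equal(cc$r[la, lb],
                 cor(mean_profile(oa, sim$clusters$ptr, la),
                     mean_profile(ob, sim$clusters$egr, lb)),
                 tolerance = 1e-12)
  }

  # symmetry: corr(a, b) is the transpose of corr(b, a)
  cc_t <- cluster_profile_correlation(ob, oa, sim$clusters$egr,
                                      sim$clusters$ptr)
  expect_equal(cc$r, t(cc_t$r), tolerance = 1e-12)
})

test_that("a relabeled copy of a species is its own best hit", {
  sim <- simulate_two_species(sim_config(seed = 3, n_per_cluster = 10,
                                         n_orthogroups = 80,
                                         n_markers_per_cluster = 5))
  oa <- aggregate_orthogroups(sim$matrix_a, sim$ortho_map)
  cc <- cluster_profile_correlation(oa, oa, sim$clusters$ptr,
                                    sim$clusters$ptr)
  expect_equal(unname(diag(cc$r[rownames(cc$r), rownames(cc$r)])),
               rep(1, nrow(cc$r)), tolerance = 1e-12)
  mbh <- mutual_best_hits(cc)
  expect_true(all(mbh$mutual$cluster_a == mbh$mutual$cluster_b))
  expect_equal(nrow(mbh$mutual), nrow(cc$r))
})

test_that("small and excluded clusters are removed from the comparison", {
  map <- tiny_map()
  set.seed(14)
  counts <- matrix(rpois(20 * 4, 5), 20, 4)
  m <- cell_matrix(counts, sprintf("c%02d", 1:20),
                   c("g1", "g2", "g3", "g5"), species = "ptr")
  cl <- c(rep("big1", 9), rep("big2", 8), rep("tiny", 3))
  cc <- cluster_profile_correlation(aggregate_orthogroups(m, map),
                                    aggregate_orthogroups(m, map),
                                    cl, cl, exclude = "big2")
  expect_false("tiny" %in% rownames(cc$r))   # < 5 cells
  expect_false("big2" %in% rownames(cc$r))   # explicit exclusion
  expect_true("tiny" %in% cc$excluded$ptr)
})

test_that("best hits and mutual flags follow the argmax definition", {
  r <- matrix(c(0.9, 0.2, 0.1, 0.8), 2,
              dimnames = list(c("A1", "A2"), c("B1", "B2")))
  mbh <- mutual_best_hits(r)
  expect_equal(mbh$mutual$cluster_a, c("A1", "A2"))
  expect_equal(mbh$mutual$cluster_b, c("B1", "B2"))

  r2 <- matrix(c(0.9, 0.85, 0.8, 0.1), 2,
               dimnames = list(c("A1", "A2"), c("B1", "B2")))
  mbh2 <- mutual_best_hits(r2)
  expect_equal(mbh2$best_a$best_b, c("B1", "B1"))
  expect_equal(mbh2$mutual$cluster_a, "A1")
  expect_equal(mbh2$mutual$cluster_b, "B1")

  id3 <- diag(3)
  dimnames(id3) <- list(paste0("A", 1:3), paste0("B", 1:3))
  mbh3 <- mutual_best_hits(id3)
  expect_equal(nrow(mbh3$mutual), 3)
  expect_equal(mbh3$mutual$cluster_a, paste0("A", 1:3))
})

test_that("DEO module assignment follows the largest fold-change rule", {
  deo <- list(
    k2 = data.frame(group_id = c("OG1", "OG7"), log2_fc = c(1.4, 2.2)),
    k5 = data.frame(group_id = c("OG1", "OG9"), log2_fc = c(2.0, 1.1)))
  modules <- c(k2 = 2, k5 = 5)
  out <- assign_deo_modules(deo, modules)
  expect_equal(out$module[out$group_id == "OG1"], 5)   # 2.0 > 1.4
  expect_equal(out$module[out$group_id == "OG7"], 2)
  expect_equal(out$module[out$group_id == "OG9"], 5)
  expect_false(any(out$unresolved))
  expect_equal(anyDuplicated(out$group_id), 0)

  plain <- assign_deo_modules(list(k2 = c("OGx", "OGy"), k5 = "OGx"),
                              modules)
  expect_true(plain$unresolved[plain$group_id == "OGx"])
  expect_false(plain$unresolved[plain$group_id == "OGy"])
})

test_that("planted module structure is recovered from fold-changes", {
  set.seed(13)
  n_groups <- 100
  true_module <- sample(1:8, n_groups, replace = TRUE)
  gids <- sprintf("OG%03d", seq_len(n_groups))
  deo <- lapply(1:8, function(k) {
    home <- gids[true_module == k]
    stray <- sample(gids[true_module != k], 5)
    data.frame(group_id = c(home, stray),
               log2_fc = c(runif(length(home), 2, 4),
                           runif(5, 0.2, 1.0)))
  })
  names(deo) <- paste0("k", 1:8)
  out <- assign_deo_modules(deo, setNames(1:8, paste0("k", 1:8)))
  acc <- mean(out$module == true_module[match(out$group_id, gids)])
  expect_gte(acc, 0.9)
})
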