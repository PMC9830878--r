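make_two_group_matrix <- function(counts_a, counts_b) {
  counts <- rbind(counts_a, counts_b)
  cell_matrix(counts, sprintf("c%03d", seq_len(nrow(counts))),
              sprintf("g%03d", seq_len(ncol(counts))))
}

test_that("identical groups give log2FC 0 and p 1 for every gene", {
  set.seed(1)
  block <- matrix(rpois(10 * 15, 3), 10, 15)
  m <- make_two_group_matrix(block, block)
  de <- sseq_exact_test(m, 1:10, 11:20)
  nonzero <- de$table$test_used != "skipped"
  expect_true(all(de$table$log2_fc[nonzero] == 0))
  expect_true(all(de$table$p_value[nonzero] == 1))
})

test_that("the Poisson limit reproduces the exact binomial test", {
  set.seed(42)
  counts <- matrix(rpois(20 * 40, 0.6), nrow = 20)
  m <- make_two_group_matrix(counts[1:10, ], counts[11:20, ])
  de <- sseq_exact_test(m, 1:10, 11:20, dispersion_override = 0)

  tot <- Matrix::rowSums(m$counts)
  sf <- tot / median(tot)
  S_a <- sum(sf[1:10])
  x_a <- Matrix::colSums(m$counts[1:10, ])
  t_all <- Matrix::colSums(m$counts)
  keep <- t_all > 0 & t_all <= 30
  expect_gt(sum(keep), 10)
  oracle <- mapply(oracle_binom_two_sided, x_a[keep], t_all[keep],
                   S_a / sum(sf))
  expect_lt(max(abs(de$table$p_value[keep] - oracle)), 1e-10)
})

test_that("swapping group labels negates fold-changes and keeps p-values", {
  m <- rand_cell_matrix(8, 30, 50, lambda = 4)
  ab <- sseq_exact_test(m, 1:15, 16:30)
  ba <- sseq_exact_test(m, 16:30, 1:15)
  expect_equal(ab$table$log2_fc, -ba$table$log2_fc, tolerance = 1e-12)
  expect_equal(ab$table$p_value, ba$table$p_value, tolerance = 1e-12)
})

test_that("p-values are invariant to gene order and cell relabeling", {
  m <- rand_cell_matrix(9, 24, 30, lambda = 3)
  de <- sseq_exact_test(m, 1:12, 13:24)

  set.seed(2)
  perm <- sample(30)
  mp <- cell_matrix(m$counts[, perm], cell_ids(m), gene_ids(m)[perm])
  dep <- sseq_exact_test(mp, 1:12, 13:24)
  expect_equal(dep$table$p_value[match(gene_ids(m), gene_ids(mp))],
               de$table$p_value, tolerance = 1e-12)

  shuffle_a <- sample(1:12)
  des <- sseq_exact_test(m, shuffle_a, 13:24)
  expect_equal(des$table$p_value, de$table$p_value, tolerance = 1e-12)
})

test_that("large counts switch to the beta test matching edgeR's formula", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  n <- 10
  big <- rpois(2 * n, 400)
  filler <- max(big) + 50 - big  # equal totals => unit size factors
  counts <- cbind(big, filler)
  m <- cell_matrix(counts, sprintf("c%02d", 1:(2 * n)), c("gBig", "gFill"))
  de <- sseq_exact_test(m, 1:n, (n + 1):(2 * n),
                        dispersion_override = 0.1)
  expect_equal(de$table$test_used[1], "asymptotic_beta")
  ed <- edgeR:::exactTestBetaApprox(
    matrix(counts[1:n, 1], nrow = 1),
    matrix(counts[(n + 1):(2 * n), 1], nrow = 1), dispersion = 0.1)
  expect_equal(de$table$p_value[1], unname(pmin(1, ed)), tolerance = 1e-10)
})

test_that("null NB data keeps the raw rejection rate near nominal", {
  set.seed(17)
  X <- matrix(rnbinom(60 * 400, mu = 5, size = 10), nrow = 60)
  m <- cell_matrix(X, sprintf("c%03d", 1:60), sprintf("g%03d", 1:400))
  de <- sseq_exact_test(m, 1:30, 31:60)
  frac <- mean(de$table$p_value < 0.05, na.rm = TRUE)
  expect_lt(frac, 0.1)
  expect_gt(de$delta, 0.5)  # homogeneous dispersions shrink strongly
})

test_that("planted four-fold changes are recovered with high power", {
  set.seed(23)
  ng <- 300
  nde <- 40
  mu <- matrix(10, 100, ng)
  mu[1:50, 1:nde] <- 40
  X <- matrix(rnbinom(100 * ng, mu = mu, size = 10), 100, ng)
  m <- cell_matrix(X, sprintf("c%03d", 1:100), sprintf("g%03d", 1:ng))
  call <- call_degs(sseq_exact_test(m, 1:50, 51:100))
  power <- mean(sprintf("g%03d", 1:nde) %in% call$up)
  expect_gt(power, 0.8)
})

test_that("BH adjustment matches hand-derived and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.9)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.9), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  with_nan <- bh_adjust(c(0.01, NaN, 0.04))
  expect_true(is.na(with_nan[2]))
  expect_equal(with_nan[c(1, 3)], c(0.02, 0.04), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:10) {
    p <- round(runif(sample(c(5, 50, 500), 1)), 2)  # rounding forces ties
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DEG calling applies both thresholds and the 5-cell rule", {
  fake <- structure(list(
    table = data.frame(gene_id = c("a", "b", "c"),
                       mean_a = 1, mean_b = 1,
                       log2_fc = c(1.2, 0.9, -1.5),
                       p_value = c(0.001, 0.0001, 0.002),
                       p_adjusted = c(0.01, 0.001, 0.01),
                       test_used = "nb_exact"),
    delta = 1, dispersion = 0.1, size_factors = 1, n_a = 20, n_b = 30),
    class = "sseq_de")
  call <- call_degs(fake)
  expect_identical(call$up, "a")
  expect_identical(call$down, "c")

  fake$n_a <- 4
  small <- call_degs(fake)
  expect_false(small$eligible)
  expect_length(small$up, 0)

  expect_error(call_degs(fake, alpha = 1.5), "alpha")
})

test_that("one-vs-rest recovers planted cluster markers and little else", {
  set.seed(31)
  n_per <- 30
  ng <- 120
  mu <- matrix(4, 3 * n_per, ng)
  mu[1:n_per, 1:20] <- 32  # cluster 1 markers at 8x
  X <- matrix(rnbinom(3 * n_per * ng, mu = mu, size = 10), 3 * n_per, ng)
  m <- cell_matrix(X, sprintf("c%03d", 1:(3 * n_per)),
                   sprintf("g%03d", 1:ng))
  cl <- rep(c("k1", "k2", "k3"), each = n_per)
  res <- one_vs_rest_degs(m, cl)
  expect_gt(mean(sprintf("g%03d", 1:20) %in% res$k1$call$up), 0.8)

  set.seed(32)
  shuffled <- sample(cl)
  null_res <- one_vs_rest_degs(m, shuffled)
  n_false <- sum(vapply(null_res, function(x)
    length(x$call$up) + length(x$call$down), 0L))
  expect_lt(n_false, 0.05 * ng * 3)

  expect_error(one_vs_rest_degs(m, rep("k1", 3 * n_per)), "two clusters")

  cl_small <- c(rep("tiny", 4), rep("big", 3 * n_per - 4))
  res_small <- one_vs_rest_degs(m, cl_small)
  expect_false(res_small$tiny$call$eligible)
})

test_that("group arguments are validated", {
  m <- rand_cell_matrix(1, 10, 5)
  expect_error(sseq_exact_test(m, 1:5, 4:10), "disjoint")
  expect_error(sseq_exact_test(m, integer(0), 1:5), "at least one cell")
  expect_error(sseq_exact_test(m, c("c0001", "nope"), 3:4), "unknown cell")
})
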