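# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# Kruskal's algorithm on the complete Euclidean graph: total MST weight.
oracle_kruskal_weight <- function(points) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[edges])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  total <- 0
  taken <- 0
  for (e in ord) {
    i <- edges[e, 1]; j <- edges[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      total <- total + d[i, j]
      taken <- taken + 1
      if (taken == n - 1) break
    }
  }
  total
}

# Naive Prim's algorithm (scalar loop) on the distance matrix.
oracle_prim_weight <- function(points) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- NA
    for (j in which(!in_tree)) {
      m <- min(d[j, in_tree])
      if (m < best) { best <- m; bi <- j }
    }
    in_tree[bi] <- TRUE
    total <- total + best
  }
  total
}

# Floyd-Warshall all-pairs shortest paths on a weighted edge list;
# returns the per-node total distance (named by node).
oracle_closeness_sums <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes)
    j <- match(edges$to[r], nodes)
    if (is.na(i) || is.na(j)) next
    D[i, j] <- D[j, i] <- min(D[i, j], edges$weight[r])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  setNames(rowSums(D), nodes)
}

# Literal step-up BH definition: sort, p * m / rank, cumulative min from
# the largest rank, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided binomial test by full enumeration: total probability of
# all splits of t no more likely than the observed one.
oracle_binom_two_sided <- function(x_a, t, prob_a) {
  if (t == 0) return(NaN)
  pr <- dbinom(0:t, t, prob_a)
  sum(pr[pr <= pr[x_a + 1] * (1 + 1e-8)])
}

# Small dense cell_matrix fixture with reproducible Poisson counts.
rand_cell_matrix <- function(seed, n_cells_, n_genes_, lambda = 2,
                             species = "ptr") {
  set.seed(seed)
  counts <- matrix(rpois(n_cells_ * n_genes_, lambda), n_cells_, n_genes_)
  cell_matrix(counts, sprintf("c%04d", seq_len(n_cells_)),
              sprintf("g%04d", seq_len(n_genes_)), species = species)
}
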