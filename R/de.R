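#' @title Negative-binomial exact test with dispersion shrinkage
#'
#' @description Two-sided differential expression test between two groups of
#' cells, following the sSeq approach used by droplet pipelines: per-cell
#' size factors, method-of-moments gene dispersions shrunk toward the global
#' mean dispersion, and an exact test on the conditional distribution of the
#' two group sums given their total. For genes whose summed counts exceed
#' \code{big_count} in both groups the exact enumeration is replaced by an
#' asymptotic beta approximation of the conditional split (the edgeR-style
#' large-count approximation).
#'
#' @details
#' Size factors are \code{s_i = total_i / median(total)} over the cells of
#' the two groups. Dispersions are method-of-moments on size-factor
#' normalized counts, \code{phi_g = max(0, (var - mean) / mean^2)}, shrunk as
#' \code{phi~_g = delta * xi + (1 - delta) * phi_g} where \code{xi} is the
#' mean positive dispersion and the plug-in weight is
#' \code{delta = [sum((phi - mean(phi))^2)/(G-1)] /
#' [sum((phi - xi)^2)/(G-2)]}, clamped to [0, 1]; when the denominator
#' degenerates (fewer than 3 usable genes or all dispersions equal)
#' \code{delta = 1}, i.e. full shrinkage to the common value.
#'
#' The exact p-value conditions on the pooled count t: each group sum is
#' approximated as NB with mean \code{S_k * mu} and dispersion
#' \code{phi / S_k} (\code{S_k} = summed size factors of group k,
#' \code{mu = t / (S_a + S_b)}), and the two-sided p is the total conditional
#' probability of all splits no more likely than the observed one. With
#' dispersion 0 and equal size factors this reduces to the exact two-sided
#' binomial test on the pooled count.
#'
#' The beta approximation evaluates the continuity-corrected tail of
#' \code{Beta(alpha_a, alpha_b)} with
#' \code{alpha_k = S_k * mu / (1 + phi * mu)} at \code{x_a / t}, doubles it,
#' and caps at 1.
#'
#' @param m a \code{\link{cell_matrix}}.
#' @param group_a,group_b disjoint cell selections (character cell ids,
#'   integer indices, or logical vectors), each with at least one cell.
#' @param big_count per-group summed-count threshold above which the beta
#'   approximation replaces enumeration (default 900).
#' @param pseudocount pseudocount for the log2 fold-change on normalized
#'   group means (default 1).
#' @param dispersion_override optional fixed dispersion (scalar or per-gene)
#'   bypassing estimation; 0 gives the Poisson limit.
#' @return An object of class \code{sseq_de}: list with \code{table} (a
#'   data.frame with gene_id, mean_a, mean_b, log2_fc, p_value, p_adjusted,
#'   test_used), \code{delta}, \code{dispersion} (shrunk, per gene),
#'   \code{size_factors}, \code{n_a}, \code{n_b}.
#' @export
sseq_exact_test <- function(m, group_a, group_b, big_count = 900,
                            pseudocount = 1, dispersion_override = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  ia <- resolve_cells(m, group_a)
  ib <- resolve_cells(m, group_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both groups need at least one cell", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("groups must be disjoint", call. = FALSE)

  counts <- m$counts[c(ia, ib), , drop = FALSE]
  in_a <- seq_along(ia)
  totals <- Matrix::rowSums(counts)
  med <- stats::median(totals)
  if (med <= 0) stop("median cell total is zero", call. = FALSE)
  sf <- totals / med

  G <- ncol(counts)
  norm <- Matrix::Diagonal(x = 1 / sf) %*% counts
  mean_g <- Matrix::colMeans(norm)
  # E[x^2] - mean^2, with the n/(n-1) sample correction
  n_all <- nrow(counts)
  ex2 <- Matrix::colMeans(norm^2)
  var_g <- (ex2 - mean_g^2) * n_all / (n_all - 1)

  if (is.null(dispersion_override)) {
    est <- sseq_dispersion(mean_g, var_g)
    phi <- est$phi_shrunk
    delta <- est$delta
  } else {
    phi <- rep_len(dispersion_override, G)
    delta <- NA_real_
  }

  x_a <- Matrix::colSums(counts[in_a, , drop = FALSE])
  x_b <- Matrix::colSums(counts[-in_a, , drop = FALSE])
  S_a <- sum(sf[in_a])
  S_b <- sum(sf[-in_a])

  t_all <- x_a + x_b
  p <- rep(NaN, G)
  test_used <- rep("skipped", G)
  nonzero <- which(t_all > 0)
  big <- nonzero[x_a[nonzero] > big_count & x_b[nonzero] > big_count]
  small <- setdiff(nonzero, big)
  if (length(big)) {
    p[big] <- nb_beta_test(x_a[big], x_b[big], S_a, S_b, phi[big])
    test_used[big] <- "asymptotic_beta"
  }
  for (g in small) {
    p[g] <- nb_exact_split_p(x_a[g], t_all[g], S_a, S_b, phi[g])
    test_used[g] <- "nb_exact"
  }

  # normalized group means: mean over cells of x_ij / s_i
  mean_a <- Matrix::colMeans(norm[in_a, , drop = FALSE])
  mean_b <- Matrix::colMeans(norm[-in_a, , drop = FALSE])
  log2_fc <- log2(mean_a + pseudocount) - log2(mean_b + pseudocount)

  tab <- data.frame(gene_id = gene_ids(m), mean_a = mean_a, mean_b = mean_b,
                    log2_fc = log2_fc, p_value = p,
                    p_adjusted = bh_adjust(p), test_used = test_used,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, delta = delta, dispersion = phi,
                 size_factors = sf, n_a = length(ia), n_b = length(ib)),
            class = "sseq_de")
}

#' @export
print.sseq_de <- function(x, ...) {
  cat(sprintf("<sseq_de> %d genes, groups %d vs %d cells, delta = %s\n",
              nrow(x$table), x$n_a, x$n_b, format(x$delta, digits = 3)))
  invisible(x)
}

resolve_cells <- function(m, sel) {
  if (is.logical(sel)) {
    stopifnot(length(sel) == n_cells(m))
    return(which(sel))
  }
  if (is.character(sel)) {
    idx <- match(sel, cell_ids(m))
    if (anyNA(idx)) stop("unknown cell ids in group", call. = FALSE)
    return(idx)
  }
  sel <- as.integer(sel)
  if (any(sel < 1 | sel > n_cells(m)))
    stop("cell indices out of range", call. = FALSE)
  sel
}

# sSeq-style dispersion shrinkage from per-gene moments.
sseq_dispersion <- function(mean_g, var_g) {
  phi_mm <- ifelse(mean_g > 0, pmax(0, (var_g - mean_g) / mean_g^2), NA_real_)
  use <- which(is.finite(phi_mm) & mean_g > 0 & var_g > 0)
  if (length(use) >= 1) {
    xi <- mean(phi_mm[use])
  } else {
    xi <- 0
  }
  G <- length(use)
  if (G >= 3) {
    num <- sum((phi_mm[use] - mean(phi_mm[use]))^2) / (G - 1)
    den <- sum((phi_mm[use] - xi)^2) / (G - 2)
    delta <- if (den > 0) min(1, max(0, num / den)) else 1
  } else {
    delta <- 1
  }
  phi_shrunk <- delta * xi + (1 - delta) * ifelse(is.na(phi_mm), 0, phi_mm)
  list(phi_mm = phi_mm, xi = xi, delta = delta, phi_shrunk = phi_shrunk)
}

# Exact two-sided p for the split (x_a, t - x_a) of the pooled count t,
# conditioning on t. Group sums are NB(mean S_k * mu, dispersion phi / S_k);
# all splits with conditional probability <= that of the observed split
# (up to a small relative tolerance for ties) are summed.
nb_exact_split_p <- function(x_a, t, S_a, S_b, phi) {
  mu <- t / (S_a + S_b)
  k <- 0:t
  lp <- nb_log_pmf(k, S_a * mu, phi / S_a) +
    nb_log_pmf(t - k, S_b * mu, phi / S_b)
  lp_obs <- lp[x_a + 1]
  keep <- lp <= lp_obs + 1e-8
  mx <- max(lp)
  num <- sum(exp(lp[keep] - mx))
  den <- sum(exp(lp - mx))
  min(1, num / den)
}

nb_log_pmf <- function(x, mu, phi) {
  if (phi <= 1e-12) stats::dpois(x, mu, log = TRUE)
  else stats::dnbinom(x, mu = mu, size = 1 / phi, log = TRUE)
}

# Vectorized beta approximation to the conditional split distribution for
# large counts; continuity-corrected two-sided tail, capped at 1.
nb_beta_test <- function(x_a, x_b, S_a, S_b, phi) {
  t <- x_a + x_b
  mu <- t / (S_a + S_b)
  a1 <- S_a * mu / (1 + phi * mu)
  a2 <- S_b * mu / (1 + phi * mu)
  med <- stats::qbeta(0.5, a1, a2)
  p <- rep(1, length(t))
  left <- (x_a + 0.5) / t < med
  right <- (x_a - 0.5) / t > med
  if (any(left))
    p[left] <- 2 * stats::pbeta((x_a[left] + 0.5) / t[left],
                                a1[left], a2[left])
  if (any(right))
    p[right] <- 2 * stats::pbeta((x_a[right] - 0.5) / t[right],
                                 a1[right], a2[right], lower.tail = FALSE)
  pmin(1, p)
}

#' Benjamini-Hochberg adjustment with NaN passthrough
#'
#' Step-up FDR adjustment. NA/NaN entries (genes skipped by the test) are
#' passed through unchanged and excluded from the number of tests m.
#'
#' @param p numeric vector of p-values in [0, 1], NA/NaN allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes from a test result
#'
#' Applies the DEG rule: BH-adjusted p < \code{alpha} and |log2FC| >=
#' \code{min_lfc}. A focal group of fewer than \code{min_cells} cells is
#' ineligible and yields an empty call.
#'
#' @param de an \code{sseq_de} result (group A is the focal group).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_lfc minimum absolute log2 fold-change (default 1).
#' @param min_cells minimum focal-group size for eligibility (default 5).
#' @return An object of class \code{deg_call}: list with \code{up},
#'   \code{down} (gene id vectors), \code{eligible}, \code{alpha},
#'   \code{min_lfc}.
#' @export
call_degs <- function(de, alpha = 0.05, min_lfc = 1, min_cells = 5) {
  stopifnot(inherits(de, "sseq_de"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  eligible <- de$n_a >= min_cells
  up <- character(0)
  down <- character(0)
  if (eligible) {
    tb <- de$table
    sig <- !is.na(tb$p_adjusted) & tb$p_adjusted < alpha &
      abs(tb$log2_fc) >= min_lfc
    up <- tb$gene_id[sig & tb$log2_fc > 0]
    down <- tb$gene_id[sig & tb$log2_fc < 0]
  }
  structure(list(up = up, down = down, eligible = eligible, alpha = alpha,
                 min_lfc = min_lfc),
            class = "deg_call")
}

#' @export
print.deg_call <- function(x, ...) {
  cat(sprintf("<deg_call> %d up, %d down%s (adj p < %g, |log2FC| >= %g)\n",
              length(x$up), length(x$down),
              if (x$eligible) "" else " [ineligible cluster]",
              x$alpha, x$min_lfc))
  invisible(x)
}

#' One-vs-rest differential expression per cluster
#'
#' For each cluster with at least \code{min_cells} cells, tests the cells
#' inside the cluster against all cells outside it, adjusts p-values and
#' applies the DEG thresholds. Smaller clusters yield ineligible empty
#' calls.
#'
#' @param m a \code{\link{cell_matrix}}.
#' @param clusters cluster label per cell (length = number of cells).
#' @param alpha,min_lfc,min_cells as in \code{\link{call_degs}}.
#' @param ... passed to \code{\link{sseq_exact_test}}.
#' @return Named list per cluster: list(\code{de} = \code{sseq_de} or NULL,
#'   \code{call} = \code{deg_call}).
#' @export
one_vs_rest_degs <- function(m, clusters, alpha = 0.05, min_lfc = 1,
                             min_cells = 5, ...) {
  stopifnot(inherits(m, "cell_matrix"))
  clusters <- as.character(clusters)
  if (length(clusters) != n_cells(m))
    stop("one cluster label per cell required", call. = FALSE)
  labs <- sort(unique(clusters))
  if (length(labs) < 2)
    stop("at least two clusters required", call. = FALSE)
  out <- lapply(labs, function(lab) {
    inside <- which(clusters == lab)
    if (length(inside) < min_cells) {
      return(list(de = NULL,
                  call = structure(list(up = character(0),
                                        down = character(0),
                                        eligible = FALSE, alpha = alpha,
                                        min_lfc = min_lfc),
                                   class = "deg_call")))
    }
    de <- sseq_exact_test(m, inside, setdiff(seq_len(n_cells(m)), inside),
                          ...)
    list(de = de, call = call_degs(de, alpha, min_lfc, min_cells))
  })
  names(out) <- labs
  out
}
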