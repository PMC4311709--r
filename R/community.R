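#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, equalizing detection effort across samples before richness and
#' rare-responder analyses. Deterministic under `seed`.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample; default (`NULL`) is the minimum
#'   sample total across the table.
#' @param seed integer seed for the subsampling.
#' @return a rarefied [otu_table()]; every sample total equals `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- check_count(depth, "depth")
  short <- totals < depth
  if (any(short))
    stopf("rarefaction depth %d exceeds the total of sample '%s' (%d reads)",
          depth, rownames(table$counts)[short][1L], min(totals[short]))
  counts <- with_seed(seed, {
    t(apply(table$counts, 1L, rarefy_counts, depth = depth))
  })
  dimnames(counts) <- dimnames(table$counts)
  otu_table(counts, table$metadata, table$taxonomy)
}

# subsample one count vector without replacement to `depth` reads
rarefy_counts <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(as.integer(x))
  reads <- rep.int(seq_along(x), x)
  kept <- reads[sample.int(total, depth)]
  tabulate(kept, nbins = length(x))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, the standard compositional
#' turnover measure in \[0, 1\] (0 = identical, 1 = disjoint).
#'
#' @param x,y nonnegative count vectors of equal length, not both all-zero.
#' @return the dissimilarity, a number in \[0, 1\].
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))  # 1 - 8/12 = 0.3333
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stopf("count vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stopf("counts must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    stopf("undefined distance: both samples are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param table an [otu_table()] with at least 2 samples.
#' @return symmetric matrix of Bray-Curtis dissimilarities with zero
#'   diagonal, dimnames = sample ids.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
  }
  d
}

#' Observed richness of a sample
#'
#' The number of OTUs with nonzero count — the plain richness measure used
#' after rarefaction.
#'
#' @param x a count vector, or an [otu_table()] (per-sample richness).
#' @return integer, or named integer vector for a table.
#' @export
observed_richness <- function(x) {
  if (inherits(x, "otu_table")) return(apply(x$counts, 1L, function(v)
    sum(v > 0)))
  sum(x > 0)
}

#' Two-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance partitioning the squared
#' distances among samples by two crossed factors and their interaction,
#' via the Gower-centered inner-product matrix `G = -0.5 * J D^2 J` and
#' sequential (Type I) sums of squares with factor A entered first.
#' Pseudo-F per term is `(SS_term / df_term) / (SS_res / df_res)`;
#' significance comes from free permutation of sample rows:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' `strata` restricts permutations to shuffles within each stratum (e.g.
#' within-ecosystem permutation for a paired design).
#'
#' @param d symmetric distance matrix (samples x samples, zero diagonal).
#' @param factor_a,factor_b factor labels aligned with the rows of `d`;
#'   each needs >= 2 levels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param strata optional labels restricting permutations within groups.
#' @return data.frame with rows A, B, A:B, Residual, Total and columns
#'   `term`, `df`, `sum_sq`, `pseudo_F`, `p`.
#' @export
permanova <- function(d, factor_a, factor_b, n_perm = 999, seed = 1L,
                      strata = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stopf("`d` must be a square distance matrix")
  n <- nrow(d)
  if (length(factor_a) != n || length(factor_b) != n)
    stopf("factor labels must align with the distance matrix")
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2L)
    stopf("degenerate factor: factor_a has a single level")
  if (nlevels(b) < 2L)
    stopf("degenerate factor: factor_b has a single level")
  n_perm <- check_count(n_perm, "n_perm", lower = 99L)

  G <- gower_center(d)
  # sequential hat matrices: 1 | +A | +A+B | +A+B+A:B
  H0 <- hat_mat(matrix(1, n, 1L))
  H1 <- hat_mat(stats::model.matrix(~a))
  H2 <- hat_mat(stats::model.matrix(~a + b))
  H3 <- hat_mat(stats::model.matrix(~a * b))
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  if (df_res < 1L) stopf("no residual degrees of freedom")

  stat <- function(Gp) {
    ss_a <- sum(diag((H1 - H0) %*% Gp))
    ss_b <- sum(diag((H2 - H1) %*% Gp))
    ss_ab <- sum(diag((H3 - H2) %*% Gp))
    ss_res <- sum(diag((diag(n) - H3) %*% Gp))
    ms_res <- ss_res / df_res
    c(ss_a, ss_b, ss_ab, ss_res,
      (ss_a / df_a) / ms_res, (ss_b / df_b) / ms_res,
      (ss_ab / df_ab) / ms_res)
  }
  obs <- stat(G)
  exceed <- c(0L, 0L, 0L)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- if (is.null(strata)) sample.int(n) else {
        p <- seq_len(n)
        for (s in unique(strata)) {
          idx <- which(strata == s)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
      Fp <- stat(G[perm, perm])[5:7]
      exceed <- exceed + (Fp >= obs[5:7] - 1e-12)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)
  ss_tot <- sum(diag(G))
  data.frame(
    term = c("A", "B", "A:B", "Residual", "Total"),
    df = c(df_a, df_b, df_ab, df_res, n - 1L),
    sum_sq = c(obs[1:4], ss_tot),
    pseudo_F = c(obs[5:7], NA, NA),
    p = c(pvals, NA, NA))
}

# Gower-centered inner-product matrix of a distance matrix
gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# projection (hat) matrix of a design matrix, rank-safe
hat_mat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}
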