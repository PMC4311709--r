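test_that("rarefy equalizes totals, never inflates counts, and is seed-stable", {
  tb <- tiny_table(depth = 200)
  r <- rarefy(tb, depth = 150, seed = 3)
  expect_true(all(rowSums(r$counts) == 150))
  expect_true(all(r$counts <= tb$counts))
  expect_identical(rarefy(tb, depth = 150, seed = 3)$counts, r$counts)
  # depth = sample total leaves counts unchanged
  expect_identical(rarefy(tb, depth = 200, seed = 1)$counts, tb$counts)
  expect_error(rarefy(tb, depth = 500), "exceeds")
  # single-OTU forcing: (10, 0) at depth 5 -> (5, 0)
  cnts <- matrix(c(10L, 0L, 10L, 0L), 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("o1", "o2")))
  md <- data.frame(sample = c("s1", "s2"), ecosystem = "E1",
                   treatment = c("dry", "rewetted"), replicate = 1,
                   pair = "E1.1")
  r2 <- rarefy(otu_table(cnts, md), depth = 5, seed = 1)
  expect_equal(unname(r2$counts[1, ]), c(5L, 0L))
})

test_that("rarefaction of (5,5) to depth 4 matches the hypergeometric mean", {
  cnts <- matrix(c(5L, 5L), 1, dimnames = list("s1", c("o1", "o2")))
  md <- data.frame(sample = "s1", ecosystem = "E1", treatment = "dry",
                   replicate = 1, pair = "E1.1")
  tb <- otu_table(cnts, md)
  draws <- vapply(1:2000, function(s)
    rarefy(tb, depth = 4, seed = s)$counts[1, 1], integer(1))
  # mean 2.0, hypergeometric SE of the MC mean ~ 0.018
  expect_equal(mean(draws), 2.0, tolerance = 0.06)
})

test_that("bray_curtis matches hand arithmetic, brute force, and its bounds", {
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 - 8 / 12)
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 7)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(77)
  for (rep in 1:25) {
    x <- stats::rpois(20, 3); y <- stats::rpois(20, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis(x, y)
    expect_equal(d, bc_oracle(x, y), tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("bray_curtis_matrix is symmetric, zero-diagonal, and permutation-equivariant", {
  tb <- tiny_table(n_eco = 1, n_rep = 2, n_taxa = 15, depth = 100)
  d <- bray_curtis_matrix(tb)
  expect_equal(d, t(d))
  expect_equal(diag(d), stats::setNames(rep(0, 4), rownames(d)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], bray_curtis(tb$counts[i, ], tb$counts[j, ]))
  # duplicated sample -> off-diagonal zero
  cnts <- rbind(tb$counts, dup = tb$counts[1, ])
  rownames(cnts) <- c(rownames(tb$counts), "dup")
  md <- rbind(tb$metadata,
              data.frame(sample = "dup", ecosystem = "E1",
                         treatment = "dry", replicate = 9, pair = "E1.9"))
  d2 <- bray_curtis_matrix(otu_table(cnts, md))
  expect_equal(d2["dup", rownames(tb$counts)[1]], 0)
  # permuting samples conjugates the matrix
  perm <- c(3, 1, 4, 2)
  tbp <- otu_table(tb$counts[perm, ], tb$metadata[perm, ])
  expect_equal(bray_curtis_matrix(tbp), d[perm, perm])
})

test_that("bray_curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  tb <- tiny_table(n_eco = 2, n_rep = 2, n_taxa = 40, depth = 300)
  d <- bray_curtis_matrix(tb)
  dv <- as.matrix(vegan::vegdist(tb$counts, "bray"))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12)
})

test_that("observed_richness counts detected OTUs and shrinks under rarefaction", {
  expect_equal(observed_richness(c(0, 3, 1)), 2)
  expect_equal(observed_richness(rep(0, 5)), 0)
  tb <- tiny_table(n_taxa = 50, depth = 300)
  rich_full <- observed_richness(tb)
  rich_rar <- observed_richness(rarefy(tb, depth = 100, seed = 2))
  expect_true(all(rich_rar <= rich_full))
})

test_that("permanova matches vegan::adonis2 sequential SS on a 6-sample fixture", {
  skip_if_not_installed("vegan")
  tb <- tiny_table(n_eco = 1, n_rep = 3, n_taxa = 25, depth = 150)
  d <- bray_curtis_matrix(tb)
  a <- tb$metadata$treatment
  b <- ifelse(tb$metadata$replicate <= 1, "plotA", "plotB")
  res <- permanova(d, a, b, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ a * b, by = "terms",
                        permutations = 2)
  expect_equal(res$sum_sq[1:4], ref$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(res$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(res$df[1:4], ref$Df[1:4])
})

test_that("permanova separates duplicated groups at maximal distance", {
  # two groups of identical samples, between-group distance 1
  d <- matrix(1, 8, 8) - diag(1, 8)
  grp <- rep(c("g1", "g2"), each = 4)
  d[grp == "g1", grp == "g1"] <- 0
  d[grp == "g2", grp == "g2"] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  b <- rep(c("x", "y"), 4)
  res <- permanova(d, grp, b, n_perm = 999, seed = 2)
  # observed F dominates everything except group-preserving relabelings
  expect_gt(res$pseudo_F[1], 10)
  expect_lte(res$p[1], 8 / 70 + 0.05)
})

test_that("permanova p-values stay on their discrete support and respect seeds", {
  tb <- tiny_table(n_eco = 2, n_rep = 2, n_taxa = 20, depth = 100, seed = 9)
  d <- bray_curtis_matrix(tb)
  res <- permanova(d, tb$metadata$ecosystem, tb$metadata$treatment,
                   n_perm = 99, seed = 5)
  expect_true(all(res$p[1:3] >= 1 / 100 & res$p[1:3] <= 1))
  expect_true(all(abs(res$p[1:3] * 100 - round(res$p[1:3] * 100)) < 1e-9))
  res2 <- permanova(d, tb$metadata$ecosystem, tb$metadata$treatment,
                    n_perm = 99, seed = 5)
  expect_identical(res, res2)
  expect_error(permanova(d, rep("one", 8), tb$metadata$treatment),
               "degenerate factor")
})
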