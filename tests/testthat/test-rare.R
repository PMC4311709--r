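test_that("partition_shared splits detected OTUs into disjoint exhaustive sets", {
  pr <- make_pair(c(5, 1, 0), c(2, 0, 4))
  part <- partition_shared(pr)
  expect_equal(part$shared, "OTU01")
  expect_equal(part$dry_only, "OTU02")
  expect_equal(part$rewet_only, "OTU03")
  # identical samples -> all shared
  pr2 <- make_pair(c(3, 2, 1), c(3, 2, 1))
  expect_length(partition_shared(pr2)$rewet_only, 0)
  expect_length(partition_shared(pr2)$dry_only, 0)
  # conservation on random fixtures
  set.seed(13)
  for (rep in 1:30) {
    d <- stats::rpois(25, 1); r <- stats::rpois(25, 1)
    if (sum(d) == 0 || sum(r) == 0) next
    p <- make_pair(d, r)
    pt <- partition_shared(p)
    union_detected <- sum(p$dry > 0 | p$rewetted > 0)
    expect_equal(length(pt$shared) + length(pt$dry_only) +
                   length(pt$rewet_only), union_detected)
    expect_length(intersect(pt$shared, c(pt$dry_only, pt$rewet_only)), 0)
  }
})

test_that("paired samples are rarefied to the pair minimum depth", {
  pr <- make_pair(c(30, 20, 10), c(5, 3, 2))
  expect_equal(sum(pr$dry), 10)
  expect_equal(sum(pr$rewetted), 10)
  expect_equal(pr$depth, 10)
})

test_that("rare fractions follow their definitions, with two-route cross-check", {
  # rewet {A:2, C:8}, responder C -> sequence fraction 0.8
  pr <- make_pair(c(5, 5, 0), c(2, 0, 8))
  fr <- rare_fractions(pr)
  expect_equal(fr$rare_seq_fraction, 0.8)
  expect_equal(fr$rare_otu_fraction, 0.5)
  # no responders -> (0, 0)
  pr0 <- make_pair(c(3, 2), c(2, 3))
  fr0 <- rare_fractions(pr0)
  expect_equal(fr0$rare_otu_fraction, 0)
  expect_equal(fr0$rare_seq_fraction, 0)
  # all rewetted OTUs new -> (1, 1)
  pr1 <- make_pair(c(4, 0), c(0, 4))
  fr1 <- rare_fractions(pr1)
  expect_equal(fr1$rare_otu_fraction, 1)
  expect_equal(fr1$rare_seq_fraction, 1)
  # independent route: 1 - (rewetted reads of dry-detected OTUs)/depth
  set.seed(23)
  for (rep in 1:20) {
    d <- stats::rpois(30, 1.2); r <- stats::rpois(30, 1.2)
    if (sum(d) == 0 || sum(r) == 0) next
    p <- make_pair(d, r)
    fr <- rare_fractions(p)
    alt <- 1 - sum(p$rewetted[p$dry > 0]) / sum(p$rewetted)
    expect_equal(fr$rare_seq_fraction, alt, tolerance = 1e-12)
  }
})

test_that("singleton/doubleton fraction counts low-abundance shared OTUs", {
  pr <- make_pair(c(1, 2, 5), c(2, 3, 3))
  expect_equal(singleton_doubleton_fraction(pr), 2 / 3)
  expect_equal(singleton_doubleton_fraction(make_pair(c(3, 4), c(4, 3))), 0)
  expect_equal(singleton_doubleton_fraction(make_pair(c(1, 2, 1), c(2, 1, 1))), 1)
  expect_error(singleton_doubleton_fraction(make_pair(c(4, 0), c(0, 4))),
               "shared")
})

test_that("rank_shift ranks by descending count with id tie-break and flags undetected", {
  pr <- make_pair(c(5, 1), c(1, 5))
  rs <- rank_shift(pr)
  expect_equal(rs$dry_rank, c(1L, 2L))
  expect_equal(rs$rewet_rank, c(2L, 1L))
  # tie resolves by ascending OTU id
  prt <- make_pair(c(3, 3), c(2, 4))
  expect_equal(rank_shift(prt)$dry_rank, c(1L, 2L))
  # ranks form a permutation of 1..n_detected; undetected are NA
  set.seed(3)
  for (rep in 1:30) {
    d <- stats::rpois(20, 1); r <- stats::rpois(20, 1)
    if (sum(d) == 0 || sum(r) == 0) next
    rs <- rank_shift(make_pair(d, r))
    det <- !is.na(rs$dry_rank)
    expect_setequal(rs$dry_rank[det], seq_len(sum(det)))
    expect_true(all(is.na(rs$dry_rank[!det])))
  }
})

test_that("dominant_responders applies an inclusive recovery threshold", {
  # responder with 8 reads of depth 100 -> recovery 0.08, dominant
  d <- c(50, 50, rep(0, 1)); r <- c(46, 46, 8)
  pr <- make_pair(d, r)
  dom <- dominant_responders(pr, 0.01)
  expect_equal(dom$otu, "OTU03")
  expect_equal(dom$recovery, 0.08)
  # recovery exactly at the threshold is included
  pr2 <- make_pair(c(50, 50, 0), c(49, 50, 1))
  dom2 <- dominant_responders(pr2, 0.01)
  expect_equal(dom2$otu, "OTU03")
  # none above threshold -> empty
  expect_equal(nrow(dominant_responders(pr2, 0.5)), 0)
  expect_error(dominant_responders(pr, 0), "threshold")
  expect_error(dominant_responders(pr, 1.5), "threshold")
})

test_that("taxon_share reproduces the 13-OTU dominant-responder composition", {
  otus <- sprintf("OTU%02d", 1:13)
  fam <- c(rep("Sphingomonadaceae", 5), rep("Comamonadaceae", 3),
           rep("Oxalobacteraceae", 2), "FamX", "FamY", "FamZ")
  phy <- c(rep("Proteobacteria", 11), "Acidobacteria", "Actinobacteria")
  taxonomy <- stats::setNames(
    paste(phy, "cls", "ord", fam, sep = ";"), otus)
  fs <- taxon_share(otus, taxonomy, level = 4)
  expect_equal(round(100 * fs[["Sphingomonadaceae"]]), 38)
  expect_equal(round(100 * fs[["Comamonadaceae"]]), 23)
  expect_equal(round(100 * fs[["Oxalobacteraceae"]]), 15)
  ps <- taxon_share(otus, taxonomy, level = 1)
  expect_equal(round(100 * ps[["Proteobacteria"]]), 85)
  expect_equal(sum(fs), 1)
  expect_error(taxon_share(otus, taxonomy, level = 9), "level")
})

test_that("taxonomy_recovery_matrix conserves recovery and is deterministic", {
  # single unit, responders all one family: cell equals rare_seq_fraction
  pr <- paired_sample(
    stats::setNames(c(10L, 10L, 0L, 0L), paste0("o", 1:4)),
    stats::setNames(c(6L, 6L, 4L, 4L), paste0("o", 1:4)),
    pair = "E1.1", ecosystem = "E1")
  tax <- stats::setNames(rep("P;C;O;Fam1", 4), paste0("o", 1:4))
  m <- taxonomy_recovery_matrix(list(pr), tax, level = 4)
  expect_equal(unname(m["Fam1", "E1"]),
               rare_fractions(pr)$rare_seq_fraction)
  # two ecosystems with identical inputs -> identical columns
  pr2 <- paired_sample(pr$dry, pr$rewetted, pair = "E2.1", ecosystem = "E2")
  m2 <- taxonomy_recovery_matrix(list(pr, pr2), tax, level = 4)
  expect_equal(m2[, "E1"], m2[, "E2"])
  # missing taxonomy buckets as unclassified
  tax3 <- tax[1:2]
  m3 <- taxonomy_recovery_matrix(list(pr), tax3, level = 4, floor = 0)
  expect_true("unclassified" %in% rownames(m3))
})

test_that("classifier sensitivity against ground truth rises with sequencing depth", {
  sens_at <- function(depth) {
    mean(vapply(1:6, function(sd) {
      p <- seed_bank_params(n_taxa = 500, seq_depth = depth,
                            n_ecosystems = 1, n_replicates = 1, seed = sd)
      sim <- generate_paired_otu_tables(p)
      pr <- pairs_from_table(sim$table, seed = sd)[[1]]
      responder_performance(pr, sim$truth[[1]]$resuscitated)$sensitivity
    }, numeric(1)))
  }
  s <- vapply(c(300, 1500, 8000), sens_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("rare sequence fraction is monotone in the resuscitation growth level", {
  frac_at <- function(glm) {
    mean(vapply(1:6, function(sd) {
      p <- seed_bank_params(n_taxa = 500, seq_depth = 800, n_ecosystems = 1,
                            n_replicates = 1, growth_log_mean = glm,
                            seed = sd)
      sim <- generate_paired_otu_tables(p)
      rare_fractions(pairs_from_table(sim$table, seed = sd)[[1]]
                     )$rare_seq_fraction
    }, numeric(1)))
  }
  f <- vapply(c(-1, 0.8, 2.5), frac_at, numeric(1))
  expect_true(all(diff(f) > 0))
})
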