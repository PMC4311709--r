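#' Paired dry/rewetted sample
#'
#' The atom of the rare-responder analysis: the dry and rewetted count
#' vectors of one experimental unit over a shared OTU universe, rarefied to
#' a common depth so both states have equal detection effort. If the two
#' totals differ, both are rarefied to the pair minimum.
#'
#' @param dry,rewetted named nonnegative integer count vectors over the
#'   same OTU ids.
#' @param pair pair id.
#' @param ecosystem ecosystem label.
#' @param seed seed used when rarefaction to the pair minimum is needed.
#' @return a list of class `paired_sample` with elements `dry`, `rewetted`
#'   (equal-total count vectors), `pair`, `ecosystem`, `depth`.
#' @export
paired_sample <- function(dry, rewetted, pair = NA_character_,
                          ecosystem = NA_character_, seed = 1L) {
  if (length(dry) != length(rewetted))
    stopf("dry and rewetted count vectors must have equal length")
  if (is.null(names(dry))) names(dry) <- paste0("OTU", seq_along(dry))
  if (is.null(names(rewetted))) names(rewetted) <- names(dry)
  if (!identical(names(dry), names(rewetted)))
    stopf("dry and rewetted must share the same OTU universe")
  if (any(dry < 0) || any(rewetted < 0) ||
      any(dry != round(dry)) || any(rewetted != round(rewetted)))
    stopf("counts must be nonnegative integers")
  depth <- min(sum(dry), sum(rewetted))
  if (depth < 1L) stopf("both samples must contain at least one read")
  with_seed(seed, {
    if (sum(dry) > depth)
      dry <- stats::setNames(rarefy_counts(dry, depth), names(dry))
    if (sum(rewetted) > depth)
      rewetted <- stats::setNames(rarefy_counts(rewetted, depth),
                                  names(rewetted))
  })
  structure(list(dry = as.integer(dry) |> stats::setNames(names(dry)),
                 rewetted = as.integer(rewetted) |>
                   stats::setNames(names(rewetted)),
                 pair = pair, ecosystem = ecosystem, depth = depth),
            class = "paired_sample")
}

#' Extract paired samples from an OTU table
#'
#' Splits an [otu_table()] into one [paired_sample()] per pair id, matching
#' the dry and rewetted member of each experimental unit.
#'
#' @param table an [otu_table()] whose metadata carries `treatment`
#'   (`dry`/`rewetted`) and `pair`.
#' @param seed rarefaction seed forwarded to [paired_sample()].
#' @return named list of `paired_sample` objects.
#' @export
pairs_from_table <- function(table, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  md <- table$metadata
  out <- list()
  for (pr in unique(md$pair)) {
    dry_id <- md$sample[md$pair == pr & md$treatment == "dry"]
    rew_id <- md$sample[md$pair == pr & md$treatment == "rewetted"]
    if (length(dry_id) != 1L || length(rew_id) != 1L)
      stopf("pair '%s' does not have exactly one dry and one rewetted sample",
            pr)
    out[[pr]] <- paired_sample(table$counts[dry_id, ],
                               table$counts[rew_id, ],
                               pair = pr,
                               ecosystem = md$ecosystem[md$pair == pr][1L],
                               seed = seed)
  }
  out
}

#' Partition detected OTUs of a pair into shared / dry-only / rewet-only
#'
#' "Detected" means nonzero rarefied count. The rewet-only set — OTUs below
#' detection in the dry sample but recovered after rewetting in the same
#' experimental unit — is the operational rare-responder set.
#'
#' @param pair a [paired_sample()].
#' @return list with disjoint OTU-id vectors `shared`, `dry_only`,
#'   `rewet_only`.
#' @export
partition_shared <- function(pair) {
  stopifnot(inherits(pair, "paired_sample"))
  in_dry <- pair$dry > 0
  in_rew <- pair$rewetted > 0
  ids <- names(pair$dry)
  list(shared = ids[in_dry & in_rew],
       dry_only = ids[in_dry & !in_rew],
       rewet_only = ids[!in_dry & in_rew])
}

#' Rare-responder OTU and sequence fractions
#'
#' `rare_otu_fraction` is the share of OTUs detected in the rewetted sample
#' that were below detection in the dry sample; `rare_seq_fraction` is the
#' share of rewetted reads belonging to those responders.
#'
#' @param pair a [paired_sample()].
#' @return list with `rare_otu_fraction` and `rare_seq_fraction`, both in
#'   \[0, 1\].
#' @export
rare_fractions <- function(pair) {
  stopifnot(inherits(pair, "paired_sample"))
  if (sum(pair$rewetted) == 0)
    stopf("undefined fraction: rewetted sample has no reads")
  part <- partition_shared(pair)
  n_rew <- sum(pair$rewetted > 0)
  list(rare_otu_fraction = length(part$rewet_only) / n_rew,
       rare_seq_fraction = sum(pair$rewetted[part$rewet_only]) /
         sum(pair$rewetted))
}

#' Singleton/doubleton share of the shared pool
#'
#' Among OTUs detected in both states, the fraction represented in the dry
#' sample by only one or two reads — low-abundance members bordering the
#' detection limit.
#'
#' @param pair a [paired_sample()].
#' @return a fraction in \[0, 1\].
#' @export
singleton_doubleton_fraction <- function(pair) {
  stopifnot(inherits(pair, "paired_sample"))
  shared <- partition_shared(pair)$shared
  if (!length(shared))
    stopf("undefined fraction: the shared OTU set is empty")
  sum(pair$dry[shared] <= 2) / length(shared)
}

#' Rank-abundance shift between the dry and rewetted states
#'
#' Ranks detected OTUs within each state by descending count (rank 1 = most
#' abundant), ties broken by ascending OTU id; OTUs below detection are
#' flagged unranked (`NA`). Relative recoveries are counts divided by the
#' sample total.
#'
#' @param pair a [paired_sample()].
#' @return data.frame with columns `otu`, `dry_rank`, `rewet_rank`,
#'   `dry_recovery`, `rewet_recovery`; ranks within each state form a
#'   permutation of 1..(number detected).
#' @export
rank_shift <- function(pair) {
  stopifnot(inherits(pair, "paired_sample"))
  rank_one <- function(x) {
    r <- rep(NA_integer_, length(x))
    det <- which(x > 0)
    ord <- det[order(-x[det], names(x)[det])]
    r[ord] <- seq_along(ord)
    r
  }
  data.frame(otu = names(pair$dry),
             dry_rank = rank_one(pair$dry),
             rewet_rank = rank_one(pair$rewetted),
             dry_recovery = as.numeric(pair$dry) / sum(pair$dry),
             rewet_recovery = as.numeric(pair$rewetted) /
               sum(pair$rewetted),
             row.names = NULL)
}

#' Rare responders that became dominant after rewetting
#'
#' Rewet-only OTUs whose rewetted relative recovery is at least `threshold`
#' (inclusive; default 1%), i.e. rare taxa recruited into dominant roles.
#'
#' @param pair a [paired_sample()].
#' @param threshold dominance threshold on relative recovery, in (0, 1\].
#' @return data.frame with columns `otu`, `recovery`, `rewet_rank`,
#'   ordered by descending recovery.
#' @export
dominant_responders <- function(pair, threshold = 0.01) {
  stopifnot(inherits(pair, "paired_sample"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stopf("`threshold` must lie in (0, 1]")
  part <- partition_shared(pair)
  rs <- rank_shift(pair)
  rec <- stats::setNames(rs$rewet_recovery, rs$otu)
  rnk <- stats::setNames(rs$rewet_rank, rs$otu)
  keep <- part$rewet_only[rec[part$rewet_only] >= threshold]
  out <- data.frame(otu = keep,
                    recovery = as.numeric(rec[keep]),
                    rewet_rank = as.integer(rnk[keep]),
                    row.names = NULL)
  out[order(-out$recovery), , drop = FALSE]
}

#' Full rare-responder report for one pair
#'
#' Bundles the shared/unshared partition, rare fractions,
#' singleton/doubleton share and dominant responders of one experimental
#' unit.
#'
#' @param pair a [paired_sample()].
#' @param threshold dominance threshold forwarded to
#'   [dominant_responders()].
#' @return a list of class `rare_responder_report`.
#' @export
rare_responder_report <- function(pair, threshold = 0.01) {
  part <- partition_shared(pair)
  fr <- rare_fractions(pair)
  sd_frac <- if (length(part$shared))
    singleton_doubleton_fraction(pair) else NA_real_
  structure(c(list(pair = pair$pair, ecosystem = pair$ecosystem,
                   depth = pair$depth),
              part, fr,
              list(singleton_doubleton_fraction = sd_frac,
                   dominant_responders = dominant_responders(pair,
                                                             threshold))),
            class = "rare_responder_report")
}

#' @export
print.rare_responder_report <- function(x, ...) {
  cat(sprintf("<rare_responder_report> pair %s (%s), depth %d\n",
              x$pair, x$ecosystem, x$depth))
  cat(sprintf("  shared %d | dry-only %d | rewet-only (rare responders) %d\n",
              length(x$shared), length(x$dry_only), length(x$rewet_only)))
  cat(sprintf("  rare OTU fraction %.1f%%, rare sequence fraction %.1f%%\n",
              100 * x$rare_otu_fraction, 100 * x$rare_seq_fraction))
  cat(sprintf("  singletons+doubletons among shared: %.1f%%\n",
              100 * x$singleton_doubleton_fraction))
  cat(sprintf("  dominant responders (>= threshold): %d\n",
              nrow(x$dominant_responders)))
  invisible(x)
}

#' Share of OTUs per taxonomic group
#'
#' Fraction of a set of OTUs falling in each group at one lineage level —
#' e.g. the family composition of a dominant-responder set. OTUs missing
#' from the taxonomy are bucketed as `"unclassified"`.
#'
#' @param otus OTU id vector.
#' @param taxonomy named character vector of semicolon-delimited lineages.
#' @param level lineage depth: 1 = phylum ... 4 = family.
#' @return named numeric vector of fractions, descending, summing to 1.
#' @export
taxon_share <- function(otus, taxonomy, level = 4L) {
  level <- check_count(level, "level")
  groups <- lineage_level(otus, taxonomy, level)
  tab <- sort(table(groups), decreasing = TRUE)
  stats::setNames(as.numeric(tab) / length(otus), names(tab))
}

lineage_level <- function(otus, taxonomy, level) {
  if (level > 4L) stopf("unknown lineage level %d (1-4 supported)", level)
  lin <- taxonomy[otus]
  lin[is.na(lin)] <- ""
  vapply(strsplit(lin, ";", fixed = TRUE), function(parts) {
    if (length(parts) >= level && nzchar(parts[level])) parts[level]
    else "unclassified"
  }, character(1))
}

#' Taxonomy-by-ecosystem recovery matrix of rare responders
#'
#' For each ecosystem, the mean over replicate units of the summed rewetted
#' relative recovery of responder OTUs per taxonomic group — the matrix
#' behind a responder-taxonomy heat map. Groups contributing less than
#' `floor` of the total recovery (summed over the matrix) are collapsed
#' into `"other"`.
#'
#' @param pairs list of [paired_sample()] objects (e.g. from
#'   [pairs_from_table()]).
#' @param taxonomy named lineage vector.
#' @param level lineage depth: 1 = phylum ... 4 = family.
#' @param floor minimum share of total recovery for a group to keep its own
#'   row (default 0.01).
#' @return numeric matrix, taxon groups x ecosystems.
#' @export
taxonomy_recovery_matrix <- function(pairs, taxonomy, level = 1L,
                                     floor = 0.01) {
  level <- check_count(level, "level")
  if (level > 4L) stopf("unknown lineage level %d (1-4 supported)", level)
  per_unit <- lapply(pairs, function(pair) {
    part <- partition_shared(pair)
    rec <- pair$rewetted[part$rewet_only] / sum(pair$rewetted)
    grp <- lineage_level(part$rewet_only, taxonomy, level)
    tapply(as.numeric(rec), grp, sum)
  })
  ecosystems <- vapply(pairs, function(p) p$ecosystem, character(1))
  groups <- sort(unique(unlist(lapply(per_unit, names))))
  eco_levels <- unique(ecosystems)
  m <- matrix(0, length(groups), length(eco_levels),
              dimnames = list(groups, eco_levels))
  cnt <- stats::setNames(integer(length(eco_levels)), eco_levels)
  for (i in seq_along(per_unit)) {
    e <- ecosystems[i]
    v <- per_unit[[i]]
    m[names(v), e] <- m[names(v), e] + as.numeric(v)
    cnt[e] <- cnt[e] + 1L
  }
  m <- sweep(m, 2L, pmax(cnt, 1L), "/")
  total <- sum(m)
  if (total > 0 && length(groups) > 1L) {
    minor <- rowSums(m) / total < floor
    if (any(minor)) {
      other <- colSums(m[minor, , drop = FALSE])
      m <- rbind(m[!minor, , drop = FALSE], other = other)
    }
  }
  m
}

#' Classifier performance against simulation ground truth
#'
#' Sensitivity and specificity of the rare-responder classification of a
#' pair relative to the generator's ground-truth resuscitated set:
#' sensitivity = resuscitated taxa classified rewet-only / resuscitated
#' taxa; specificity = non-resuscitated taxa not classified rewet-only /
#' non-resuscitated taxa.
#'
#' @param pair a [paired_sample()].
#' @param resuscitated ground-truth resuscitated OTU ids for the pair.
#' @return list with `sensitivity`, `specificity`, `n_called`.
#' @export
responder_performance <- function(pair, resuscitated) {
  part <- partition_shared(pair)
  called <- part$rewet_only
  all_ids <- names(pair$dry)
  pos <- intersect(resuscitated, all_ids)
  neg <- setdiff(all_ids, pos)
  list(sensitivity = if (length(pos)) length(intersect(called, pos)) /
         length(pos) else NA_real_,
       specificity = length(setdiff(neg, called)) / length(neg),
       n_called = length(called))
}
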