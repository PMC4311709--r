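#' OTU count table with sample metadata and taxonomy
#'
#' The central container of the community analyses: an integer count matrix
#' (samples in rows, OTUs in columns), per-sample metadata (ecosystem,
#' treatment, replicate, pair id) and an optional per-OTU semicolon-delimited
#' lineage ("Phylum;Class;Order;Family").
#'
#' @param counts nonnegative integer matrix, samples x OTUs, with rownames
#'   (sample ids) and colnames (OTU ids).
#' @param metadata data.frame with columns `sample`, `ecosystem`,
#'   `treatment`, `replicate`, `pair`; one row per sample, rows matched to
#'   `counts` by sample id.
#' @param taxonomy optional named character vector of lineages, names = OTU
#'   ids.
#'
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("`counts` must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("`counts` must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample id: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate OTU id: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("`counts` must be nonnegative integers")
  storage.mode(counts) <- "integer"
  need <- c("sample", "ecosystem", "treatment", "replicate", "pair")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stopf("`metadata` must contain columns: %s", paste(need, collapse = ", "))
  if (!setequal(metadata$sample, rownames(counts)))
    stopf("`metadata$sample` must match the rownames of `counts`")
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stopf("`taxonomy` must be a named character vector (names = OTU ids)")
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
  }
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  treatments: %s\n",
              paste(unique(x$metadata$treatment), collapse = ", ")))
  cat(sprintf("  ecosystems: %s\n",
              paste(unique(x$metadata$ecosystem), collapse = ", ")))
  cat(sprintf("  taxonomy: %s\n",
              if (is.null(x$taxonomy)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample read totals of an OTU table
#'
#' @param table an [otu_table()].
#' @return named integer vector of per-sample read totals.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rowSums(table$counts)
}
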