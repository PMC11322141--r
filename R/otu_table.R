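#' OTU count table with sample metadata
#'
#' Container for an OTU-by-sample matrix of sequencing counts plus per-sample
#' metadata (sampling day, sampling port, nutrient stage) and optional
#' taxonomic lineages. This is the unit of data every preprocessing and
#' network-construction step consumes.
#'
#' @param counts non-negative integer matrix, rows = OTUs, columns = samples.
#'   Row and column names are used as OTU and sample identifiers; they must be
#'   unique and non-empty.
#' @param metadata data.frame with one row per sample and columns `sample`,
#'   `day` (integer), `port` (character) and `stage` (`"high"` or `"low"`).
#' @param taxonomy optional named character vector of lineage strings
#'   (QIIME-style `"k__...; p__...; ..."`), named by OTU id.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `metadata` and `taxonomy`.
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("`counts` must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate OTU identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers in count matrix")
  if (any(is.na(counts)) || any(counts < 0))
    stopf("counts must be non-negative and non-missing")
  if (any(counts != floor(counts)))
    stopf("counts must be integers")
  storage.mode(counts) <- "double"  # keeps counts > .Machine$integer.max safe

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample", "day", "port", "stage")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample))
    stopf("duplicate sample identifiers in metadata")
  extra_tab <- setdiff(colnames(counts), metadata$sample)
  extra_meta <- setdiff(metadata$sample, colnames(counts))
  if (length(extra_tab))
    stopf("sample(s) in count table but not metadata: %s",
          paste(extra_tab, collapse = ", "))
  if (length(extra_meta))
    stopf("sample(s) in metadata but not count table: %s",
          paste(extra_meta, collapse = ", "))
  if (!all(metadata$stage %in% c("high", "low")))
    stopf("metadata$stage must be 'high' or 'low'")
  metadata <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata$day <- as.integer(metadata$day)
  metadata$port <- as.character(metadata$port)

  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stopf("taxonomy must be named by OTU id")
    taxonomy <- taxonomy[rownames(counts)]
    names(taxonomy) <- rownames(counts)
  }
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  st <- table(x$metadata$stage)
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  cat(sprintf("  days %d..%d, %d ports; taxonomy %s\n",
              min(x$metadata$day), max(x$metadata$day),
              length(unique(x$metadata$port)),
              if (is.null(x$taxonomy)) "absent" else "attached"))
  invisible(x)
}

#' @export
summary.otu_table <- function(object, ...) {
  tot <- colSums(object$counts)
  cat(sprintf("OTU table: %d OTUs x %d samples\n",
              nrow(object$counts), ncol(object$counts)))
  cat(sprintf("  sample depth: min %g, median %g, max %g\n",
              min(tot), stats::median(tot), max(tot)))
  cat(sprintf("  OTUs observed per sample: median %g\n",
              stats::median(colSums(object$counts > 0))))
  invisible(object)
}

n_otus <- function(x) nrow(x$counts)
n_samples <- function(x) ncol(x$counts)

#' Subset an OTU table by samples
#'
#' @param x `otu_table`
#' @param samples character vector of sample ids (or logical/integer index
#'   over columns).
#' @return `otu_table` restricted to the chosen samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts[, samples, drop = FALSE]
  meta <- x$metadata[match(colnames(counts), x$metadata$sample), , drop = FALSE]
  otu_table(counts, meta, x$taxonomy)
}

#' Read an OTU table and its sample metadata from TSV files
#'
#' Expects a QIIME-style feature table: first column `#OTU ID`, remaining
#' columns one per sample, tab-separated. Metadata is a TSV with columns
#' `sample`, `day`, `port`, `stage`. Sample sets in the two files must agree
#' exactly.
#'
#' @param path OTU table TSV path.
#' @param metadata_path metadata TSV path.
#' @param taxonomy_path optional taxonomy TSV (columns `otu`, `lineage`).
#' @return validated [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path, taxonomy_path = NULL) {
  for (p in c(path, metadata_path, taxonomy_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) >= 2L) stopf("OTU table %s has no sample columns", path)
  otus <- as.character(tab[[1L]])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stopf("non-numeric counts in %s", path)
  rownames(counts) <- otus
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    taxonomy <- stats::setNames(as.character(tx[[2L]]), as.character(tx[[1L]]))
  }
  otu_table(counts, meta, taxonomy)
}

#' Write an OTU table (and metadata/taxonomy) to TSV files
#'
#' Inverse of [read_otu_table()]; a write-then-read round trip reproduces the
#' object exactly.
#'
#' @param x `otu_table`
#' @param path,metadata_path,taxonomy_path output TSV paths (taxonomy written
#'   only if the table carries one and a path is given).
#' @return invisibly, the paths written.
#' @export
write_otu_table <- function(x, path, metadata_path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(`#OTU ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(path, metadata_path)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    utils::write.table(
      data.frame(otu = names(x$taxonomy), lineage = unname(x$taxonomy),
                 stringsAsFactors = FALSE),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, taxonomy_path)
  }
  invisible(written)
}
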