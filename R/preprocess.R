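#' Per-sample relative abundances
#'
#' Converts counts to proportions column by column; each sample's proportions
#' sum to one.
#'
#' @param x `otu_table` or an OTU-by-sample count matrix.
#' @return matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0]
    stopf("sample(s) with zero total count: %s", paste(bad, collapse = ", "))
  }
  sweep(m, 2L, tot, "/")
}

#' Remove low-abundance OTUs
#'
#' Drops sparse OTUs ahead of correlation analysis. The default criterion
#' retains an OTU when its mean relative abundance across all samples is at
#' least `threshold` (default 0.01\%); OTUs strictly below the threshold are
#' removed. Alternatives: `"max"` (maximum per-sample relative abundance) and
#' `"pooled"` (abundance of pooled counts over all samples).
#'
#' @param x `otu_table`.
#' @param threshold proportion in \[0, 1\]; default `1e-4`.
#' @param criterion `"mean"` (default), `"max"`, or `"pooled"`.
#' @return filtered `otu_table`; the sample set is unchanged.
#' @export
filter_low_abundance <- function(x, threshold = 1e-4,
                                 criterion = c("mean", "max", "pooled")) {
  stopifnot(inherits(x, "otu_table"))
  criterion <- match.arg(criterion)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stopf("`threshold` must be a proportion in [0, 1]")
  rel <- relative_abundance(x)
  score <- switch(criterion,
    mean = rowMeans(rel),
    max = apply(rel, 1L, max),
    pooled = rowSums(x$counts) / sum(x$counts))
  keep <- score >= threshold
  otu_table(x$counts[keep, , drop = FALSE], x$metadata,
            if (is.null(x$taxonomy)) NULL else x$taxonomy[keep])
}

#' Rarefy samples to a common depth
#'
#' Randomly subsamples each sample's reads without replacement to exactly
#' `depth` reads (one draw per sample). Samples whose total count is below
#' `depth` are dropped with a warning listing them. Deterministic for a given
#' `seed`.
#'
#' @param x `otu_table`.
#' @param depth target reads per sample; default 41051.
#' @param seed integer RNG seed (required: rarefaction is stochastic).
#' @return rarefied `otu_table` in which every sample totals exactly `depth`.
#' @export
rarefy <- function(x, depth = 41051, seed) {
  stopifnot(inherits(x, "otu_table"))
  if (!is_count(depth)) stopf("`depth` must be a positive integer")
  if (missing(seed)) stopf("`seed` is required for rarefaction")
  tot <- colSums(x$counts)
  drop <- tot < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(colnames(x$counts)[drop], collapse = ", ")),
            call. = FALSE)
  if (all(drop)) stopf("no sample reaches rarefaction depth %d", depth)
  m <- x$counts[, !drop, drop = FALSE]
  # vegan warns about "observed counts" whenever the smallest nonzero count
  # exceeds 1; that is expected for deep samples, so silence it
  rar <- with_seed(seed, suppressWarnings(vegan::rrarefy(t(m), sample = depth)))
  counts <- t(rar)
  dimnames(counts) <- dimnames(m)
  meta <- x$metadata[!drop, , drop = FALSE]
  otu_table(counts, meta, x$taxonomy)
}
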