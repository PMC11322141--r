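#' Per-sample alpha diversity
#'
#' Computes a within-sample diversity metric for every sample. Shannon
#' diversity is reported in bits (log base 2 on relative abundances) by
#' default; Simpson is the Gini-Simpson index 1 - sum(p^2); Pielou evenness is
#' Shannon divided by log2 of the observed richness (NA for single-OTU
#' samples, where evenness is undefined).
#'
#' @param x `otu_table`.
#' @param metric one of `"shannon"`, `"observed_otus"`, `"simpson"`,
#'   `"pielou_evenness"`.
#' @param base logarithm base for Shannon/Pielou; default 2.
#' @return data.frame with columns `sample`, `metric`, `value`, plus the
#'   sample metadata columns (`day`, `port`, `stage`).
#' @export
alpha_diversity <- function(x,
                            metric = c("shannon", "observed_otus", "simpson",
                                       "pielou_evenness"),
                            base = 2) {
  stopifnot(inherits(x, "otu_table"))
  metric <- match.arg(metric)
  m <- t(x$counts)  # vegan convention: rows = samples
  value <- switch(metric,
    shannon = vegan::diversity(m, index = "shannon", base = base),
    simpson = vegan::diversity(m, index = "simpson"),
    observed_otus = rowSums(m > 0),
    pielou_evenness = {
      h <- vegan::diversity(m, index = "shannon", base = base)
      s <- rowSums(m > 0)
      ifelse(s > 1, h / log(s, base = base), NA_real_)
    })
  out <- data.frame(sample = colnames(x$counts), metric = metric,
                    value = as.numeric(value), stringsAsFactors = FALSE)
  cbind(out, x$metadata[, c("day", "port", "stage"), drop = FALSE])
}
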