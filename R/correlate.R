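#' All-pairs Spearman correlation with t-approximation p-values
#'
#' Computes Spearman's rho for every pair of variables (rows) as the Pearson
#' correlation of mid-ranks (average ranks for ties), with a two-sided
#' p-value from the t-approximation `t = rho * sqrt((n-2) / (1-rho^2))` on
#' `n - 2` degrees of freedom. Variables with zero variance (constant across
#' samples) cannot carry rank information: they are flagged, and get rho = 0
#' and p = 1 against every partner.
#'
#' @param m numeric matrix, rows = variables, columns = samples (at least 4
#'   samples and 2 variables).
#' @return object of class `correlation_result`: list with symmetric matrices
#'   `rho` (unit diagonal), `p_raw`, `p_adj` (Benjamini-Hochberg over the
#'   `V(V-1)/2` distinct pairs, see [fdr_adjust()]), `n_samples`,
#'   `variable_ids`, and `constant` (logical flag per variable).
#' @export
spearman_all_pairs <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  if (nrow(m) < 2L) stopf("need at least 2 variables")
  n <- ncol(m)
  if (n < 4L) stopf("need at least 4 samples for correlation p-values")
  ranks <- t(apply(m, 1L, rank, ties.method = "average"))
  constant <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(t(ranks)))  # Pearson on mid-ranks
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  rho <- pmin(pmax(rho, -1), 1)

  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tstat[abs(rho) >= 1] <- Inf * sign(rho[abs(rho) >= 1])
  p_raw <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p_raw[constant, ] <- 1
  p_raw[, constant] <- 1
  diag(p_raw) <- 0
  dimnames(p_raw) <- dimnames(rho)

  res <- structure(
    list(rho = rho, p_raw = p_raw, p_adj = NULL, n_samples = n,
         variable_ids = rownames(m), constant = constant),
    class = "correlation_result")
  res$p_adj <- fdr_adjust(res)$p_adj
  res
}

#' Benjamini-Hochberg adjustment over distinct variable pairs
#'
#' Applies the BH step-up procedure to the raw p-values of the upper-triangle
#' pairs (`m = V(V-1)/2` tests), then mirrors the adjusted values into a
#' symmetric matrix. Adjusted values are clipped at 1 and are never smaller
#' than the raw values.
#'
#' @param x a `correlation_result`, or a symmetric matrix of raw p-values.
#' @return for a `correlation_result`, the object with `p_adj` filled; for a
#'   matrix, the symmetric matrix of adjusted p-values.
#' @export
fdr_adjust <- function(x) {
  p <- if (inherits(x, "correlation_result")) x$p_raw else as.matrix(x)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  ut <- upper.tri(p)
  adj <- p
  adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  if (inherits(x, "correlation_result")) {
    x$p_adj <- adj
    x
  } else adj
}

#' @export
print.correlation_result <- function(x, ...) {
  v <- length(x$variable_ids)
  cat(sprintf("Spearman correlation over %d variables (%d pairs), n = %d samples\n",
              v, v * (v - 1) / 2, x$n_samples))
  if (any(x$constant))
    cat(sprintf("  %d zero-variance variable(s) flagged\n", sum(x$constant)))
  invisible(x)
}
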