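# Count-matrix normalization, gene filtering, and the transformations applied
# before Gaussian-mixture comparators. All functions take and return the
# canonical samples x genes numeric matrix with sample ids in rownames and
# gene ids in colnames.

#' Upper-quartile normalized counts per million
#'
#' Library-size normalization for raw counts: each sample's scaling factor is
#' the 75th percentile of its nonzero counts relative to its total count
#' (i.e. the upper quartile of `x / sum(x)` over expressed genes); factors
#' are rescaled to have geometric mean 1; the effective library size is total
#' count times factor; the output is `1e6 * x / effective library size`, per
#' sample. Basing the factor on depth-relative counts makes the result
#' invariant to multiplying any single sample's counts by a positive
#' constant, which raw-count quantiles would not be.
#'
#' @param x Samples-by-genes matrix of raw non-negative counts; every sample
#'   must have at least one nonzero gene.
#'
#' @return Matrix of upper-quartile normalized CPM values, same shape and
#'   dimnames as `x`.
#' @export
#' @examples
#' m <- rbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8))
#' upper_quartile_cpm(m)  # identical rows: scaling removes depth differences
upper_quartile_cpm <- function(x) {
  x <- as_count_matrix(x)
  lib <- rowSums(x)
  if (any(lib == 0)) {
    stop("Sample(s) with all-zero counts: ",
         paste(rownames(x)[lib == 0], collapse = ", "), call. = FALSE)
  }
  uq <- vapply(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    stats::quantile(r[r > 0] / lib[i], 0.75, names = FALSE)
  }, numeric(1))
  fac <- uq / exp(mean(log(uq)))  # geometric mean 1
  eff <- lib * fac
  out <- 1e6 * x / eff
  dimnames(out) <- dimnames(x)
  out
}

#' Keep the most variable genes by median absolute deviation
#'
#' Ranks genes by MAD across samples, `median_i |x_ig - median_i(x_ig)|`
#' (without the normal-consistency constant; the ranking is scale-invariant
#' either way), and keeps the `top_n` largest. Ties keep the original gene
#' order; sample order is preserved; selected genes are returned in
#' descending-MAD order.
#'
#' @param x Samples-by-genes numeric matrix.
#' @param top_n Number of genes to keep (<= number of genes).
#'
#' @return The filtered matrix with `top_n` columns.
#' @export
mad_top_genes <- function(x, top_n = 1000) {
  x <- as_count_matrix(x)
  if (top_n > ncol(x)) {
    stop(sprintf("`top_n` (%d) exceeds the number of genes (%d).",
                 top_n, ncol(x)), call. = FALSE)
  }
  mads <- apply(x, 2, function(g) stats::median(abs(g - stats::median(g))))
  keep <- order(-mads)[seq_len(top_n)]  # order() breaks ties by position
  x[, keep, drop = FALSE]
}

#' Elementwise log transform with pseudocount
#'
#' `log(x + pseudocount)`, natural log. A positive pseudocount is required
#' whenever zeros are present.
#'
#' @param x Samples-by-genes numeric matrix.
#' @param pseudocount Added before taking logs (default 1).
#'
#' @return Transformed matrix, same shape and dimnames.
#' @export
log_transform <- function(x, pseudocount = 1) {
  x <- as_count_matrix(x)
  if (pseudocount < 0) stop("`pseudocount` must be >= 0.", call. = FALSE)
  if (pseudocount == 0 && any(x == 0)) {
    stop("Zero entries present; use a positive `pseudocount`.", call. = FALSE)
  }
  log(x + pseudocount)
}

#' Rank-based inverse-normal (Blom) transform
#'
#' Per gene, sample values are replaced by normal scores:
#' `qnorm((r_i - 3/8) / (N + 1/4))` where `r_i` is the within-gene rank of
#' sample i (ties get average ranks). The middle observation of an odd-length
#' gene maps to 0; each transformed gene is approximately standard normal.
#'
#' @param x Samples-by-genes numeric matrix with >= 2 samples.
#'
#' @return Transformed matrix (entries may be negative), same shape and
#'   dimnames as `x`.
#' @export
blom_transform <- function(x) {
  x <- as_count_matrix(x)
  n <- nrow(x)
  if (n < 2) stop("Need at least 2 samples.", call. = FALSE)
  out <- apply(x, 2, function(g) stats::qnorm((rank(g) - 3 / 8) / (n + 1 / 4)))
  dimnames(out) <- dimnames(x)
  out
}
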