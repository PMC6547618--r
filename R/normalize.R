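#' Log2 counts-per-million with pseudocount
#'
#' `logCPM = log2((count + pseudocount) / (libsize + 2 * pseudocount) * 1e6)`
#' where the library size is the column sum of the raw counts. The
#' pseudocount keeps zero counts finite and the transform strictly monotone
#' in the count within a sample.
#'
#' @param counts A [paired_counts()] object or a non-negative numeric matrix
#'   (features x samples).
#' @param pseudocount Positive prior count added to every observation
#'   (default 0.5, the common logCPM convention).
#'
#' @return Numeric matrix of logCPM values, same dimnames as the counts.
#' @export
#' @examples
#' m <- matrix(c(0, 10, 999989, 1000, 0, 999000), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' log_cpm(m)
log_cpm <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "paired_counts")) counts <- counts$counts
  stopifnot_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  libsize <- colSums(counts)
  zero <- libsize <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  t(log2(t(counts + pseudocount) / (libsize + 2 * pseudocount) * 1e6))
}

#' Quantile normalization
#'
#' Forces every column of the matrix onto a common reference distribution:
#' the across-column mean of sorted values. Rank order within each column is
#' preserved; tied values within a column receive the mean of the reference
#' values spanned by the tie, so the output is deterministic.
#'
#' @param m Numeric matrix with at least two columns and finite entries.
#' @return Matrix of the same shape; after the transform every column holds
#'   the same multiset of values.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 6), nrow = 2)
#' quantile_normalize(m)  # both columns become (1.5, 4.5)
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`m` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in input", call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    # consecutive runs of equal values in sort order share the mean of the
    # reference values over the tied rank span
    grp <- cumsum(!duplicated(x[o]))
    out[o, j] <- stats::ave(ref, grp)
  }
  out
}
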