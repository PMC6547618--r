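#' Paired count matrix with tumor/normal manifest
#'
#' Container for a raw feature-by-sample count matrix together with the
#' patient manifest pairing each patient's tumor and normal sample. This is
#' the input object of the differential-expression stage.
#'
#' @param counts Non-negative integer matrix, features in rows, samples in
#'   columns; row and column names must be unique identifiers.
#' @param manifest Data frame with columns `patient_id`, `tumor_sample`,
#'   `normal_sample`. Every referenced sample must be a column of `counts`,
#'   each sample may appear at most once across the whole manifest, and a
#'   patient's tumor and normal sample must differ.
#'
#' @return An object of class `paired_counts`: a list with elements `counts`
#'   and `manifest`.
#' @export
#' @examples
#' cnt <- matrix(rpois(12, 20), nrow = 3,
#'               dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' man <- data.frame(patient_id = c("p1", "p2"),
#'                   tumor_sample = c("s1", "s3"),
#'                   normal_sample = c("s2", "s4"))
#' paired_counts(cnt, man)
paired_counts <- function(counts, manifest) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs feature (row) and sample (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids in `counts`", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in `counts`", call. = FALSE)
  }
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  req <- c("patient_id", "tumor_sample", "normal_sample")
  if (!all(req %in% names(manifest))) {
    stop("`manifest` needs columns patient_id, tumor_sample, normal_sample",
         call. = FALSE)
  }
  manifest <- manifest[, req]
  if (anyDuplicated(manifest$patient_id)) {
    stop("duplicate patient ids in manifest", call. = FALSE)
  }
  if (any(manifest$tumor_sample == manifest$normal_sample)) {
    stop("tumor and normal sample must differ for every patient",
         call. = FALSE)
  }
  used <- c(manifest$tumor_sample, manifest$normal_sample)
  if (anyDuplicated(used)) {
    stop("a sample appears more than once in the manifest", call. = FALSE)
  }
  missing <- setdiff(used, colnames(counts))
  if (length(missing)) {
    stop("manifest samples absent from counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, manifest = manifest),
            class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("paired_counts: %d features x %d samples, %d patient pairs\n",
              nrow(x$counts), ncol(x$counts), nrow(x$manifest)))
  invisible(x)
}

#' Read / write count and expression matrices as TSV
#'
#' The TSV layout has `feature_id` as the first column and one column per
#' sample thereafter; `read_manifest_tsv()` expects columns `patient_id`,
#' `tumor_sample`, `normal_sample`.
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with feature row
#'   names; `read_manifest_tsv()` returns a data frame.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix with feature row names and sample column names.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @export
read_manifest_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_matrix_tsv
#' @param manifest Manifest data frame.
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @param manifest_path Path of the manifest TSV accompanying the counts.
#' @export
read_paired_counts <- function(path, manifest_path) {
  m <- read_matrix_tsv(path)
  paired_counts(m, read_manifest_tsv(manifest_path))
}
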