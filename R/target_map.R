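#' miRNA-target relation map
#'
#' A set of (miRNA, gene) relations with provenance (`"validated"`,
#' `"predicted:<source>"`, or `"mlr"`) and an optional score. Duplicate
#' (miRNA, gene, provenance) triples are collapsed.
#'
#' @param relations Data frame with columns `mirna_id`, `gene_id`,
#'   `provenance` and optionally `score`.
#' @return Data frame of class `target_map`.
#' @export
target_map <- function(relations) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "provenance")
  if (!all(need %in% names(relations))) {
    stop("`relations` must have columns mirna_id, gene_id, provenance",
         call. = FALSE)
  }
  if (!"score" %in% names(relations)) relations$score <- NA_real_
  relations <- relations[, c(need, "score")]
  dup <- duplicated(relations[, need])
  relations <- relations[!dup, , drop = FALSE]
  rownames(relations) <- NULL
  class(relations) <- c("target_map", "data.frame")
  relations
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d relations, %d miRNAs, %d genes\n",
              nrow(x), length(unique(x$mirna_id)),
              length(unique(x$gene_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Merge validated, program-consensus and score-filtered target lists
#'
#' Compiles one target map from three kinds of sources, mirroring the
#' standard knowledgebase merge: (i) validated relations are always kept;
#' (ii) relations predicted by at least `min_support` of the supplied
#' prediction programs are kept (default 3, the "three or more programs"
#' rule); (iii) relations from a scored list (TargetScan-style) are kept
#' when their score passes `ts_threshold`. The published recommendation
#' compares the cumulative weighted context score with `> 0.2`; because the
#' usual TargetScan convention is that more-negative context scores mean
#' stronger targeting, the comparison direction is configurable via
#' `ts_keep_greater` rather than silently resolved.
#'
#' @param validated List of [target_map()]s (or `NULL`) with knowledgebase
#'   relations.
#' @param predicted List of [target_map()]s, one per prediction program.
#' @param scored A scored [target_map()] (or `NULL`).
#' @param min_support Minimum number of distinct prediction programs
#'   supporting a relation (>= 1).
#' @param ts_threshold Score threshold for the scored list.
#' @param ts_keep_greater If `TRUE` (default) keep `score > ts_threshold`,
#'   otherwise keep `score < ts_threshold`.
#' @return A [target_map()]; provenance is preserved per supporting source
#'   for audit, so one (miRNA, gene) relation may occupy several rows.
#' @export
merge_target_maps <- function(validated = list(), predicted = list(),
                              scored = NULL, min_support = 3,
                              ts_threshold = 0.2, ts_keep_greater = TRUE) {
  if (min_support < 1) stop("`min_support` must be >= 1", call. = FALSE)
  pieces <- list()

  if (length(validated)) {
    for (v in validated) pieces[[length(pieces) + 1L]] <- as.data.frame(v)
  }

  if (length(predicted)) {
    # count distinct programs per (mirna, gene)
    per_prog <- lapply(predicted, function(p) {
      p <- as.data.frame(p)
      unique(p[, c("mirna_id", "gene_id", "provenance", "score")])
    })
    all_pred <- do.call(rbind, per_prog)
    key <- paste(all_pred$mirna_id, all_pred$gene_id, sep = "\r")
    prog_of_row <- rep(seq_along(per_prog),
                       vapply(per_prog, nrow, integer(1)))
    support <- tapply(prog_of_row, key, function(x) length(unique(x)))
    keep_keys <- names(support)[support >= min_support]
    pieces[[length(pieces) + 1L]] <-
      all_pred[key %in% keep_keys, , drop = FALSE]
  }

  if (!is.null(scored)) {
    sc <- as.data.frame(scored)
    keep <- if (ts_keep_greater) sc$score > ts_threshold
            else sc$score < ts_threshold
    keep[is.na(keep)] <- FALSE
    pieces[[length(pieces) + 1L]] <- sc[keep, , drop = FALSE]
  }

  if (!length(pieces)) {
    return(target_map(data.frame(mirna_id = character(0),
                                 gene_id = character(0),
                                 provenance = character(0),
                                 score = numeric(0))))
  }
  target_map(do.call(rbind, pieces))
}

#' Read / write target maps as 4-column TSV
#'
#' Columns `mirna_id`, `gene_id`, `provenance`, `score`.
#'
#' @param path File path.
#' @return A [target_map()].
#' @export
read_target_map_tsv <- function(path) {
  target_map(utils::read.delim(path, stringsAsFactors = FALSE,
                               comment.char = "#"))
}

#' @rdname read_target_map_tsv
#' @param map A [target_map()].
#' @export
write_target_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
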