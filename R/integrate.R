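#' Anticorrelated miRNA-gene regulatory pairs
#'
#' Builds the set of (DEmiR, DEG) pairs satisfying the three integration
#' conditions: both members are differentially expressed, their
#' tumor-vs-normal directions are opposite, and the relation is present in
#' the target map.
#'
#' @param demirs Data frame of called miRNAs with columns `feature_id` and
#'   `direction` (`"up"`/`"down"`), e.g. the called rows of
#'   [select_de_features()].
#' @param degs Same layout for called genes.
#' @param targets A [target_map()].
#' @return Data frame `mirna_id`, `mirna_dir`, `gene_id`, `gene_dir`,
#'   `provenance` (sources collapsed with `","` per relation), one row per
#'   (miRNA, gene) pair. The attribute `summary` holds the pair count and
#'   the distinct miRNA/gene counts split by direction.
#' @export
anticorrelated_pairs <- function(demirs, degs, targets) {
  mir_dir <- setNames(demirs$direction, demirs$feature_id)
  gene_dir <- setNames(degs$direction, degs$feature_id)
  tg <- as.data.frame(targets)

  # collapse provenance per relation
  key <- paste(tg$mirna_id, tg$gene_id, sep = "\r")
  prov <- tapply(tg$provenance, key,
                 function(x) paste(sort(unique(x)), collapse = ","))
  rel <- unique(tg[, c("mirna_id", "gene_id")])
  rel$provenance <- as.character(
    prov[paste(rel$mirna_id, rel$gene_id, sep = "\r")])

  keep <- rel$mirna_id %in% names(mir_dir) &
    rel$gene_id %in% names(gene_dir)
  rel <- rel[keep, , drop = FALSE]
  md <- mir_dir[rel$mirna_id]
  gd <- gene_dir[rel$gene_id]
  opp <- (md == "up" & gd == "down") | (md == "down" & gd == "up")
  out <- data.frame(mirna_id = rel$mirna_id[opp],
                    mirna_dir = unname(md[opp]),
                    gene_id = rel$gene_id[opp],
                    gene_dir = unname(gd[opp]),
                    provenance = rel$provenance[opp],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    n_pairs = nrow(out),
    n_mirnas = length(unique(out$mirna_id)),
    n_genes = length(unique(out$gene_id)),
    n_mirnas_up = length(unique(out$mirna_id[out$mirna_dir == "up"])),
    n_mirnas_down = length(unique(out$mirna_id[out$mirna_dir == "down"])),
    n_genes_up = length(unique(out$gene_id[out$gene_dir == "up"])),
    n_genes_down = length(unique(out$gene_id[out$gene_dir == "down"]))
  )
  out
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes. Tolerant of
#' CRLF line endings and empty trailing fields.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; the `description` attribute
#'   keeps the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set: with universe size N, set size K (after intersecting the
#' set with the universe), query size n and overlap k, the one-sided
#' enrichment p-value is the upper hypergeometric tail `P(X >= k)`.
#' Benjamini-Hochberg adjustment is applied across all sets tested for the
#' query, and rows are sorted by q-value. Depletion is not tested.
#'
#' @param query Character vector of genes (intersected with the universe).
#' @param gene_sets Named list of character vectors, e.g. from
#'   [read_gmt()].
#' @param universe Character vector of background genes (non-empty); the
#'   standard choice is all expressed genes entering the DE analysis.
#' @param query_direction Optional label (`"up"`/`"down"`) carried into the
#'   output.
#' @return Data frame `set_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `query_direction`, sorted by `q` then `p`.
#' @export
hypergeometric_enrich <- function(query, gene_sets, universe,
                                  query_direction = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(intersect(query, universe))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$query_direction <- query_direction
  out <- out[order(out$q, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
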