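# Independent brute-force oracles used across the suite. These deliberately
# take the slow, literal route so that they share no code with the package
# implementations they check.

# O(m^2) Benjamini-Hochberg step-up: q_i = min over {j: p_j >= p_i} of
# m * p_j / rank(p_j), clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) {
      m * p[j] / sum(p <= p[j])
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Exhaustive per-offset seed-site scan: tests every UTR offset against the
# three patterns, applying type priority 8mer > 7mer-m8 > 7mer-A1 per locus
# and suppressing the 7mer-A1 that forms the tail of an 8mer.
oracle_scan <- function(mirna, utr) {
  p8 <- paste0(oracle_revcomp(substr(mirna, 2, 8)), "A")
  p7m8 <- oracle_revcomp(substr(mirna, 2, 8))
  p7a1 <- paste0(oracle_revcomp(substr(mirna, 2, 7)), "A")
  L <- nchar(utr)
  hits <- list()
  starts8 <- integer(0)
  for (s in seq_len(max(L - 8 + 1, 0))) {
    if (substr(utr, s, s + 7) == p8) starts8 <- c(starts8, s)
  }
  for (s in starts8) {
    hits[[length(hits) + 1]] <- data.frame(start = s - 1L,
                                           site_type = "8mer")
  }
  for (s in seq_len(max(L - 7 + 1, 0))) {
    seg <- substr(utr, s, s + 6)
    if (s %in% starts8) next
    if (seg == p7m8) {
      hits[[length(hits) + 1]] <- data.frame(start = s - 1L,
                                             site_type = "7mer-m8")
    } else if (seg == p7a1 && !((s - 1) %in% starts8)) {
      hits[[length(hits) + 1]] <- data.frame(start = s - 1L,
                                             site_type = "7mer-A1")
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), site_type = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

# Naive set-comprehension consensus: all three q-values at or below the cut.
oracle_consensus <- function(q, cut) {
  vapply(seq_len(nrow(q)), function(i) {
    all(q$q_modt[i] <= cut, q$q_wilcoxon[i] <= cut, q$q_nbwald[i] <= cut)
  }, logical(1))
}

# Naive per-feature consistency filter.
oracle_consistency <- function(lfc_row, dir_frac, fold_frac, fold_thr,
                               dir_strict = TRUE, fold_strict = FALSE) {
  N <- length(lfc_row)
  npos <- sum(lfc_row > 0); nneg <- sum(lfc_row < 0)
  conc <- max(npos, nneg)
  two <- sum(abs(lfc_row) >= log2(fold_thr))
  a <- if (dir_strict) conc > dir_frac * N else conc >= dir_frac * N
  b <- if (fold_strict) two > fold_frac * N else two >= fold_frac * N
  a && b && npos != nneg
}

# Naive anticorrelated-pair triple filter over the full cross join.
oracle_pairs <- function(demirs, degs, targets) {
  rel <- unique(as.data.frame(targets)[, c("mirna_id", "gene_id")])
  out <- list()
  for (i in seq_len(nrow(demirs))) {
    for (j in seq_len(nrow(degs))) {
      m <- demirs$feature_id[i]; g <- degs$feature_id[j]
      if (!any(rel$mirna_id == m & rel$gene_id == g)) next
      if (demirs$direction[i] == degs$direction[j]) next
      out[[length(out) + 1]] <- data.frame(mirna_id = m, gene_id = g)
    }
  }
  if (!length(out)) return(data.frame(mirna_id = character(0),
                                      gene_id = character(0)))
  unique(do.call(rbind, out))
}

# Naive target-map merge by set comprehension.
oracle_merge <- function(validated, predicted, scored, min_support,
                         ts_threshold) {
  keys <- function(map) {
    df <- as.data.frame(map)
    paste(df$mirna_id, df$gene_id)
  }
  out <- character(0)
  for (v in validated) out <- c(out, keys(v))
  all_keys <- unique(unlist(lapply(predicted, keys)))
  for (k in all_keys) {
    support <- sum(vapply(predicted, function(p) k %in% keys(p),
                          logical(1)))
    if (support >= min_support) out <- c(out, k)
  }
  if (!is.null(scored)) {
    df <- as.data.frame(scored)
    out <- c(out, paste(df$mirna_id, df$gene_id)[df$score > ts_threshold])
  }
  sort(unique(out))
}

# Exact hypergeometric upper tail by enumeration of dhyper terms.
oracle_hyper_upper <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) dhyper(x, K, N - K, n), numeric(1)))
}

# Hand O/E/V log-rank tabulation over distinct event times.
oracle_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small random fixture factory for DE-shaped q-value tables.
random_q_table <- function(m) {
  data.frame(q_modt = runif(m), q_wilcoxon = runif(m), q_nbwald = runif(m))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
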