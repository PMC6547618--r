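## Canonical miRNA seed-site detection and context features.
## Coordinates are 0-based half-open on the UTR plus strand; the UTRs are
## assumed to arrive already stranded. RNA alphabet throughout (T is
## normalized to U on input).

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside A/C/G/U/N raise an
#' error.
#'
#' @param x Character vector of sequences.
#' @return Normalized character vector.
#' @export
normalize_rna <- function(x) {
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("non-IUPAC nucleotide characters in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out
}

rc_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' UTR pattern demanded by a seed-site type
#'
#' With miRNA positions numbered 5' to 3' from 1: the 7mer-m8 site is the
#' reverse complement of positions 2-8; the 7mer-A1 site is the reverse
#' complement of positions 2-7 followed by an A in the UTR (the A faces
#' position 1 regardless of the miRNA's first base); the 8mer site is the
#' reverse complement of positions 2-8 followed by an A.
#'
#' @param mirna_seq Mature miRNA sequence (RNA, length >= 8).
#' @param site_type `"8mer"`, `"7mer-m8"` or `"7mer-A1"`.
#' @return The exact UTR match pattern (character scalar).
#' @export
seed_site_pattern <- function(mirna_seq,
                              site_type = c("8mer", "7mer-m8", "7mer-A1")) {
  site_type <- match.arg(site_type)
  mirna_seq <- normalize_rna(mirna_seq)
  if (nchar(mirna_seq) < 8L) stop("miRNA must be at least 8 nt",
                                  call. = FALSE)
  switch(site_type,
         "8mer" = paste0(rc_rna(substr(mirna_seq, 2L, 8L)), "A"),
         "7mer-m8" = rc_rna(substr(mirna_seq, 2L, 8L)),
         "7mer-A1" = paste0(rc_rna(substr(mirna_seq, 2L, 7L)), "A"))
}

# all 0-based start offsets of `pattern` in `subject` (overlaps included)
.find_starts <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, subject)
  Biostrings::start(m) - 1L
}

#' Scan a 3'UTR for canonical seed sites of one miRNA
#'
#' Enumerates all 8mer, 7mer-m8 and 7mer-A1 matches of the miRNA's seed in
#' the UTR, left to right. Overlapping matches at one locus are reported
#' once with the most specific type (8mer > 7mer-m8 > 7mer-A1): every 8mer
#' locus also matches the two 7mer patterns, and the weaker calls at and
#' just downstream of an 8mer are suppressed.
#'
#' @param mirna_seq Mature miRNA sequence (>= 8 nt; T accepted, normalized
#'   to U).
#' @param utr_seq 3'UTR sequence.
#' @param mirna_id,utr_id Identifiers carried into the output.
#' @return Data frame `mirna_id`, `utr_id`, `start` (0-based), `end`
#'   (half-open), `site_type`, ordered by start.
#' @export
#' @examples
#' # let-7a: seed pairing positions 2-8 = GAGGUAG, reverse complement CUACCUC
#' scan_seed_sites("UGAGGUAGUAGGUUGUAUAGUU",
#'                 "GGGCUACCUCAGGG")  # one 8mer at offset 3
scan_seed_sites <- function(mirna_seq, utr_seq, mirna_id = "mirna",
                            utr_id = "utr") {
  mirna_seq <- normalize_rna(mirna_seq)
  utr_seq <- normalize_rna(utr_seq)
  p8 <- seed_site_pattern(mirna_seq, "8mer")
  p7m8 <- seed_site_pattern(mirna_seq, "7mer-m8")
  p7a1 <- seed_site_pattern(mirna_seq, "7mer-A1")
  if (nchar(utr_seq) < 7L) {
    return(data.frame(mirna_id = character(0), utr_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  subject <- Biostrings::RNAString(utr_seq)
  s8 <- .find_starts(p8, subject)
  s7m8 <- setdiff(.find_starts(p7m8, subject), s8)
  s7a1 <- .find_starts(p7a1, subject)
  # suppress an A1 call that is the tail of an 8mer (one base downstream of
  # its start) or that coincides with a 7mer-m8/8mer start
  s7a1 <- setdiff(s7a1, c(s8, s8 + 1L, s7m8, .find_starts(p7m8, subject)))
  starts <- c(s8, s7m8, s7a1)
  types <- rep(c("8mer", "7mer-m8", "7mer-A1"),
               c(length(s8), length(s7m8), length(s7a1)))
  lens <- rep(c(8L, 7L, 7L), c(length(s8), length(s7m8), length(s7a1)))
  o <- order(starts)
  data.frame(mirna_id = rep(mirna_id, length(starts)),
             utr_id = rep(utr_id, length(starts)),
             start = starts[o], end = starts[o] + lens[o],
             site_type = types[o], stringsAsFactors = FALSE)
}

## Watson-Crick RNA nearest-neighbour stacking free energies, dG37 in
## kcal/mol (Xia et al. / Turner parameters). Keyed by the 5'->3'
## dinucleotide of one strand; the complementary-strand step maps onto the
## same value via reverse complement.
rna_nn_dg37 <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08,
                 CA = -2.11, GU = -2.24, GA = -2.35, CG = -2.36,
                 GC = -3.42, GG = -3.26)

.nn_lookup <- function(step) {
  v <- rna_nn_dg37[step]
  miss <- is.na(v)
  if (any(miss)) v[miss] <- rna_nn_dg37[rc_rna(step[miss])]
  unname(v)
}

#' Seed-pairing stability (SPS)
#'
#' Nearest-neighbour stacking free energy of the perfect Watson-Crick
#' duplex between miRNA positions 2-8 and the target site: the sum of the
#' six dinucleotide stacking terms (dG37, kcal/mol) along the seed. No
#' duplex-initiation term and no G:U wobbles are counted, so the value is
#' always negative for a canonical seed.
#'
#' @param mirna_seq Mature miRNA sequence(s).
#' @return Numeric vector of free energies (kcal/mol, <= 0).
#' @export
seed_pairing_stability <- function(mirna_seq) {
  mirna_seq <- normalize_rna(mirna_seq)
  vapply(mirna_seq, function(m) {
    seed <- substr(m, 2L, 8L)
    steps <- substring(seed, 1:6, 2:7)
    sum(.nn_lookup(steps))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compute the four MLR context features for scanned sites
#'
#' For each site: `au` is the fraction of A/U bases in the `flank` nt
#' upstream plus `flank` nt downstream of the site (truncated at the UTR
#' ends; the denominator is the number of bases actually present);
#' `utr_len` is log10 of the UTR length in nt; `ta` is log10(1 + count of
#' this miRNA's 7mer-m8 match over all UTRs in the supplied universe), the
#' target-site abundance; `sps` is the seed-pairing stability from
#' [seed_pairing_stability()].
#'
#' @param sites Data frame as returned by [scan_seed_sites()].
#' @param mirnas Named character vector of miRNA sequences (must cover all
#'   `sites$mirna_id`).
#' @param utrs Named character vector of UTR sequences; this is also the
#'   universe over which target-site abundance is counted.
#' @param flank Flank width in nt on each side for the AU content
#'   (default 30).
#' @return `sites` with columns `au`, `utr_len`, `ta`, `sps` appended.
#' @export
compute_site_features <- function(sites, mirnas, utrs, flank = 30L) {
  if (flank < 0) stop("`flank` must be >= 0", call. = FALSE)
  mirnas <- setNames(normalize_rna(mirnas), names(mirnas))
  utrs <- setNames(normalize_rna(utrs), names(utrs))
  if (nrow(sites) == 0L) {
    sites$au <- sites$utr_len <- sites$ta <- sites$sps <- numeric(0)
    return(sites)
  }
  if (!all(sites$mirna_id %in% names(mirnas))) {
    stop("sites reference miRNAs absent from `mirnas`", call. = FALSE)
  }
  if (!all(sites$utr_id %in% names(utrs))) {
    stop("sites reference UTRs absent from `utrs`", call. = FALSE)
  }

  utr_set <- Biostrings::RNAStringSet(utrs)
  ta_by_mirna <- vapply(unique(sites$mirna_id), function(mid) {
    pat <- seed_site_pattern(mirnas[[mid]], "7mer-m8")
    sum(Biostrings::vcountPattern(pat, utr_set))
  }, numeric(1))

  sps_by_mirna <- setNames(
    seed_pairing_stability(mirnas[unique(sites$mirna_id)]),
    unique(sites$mirna_id))

  n <- nrow(sites)
  au <- numeric(n)
  for (i in seq_len(n)) {
    useq <- utrs[[sites$utr_id[i]]]
    L <- nchar(useq)
    s1 <- sites$start[i] + 1L           # 1-based site start
    e1 <- sites$end[i]                  # 1-based site end (inclusive)
    up <- if (s1 > 1L) substr(useq, max(1L, s1 - flank), s1 - 1L) else ""
    down <- if (e1 < L) substr(useq, e1 + 1L, min(L, e1 + flank)) else ""
    ctx <- paste0(up, down)
    nb <- nchar(ctx)
    au[i] <- if (nb > 0) {
      sum(strsplit(ctx, "", fixed = TRUE)[[1]] %in% c("A", "U")) / nb
    } else 0
  }
  sites$au <- au
  sites$utr_len <- log10(nchar(utrs[sites$utr_id]))
  sites$ta <- log10(1 + ta_by_mirna[sites$mirna_id])
  sites$sps <- unname(sps_by_mirna[sites$mirna_id])
  rownames(sites) <- NULL
  sites
}

#' Read / write FASTA files of RNA sequences
#'
#' Thin wrappers over Biostrings IO. Reading accepts DNA or RNA alphabets
#' and normalizes T to U; writing wraps lines at 80 columns.
#'
#' @param path FASTA file path.
#' @return `read_fasta_rna()`: named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(normalize_rna(as.character(x)), names(x))
}

#' @rdname read_fasta_rna
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}
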