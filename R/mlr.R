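#' Multiple-linear-regression site-scoring model
#'
#' Holds the intercept, the four context-feature coefficients (local AU
#' content, log10 UTR length, log10 target-site abundance, seed-pairing
#' stability) and the putative-target score threshold. mRNAs whose
#' aggregated score falls below the threshold (default -0.3) are classified
#' as putative targets.
#'
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric of length 4 with names `au`,
#'   `utr_len`, `ta`, `sps`.
#' @param score_threshold Putative-target cutoff (scores strictly below
#'   pass; default -0.3).
#' @param residual_sd Optional residual sd recorded when fitted from data.
#' @return An object of class `mlr_model`.
#' @export
mlr_model <- function(intercept, coefficients, score_threshold = -0.3,
                      residual_sd = NA_real_) {
  need <- c("au", "utr_len", "ta", "sps")
  if (length(coefficients) != 4L || !all(need %in% names(coefficients))) {
    stop("`coefficients` must be length 4 with names au, utr_len, ta, sps",
         call. = FALSE)
  }
  if (!all(is.finite(c(intercept, coefficients, score_threshold)))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients[need],
                 score_threshold = score_threshold,
                 residual_sd = residual_sd),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("MLR site-scoring model\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-8s %+ .4f\n", nm, x$coefficients[[nm]]))
  }
  cat(sprintf("  putative-target threshold: score < %.3f\n",
              x$score_threshold))
  if (is.finite(x$residual_sd)) {
    cat(sprintf("  residual sd: %.4f\n", x$residual_sd))
  }
  invisible(x)
}

#' Default MLR model
#'
#' Synthetic-calibration coefficients with the canonical signs: higher
#' flanking AU content strengthens repression (negative coefficient), longer
#' UTRs and higher target-site abundance weaken it (positive coefficients),
#' and stronger (more negative, kcal/mol) seed-pairing stability strengthens
#' it (positive coefficient acting on a negative feature). The coefficients
#' are calibration values for the bundled synthetic repression generator,
#' not estimates from any published compendium.
#'
#' @return An [mlr_model()].
#' @export
default_mlr_model <- function() {
  mlr_model(intercept = -0.1,
            coefficients = c(au = -0.30, utr_len = 0.05, ta = 0.08,
                             sps = 0.03),
            score_threshold = -0.3)
}

#' Score sites under an MLR model
#'
#' `score = intercept + sum(coefficient * feature)` per site.
#'
#' @param features Data frame with columns `au`, `utr_len`, `ta`, `sps`
#'   (e.g. from [compute_site_features()]).
#' @param model An [mlr_model()].
#' @return Numeric vector of site scores.
#' @export
mlr_score <- function(features, model = default_mlr_model()) {
  need <- names(model$coefficients)
  X <- as.matrix(as.data.frame(features)[, need, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite site features", call. = FALSE)
  model$intercept + drop(X %*% model$coefficients)
}

#' Fit MLR coefficients from site-level repression data
#'
#' Ordinary least squares of observed repression on the four context
#' features.
#'
#' @param training Data frame with columns `au`, `utr_len`, `ta`, `sps`,
#'   `repression` and at least 20 rows.
#' @param score_threshold Threshold carried into the returned model.
#' @return An [mlr_model()] with `residual_sd` set.
#' @export
fit_mlr_coefficients <- function(training, score_threshold = -0.3) {
  need <- c("au", "utr_len", "ta", "sps", "repression")
  if (!all(need %in% names(training))) {
    stop("`training` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(training) < 20L) stop("need at least 20 training rows",
                                 call. = FALSE)
  X <- model.matrix(~ au + utr_len + ta + sps, data = training)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: collinear or constant feature columns",
         call. = FALSE)
  }
  fit <- lm(repression ~ au + utr_len + ta + sps, data = training)
  cf <- coef(fit)
  mlr_model(intercept = cf[["(Intercept)"]],
            coefficients = c(au = cf[["au"]], utr_len = cf[["utr_len"]],
                             ta = cf[["ta"]], sps = cf[["sps"]]),
            score_threshold = score_threshold,
            residual_sd = sqrt(sum(fit$residuals^2) / fit$df.residual))
}

#' Predict miRNA targets by seed scanning and MLR scoring
#'
#' For every (miRNA, UTR) combination: scan for canonical seed sites,
#' compute the four context features (target-site abundance over the full
#' UTR set), score each site, aggregate the site scores to the mRNA level
#' (sum by default, or the minimum site score), and emit a target relation
#' with provenance `"mlr"` whenever the aggregated score falls below the
#' model threshold.
#'
#' @param mirnas,utrs Named character vectors of sequences (or paths read
#'   via [read_fasta_rna()] beforehand).
#' @param model An [mlr_model()].
#' @param flank Flank width for AU content.
#' @param aggregate `"sum"` or `"min"` over a gene's site scores.
#' @return A [target_map()] data frame with the aggregated score; the
#'   attribute `sites` holds the full per-site feature/score table.
#' @export
predict_targets <- function(mirnas, utrs, model = default_mlr_model(),
                            flank = 30L, aggregate = c("sum", "min")) {
  aggregate <- match.arg(aggregate)
  if (length(mirnas) == 0L || length(utrs) == 0L) {
    return(target_map(data.frame(mirna_id = character(0),
                                 gene_id = character(0),
                                 provenance = character(0),
                                 score = numeric(0))))
  }
  mirnas <- setNames(normalize_rna(mirnas), names(mirnas))
  utrs <- setNames(normalize_rna(utrs), names(utrs))
  utr_set <- Biostrings::RNAStringSet(utrs)

  all_sites <- list()
  for (mid in names(mirnas)) {
    pats <- c("8mer" = seed_site_pattern(mirnas[[mid]], "8mer"),
              "7mer-m8" = seed_site_pattern(mirnas[[mid]], "7mer-m8"),
              "7mer-A1" = seed_site_pattern(mirnas[[mid]], "7mer-A1"))
    hits8 <- Biostrings::vmatchPattern(pats[["8mer"]], utr_set)
    hits7 <- Biostrings::vmatchPattern(pats[["7mer-m8"]], utr_set)
    hitsA <- Biostrings::vmatchPattern(pats[["7mer-A1"]], utr_set)
    for (ui in seq_along(utrs)) {
      s8 <- Biostrings::start(hits8[[ui]]) - 1L
      s7r <- Biostrings::start(hits7[[ui]]) - 1L
      s7 <- setdiff(s7r, s8)
      sA <- setdiff(Biostrings::start(hitsA[[ui]]) - 1L,
                    c(s8, s8 + 1L, s7r))
      if (!length(s8) && !length(s7) && !length(sA)) next
      starts <- c(s8, s7, sA)
      types <- rep(c("8mer", "7mer-m8", "7mer-A1"),
                   c(length(s8), length(s7), length(sA)))
      lens <- ifelse(types == "8mer", 8L, 7L)
      all_sites[[length(all_sites) + 1L]] <-
        data.frame(mirna_id = mid, utr_id = names(utrs)[ui],
                   start = starts, end = starts + lens, site_type = types,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(all_sites)) {
    return(target_map(data.frame(mirna_id = character(0),
                                 gene_id = character(0),
                                 provenance = character(0),
                                 score = numeric(0))))
  }
  sites <- do.call(rbind, all_sites)
  sites <- compute_site_features(sites, mirnas, utrs, flank = flank)
  sites$mlr_score <- mlr_score(sites, model)

  key <- paste(sites$mirna_id, sites$utr_id, sep = "\r")
  agg_fun <- if (aggregate == "sum") sum else min
  agg <- tapply(sites$mlr_score, key, agg_fun)
  ids <- strsplit(names(agg), "\r", fixed = TRUE)
  rel <- data.frame(mirna_id = vapply(ids, `[`, "", 1L),
                    gene_id = vapply(ids, `[`, "", 2L),
                    provenance = "mlr",
                    score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- target_map(rel[rel$score < model$score_threshold, , drop = FALSE])
  attr(out, "sites") <- sites
  out
}
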