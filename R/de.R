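#' Differential-expression configuration
#'
#' Bundles every threshold of the consensus DE pipeline. The two modes
#' mirror the study design: miRNA mode gates on overall average expression
#' (logCPM >= 3) with consistency fractions 0.80 / 0.70, while mRNA mode
#' gates on the overall average fold change (|logFC| > 0.5) and relaxes each
#' consistency fraction by 10 percentage points (0.70 / 0.60).
#'
#' @param mode `"mirna"` or `"mrna"`.
#' @param fdr_threshold Consensus FDR cutoff; a feature must reach
#'   `q <= fdr_threshold` in all three statistics (default `1e-5`).
#' @param min_avg_logcpm Expression gate in miRNA mode: mean logCPM across
#'   all samples must be `>= min_avg_logcpm` (default 3).
#' @param min_abs_avg_logfc Fold-change gate in mRNA mode: `|mean per-pair
#'   log2FC| > min_abs_avg_logfc` (default 0.5).
#' @param direction_frac Fraction of patients whose per-pair fold-change
#'   direction must agree with the majority; compared with strict `>` by
#'   default (`direction_strict`).
#' @param fold_frac Fraction of patients that must show at least a
#'   `fold_threshold`-fold change; compared with `>=` by default
#'   (`fold_strict = FALSE`).
#' @param fold_threshold Linear fold-change threshold for the per-patient
#'   criterion (default 2, i.e. |per-pair log2FC| >= 1).
#' @param direction_strict,fold_strict Use strict `>` instead of `>=` for
#'   the respective patient-count comparison.
#' @param prefilter_cpm,prefilter_frac Low-expression prefilter: keep
#'   features with CPM > `prefilter_cpm` in at least `prefilter_frac` of
#'   samples (defaults 1 and 0.25).
#' @param quantile_norm Apply [quantile_normalize()] to the logCPM matrix
#'   before fold-change computation (default `TRUE` in miRNA mode,
#'   `FALSE` in mRNA mode).
#' @param pseudocount Pseudocount for [log_cpm()].
#'
#' @return A list of class `de_config`.
#' @export
de_config <- function(mode = c("mirna", "mrna"),
                      fdr_threshold = 1e-5,
                      min_avg_logcpm = 3,
                      min_abs_avg_logfc = 0.5,
                      direction_frac = NULL,
                      fold_frac = NULL,
                      fold_threshold = 2,
                      direction_strict = TRUE,
                      fold_strict = FALSE,
                      prefilter_cpm = 1,
                      prefilter_frac = 0.25,
                      quantile_norm = NULL,
                      pseudocount = 0.5) {
  mode <- match.arg(mode)
  if (is.null(direction_frac)) {
    direction_frac <- if (mode == "mirna") 0.80 else 0.70
  }
  if (is.null(fold_frac)) fold_frac <- if (mode == "mirna") 0.70 else 0.60
  if (is.null(quantile_norm)) quantile_norm <- mode == "mirna"
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must be in (0,1)", call. = FALSE)
  }
  for (fr in c(direction_frac, fold_frac)) {
    if (fr <= 0 || fr > 1) {
      stop("consistency fractions must be in (0,1]", call. = FALSE)
    }
  }
  stopifnot_scalar_number(fold_threshold, "fold_threshold", positive = TRUE)
  structure(list(mode = mode, fdr_threshold = fdr_threshold,
                 min_avg_logcpm = min_avg_logcpm,
                 min_abs_avg_logfc = min_abs_avg_logfc,
                 direction_frac = direction_frac, fold_frac = fold_frac,
                 fold_threshold = fold_threshold,
                 direction_strict = direction_strict,
                 fold_strict = fold_strict,
                 prefilter_cpm = prefilter_cpm,
                 prefilter_frac = prefilter_frac,
                 quantile_norm = quantile_norm,
                 pseudocount = pseudocount),
            class = "de_config")
}

#' Per-patient log2 fold changes
#'
#' For each feature and each patient, the tumor-minus-normal difference of
#' logCPM values, which is the log2 tumor/normal fold change on the CPM
#' scale.
#'
#' @param expr Expression (logCPM) matrix, features x samples.
#' @param manifest Manifest data frame (`patient_id`, `tumor_sample`,
#'   `normal_sample`).
#' @return Matrix features x patients (columns named by patient id).
#' @export
per_pair_logfc <- function(expr, manifest) {
  missing_t <- !(manifest$tumor_sample %in% colnames(expr))
  missing_n <- !(manifest$normal_sample %in% colnames(expr))
  if (any(missing_t | missing_n)) {
    bad <- manifest$patient_id[missing_t | missing_n]
    stop("missing sample(s) in expression matrix for patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lfc <- expr[, manifest$tumor_sample, drop = FALSE] -
    expr[, manifest$normal_sample, drop = FALSE]
  colnames(lfc) <- manifest$patient_id
  lfc
}

# -- the three DE statistics --------------------------------------------------

#' Moderated paired t-test with empirical-Bayes variance shrinkage
#'
#' Per-feature paired t on the per-patient log2 fold changes, with the
#' feature variance s^2 shrunk toward a prior (s0^2, d0) estimated from the
#' across-feature distribution of s^2 by moment matching under the scaled
#' inverse-chi-square model. The statistic is
#' `t = mean(d) / (s_post / sqrt(n))` with `s_post^2 = (d0 s0^2 + d s^2) /
#' (d0 + d)`, `d = n - 1`, referred to a t distribution on `d0 + n - 1`
#' degrees of freedom.
#'
#' @param d Matrix of per-pair log2 fold changes, features x patients.
#' @return Data frame `t`, `df`, `p` (two-sided), one row per feature.
#' @export
moderated_t_test <- function(d) {
  n <- ncol(d)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  dfree <- n - 1
  m <- rowMeans(d)
  s2 <- row_vars(d)
  m1 <- mean(s2)
  v <- var(s2)
  cv2 <- if (m1 > 0) v / m1^2 else 0
  # E[s^4]/E[s^2]^2 = (d0-2)(d+2)/((d0-4) d) under s^2 ~ s0^2 d0/chisq_d0 * chisq_d/d
  R <- (1 + cv2) * dfree / (dfree + 2)
  if (!is.finite(R) || R <= 1 + 1e-10) {
    d0 <- 1e8  # no detectable spread: total shrinkage to the pooled variance
  } else {
    d0 <- (4 * R - 2) / (R - 1)
    if (d0 < 4 + 1e-8) d0 <- 4 + 1e-8
  }
  s0_sq <- m1 * (d0 - 2) / d0
  s_post_sq <- (d0 * s0_sq + dfree * s2) / (d0 + dfree)
  tt <- ifelse(s_post_sq > 0, m / sqrt(s_post_sq / n), 0)
  df_total <- min(d0 + dfree, 1e8)
  p <- 2 * pt(-abs(tt), df_total)
  p[!is.finite(tt)] <- 1
  data.frame(t = tt, df = df_total, p = pmin(p, 1), row.names = rownames(d))
}

#' Wilcoxon signed-rank test on per-pair fold changes
#'
#' Vectorised signed-rank test per feature: zero differences are dropped,
#' |d| are ranked with average ranks, and the positive-rank sum W is referred
#' to the exact signed-rank distribution for n <= `exact_max` without ties,
#' otherwise to the normal approximation with continuity correction and tie
#' correction (the same conventions as `stats::wilcox.test`).
#'
#' @param d Matrix of per-pair log2 fold changes, features x patients.
#' @param exact_max Largest n for which the exact null distribution is used.
#' @return Data frame `w`, `p`, one row per feature.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  if (ncol(d) < 3L) stop("need at least 3 pairs", call. = FALSE)
  res <- t(apply(d, 1L, function(x) {
    x <- x[x != 0]
    n <- length(x)
    if (n == 0L) return(c(NA_real_, 1))
    r <- rank(abs(x))
    w <- sum(r[x > 0])
    ties <- any(duplicated(abs(x)))
    if (n <= exact_max && !ties) {
      p <- if (w > n * (n + 1) / 4) {
        2 * psignrank(w - 1, n, lower.tail = FALSE)
      } else {
        2 * psignrank(w, n)
      }
    } else {
      mu <- n * (n + 1) / 4
      tab <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
      z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    c(w, min(p, 1))
  }))
  data.frame(w = res[, 1], p = res[, 2], row.names = rownames(d))
}

# Profile out the per-pair intercepts of a paired NB (or Poisson) model with
# log link and known dispersion phi. yt, yn: features x pairs count matrices;
# ot, on: log library-size offsets (length = pairs); phi: per-feature
# dispersion (0 = Poisson). Returns beta (log fold change, natural log),
# Wald SE, and the fitted means.
.nb_paired_fit <- function(yt, yn, ot, on, phi, max_iter = 60L,
                           tol = 1e-10) {
  f <- nrow(yt); J <- ncol(yt)
  phi <- rep_len(phi, f)
  TT <- yt + yn
  ot_m <- matrix(ot, f, J, byrow = TRUE)
  on_m <- matrix(on, f, J, byrow = TRUE)
  # init from the pooled ratio
  beta <- log((rowSums(yt) + 0.5) / (rowSums(yn) + 0.5)) -
    log(sum(exp(ot)) / sum(exp(on)))
  a <- log(pmax(TT, 0.5)) - log(exp(beta + ot_m) + exp(on_m))
  for (it in seq_len(max_iter)) {
    # pair intercepts: two Fisher-scoring steps each outer iteration
    for (k in 1:2) {
      mut <- exp(a + beta + ot_m)
      mun <- exp(a + on_m)
      wt <- mut / (1 + phi * mut)
      wn <- mun / (1 + phi * mun)
      score_a <- (yt - mut) / (1 + phi * mut) + (yn - mun) / (1 + phi * mun)
      step <- score_a / pmax(wt + wn, 1e-12)
      a <- a + pmax(pmin(step, 3), -3)
      a[TT == 0] <- -30       # empty pair: contributes nothing
    }
    mut <- exp(a + beta + ot_m)
    mun <- exp(a + on_m)
    wt <- mut / (1 + phi * mut)
    score_b <- rowSums((yt - mut) / (1 + phi * mut))
    info_b <- pmax(rowSums(wt), 1e-12)
    step_b <- score_b / info_b
    step_b <- pmax(pmin(step_b, 2), -2)
    beta <- beta + step_b
    if (max(abs(step_b)) < tol) break
  }
  mut <- exp(a + beta + ot_m)
  mun <- exp(a + on_m)
  wt <- mut / (1 + phi * mut)
  wn <- mun / (1 + phi * mun)
  # profile information for beta after eliminating the pair intercepts
  info <- rowSums(wt * wn / pmax(wt + wn, 1e-12))
  list(beta = beta, se = 1 / sqrt(pmax(info, 1e-12)), mut = mut, mun = mun)
}

#' Negative-binomial Wald test for paired designs
#'
#' Per-feature NB generalized linear model with a condition (tumor vs
#' normal) effect, per-patient intercepts, and log-library-size offsets.
#' Dispersions are estimated by a degrees-of-freedom-corrected Pearson
#' method of moments around the paired Poisson fit and shrunk 50/50 toward a
#' trended fit (binned means over average expression). The Wald statistic
#' `z = beta / SE` uses the profile information for the condition effect and
#' is referred to a t distribution on `n_pairs - 1` degrees of freedom,
#' which matches the effective replication of the matched design.
#'
#' @param counts A [paired_counts()] object (raw counts; library sizes are
#'   the full column sums).
#' @param features Optional character vector restricting the test to a
#'   subset of features (e.g. after prefiltering).
#' @param trend_bins Number of expression bins for the dispersion trend.
#' @return Data frame `log2fc`, `dispersion`, `z`, `p`, one row per feature.
#' @export
nb_wald_test <- function(counts, features = NULL, trend_bins = 20L) {
  stopifnot(inherits(counts, "paired_counts"))
  manifest <- counts$manifest
  if (nrow(manifest) < 3L) stop("need at least 3 pairs", call. = FALSE)
  cnt <- counts$counts
  libsize <- colSums(cnt)
  if (!is.null(features)) cnt <- cnt[features, , drop = FALSE]
  yt <- cnt[, manifest$tumor_sample, drop = FALSE]
  yn <- cnt[, manifest$normal_sample, drop = FALSE]
  ot <- log(libsize[manifest$tumor_sample])
  on <- log(libsize[manifest$normal_sample])
  f <- nrow(yt); J <- ncol(yt)

  # 1. Poisson fit for the moment estimator of dispersion
  pois <- .nb_paired_fit(yt, yn, ot, on, phi = 0, max_iter = 40L)
  resid2 <- cbind((yt - pois$mut)^2, (yn - pois$mun)^2)
  mu_all <- cbind(pois$mut, pois$mun)
  use <- mu_all > 1e-8
  X <- ifelse(use, resid2 / pmax(mu_all, 1e-8), 0)
  n_eff <- rowSums(use)
  df_resid <- pmax(n_eff - (rowSums(yt + yn > 0) + 1), 1)
  # solve sum_s X_s / (1 + phi mu_s) = df_resid for phi >= 0 (Newton)
  phi <- pmax((rowSums(X) - df_resid) / pmax(rowSums(X * mu_all), 1e-8), 0)
  for (it in seq_len(30L)) {
    denom <- 1 + phi * mu_all
    g <- rowSums(X / denom) - df_resid
    gp <- -rowSums(X * mu_all / denom^2)
    step <- ifelse(abs(gp) > 1e-12, g / gp, 0)
    phi <- pmax(phi - step, 0)
  }

  # 2. trended dispersion: bin features on average log expression
  avg_expr <- log2(rowMeans(t(t(yt + yn) / (exp(ot) + exp(on)))) * 1e6 + 0.25)
  n_bins <- max(1L, min(trend_bins, floor(f / 10)))
  br <- unique(quantile(avg_expr, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) {
    cut(avg_expr, br, include.lowest = TRUE)
  } else {
    factor(rep(1, f))
  }
  trend <- stats::ave(phi, bin)
  phi_shrunk <- 0.5 * phi + 0.5 * trend

  # 3. NB fit at the shrunken dispersion
  fit <- .nb_paired_fit(yt, yn, ot, on, phi = phi_shrunk)
  z <- fit$beta / fit$se
  p <- 2 * pt(-abs(z), df = J - 1)
  data.frame(log2fc = fit$beta / log(2), dispersion = phi_shrunk,
             z = z, p = pmin(p, 1), row.names = rownames(yt))
}

#' Run the three differential-expression statistics
#'
#' @param counts A [paired_counts()] object (raw counts; used by the NB
#'   Wald test).
#' @param expr logCPM (optionally quantile-normalized) matrix whose rows are
#'   the features to test; the moderated t and Wilcoxon statistics act on
#'   the per-pair fold changes derived from it.
#' @return Data frame with columns `p_modt`, `p_wilcoxon`, `p_nbwald`,
#'   rownames = feature ids.
#' @export
run_de_tests <- function(counts, expr) {
  stopifnot(inherits(counts, "paired_counts"))
  if (nrow(counts$manifest) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- per_pair_logfc(expr, counts$manifest)
  modt <- moderated_t_test(d)
  wlx <- wilcoxon_signed_rank(d)
  nb <- nb_wald_test(counts, features = rownames(expr))
  data.frame(p_modt = modt$p, p_wilcoxon = wlx$p, p_nbwald = nb$p,
             row.names = rownames(expr))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min over p_j >= p_i of (m p_j / rank_j)`,
#' clipped at 1.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0,1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Consensus selection across the three statistics
#'
#' A feature survives only if its q-value is at or below the threshold for
#' all three methods (the intersection of the three per-method pass sets).
#'
#' @param q Data frame or matrix with columns `q_modt`, `q_wilcoxon`,
#'   `q_nbwald`.
#' @param fdr_threshold Consensus FDR cutoff.
#' @return Logical vector: consensus pass per feature.
#' @export
consensus_select <- function(q, fdr_threshold = 1e-5) {
  need <- c("q_modt", "q_wilcoxon", "q_nbwald")
  if (!all(need %in% colnames(q))) {
    stop("q-values for all three methods are required", call. = FALSE)
  }
  qm <- as.matrix(as.data.frame(q)[, need])
  rowSums(qm <= fdr_threshold) == 3L
}

#' Per-patient consistency filters
#'
#' Applies the two matched-design consistency criteria to each feature's
#' per-pair log2 fold changes: (a) the direction of change must agree with
#' the majority sign in more than `direction_frac` of the N evaluable
#' patients (strict `>` by default), and (b) at least `fold_frac` of the
#' patients must show a fold change of `fold_threshold` or more (`>=` by
#' default). Pairs with a per-pair fold change of exactly zero count against
#' both criteria. The majority sign defines the feature's direction; an
#' exact positive/negative tie yields direction `"none"` and fails.
#'
#' @param lfc Matrix of per-pair log2 fold changes, features x patients.
#' @param cfg A [de_config()].
#' @return Data frame `n_concordant`, `n_twofold`, `n_pairs`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `consistent` (logical).
#' @export
consistency_filter <- function(lfc, cfg = de_config("mirna")) {
  N <- ncol(lfc)
  if (N == 0L) stop("no evaluable pairs", call. = FALSE)
  n_pos <- rowSums(lfc > 0)
  n_neg <- rowSums(lfc < 0)
  n_conc <- pmax(n_pos, n_neg)
  tie <- n_pos == n_neg
  direction <- ifelse(tie, "none", ifelse(n_pos > n_neg, "up", "down"))
  n_twofold <- rowSums(abs(lfc) >= log2(cfg$fold_threshold))
  pass_a <- if (cfg$direction_strict) {
    n_conc > cfg$direction_frac * N
  } else {
    n_conc >= cfg$direction_frac * N
  }
  pass_b <- if (cfg$fold_strict) {
    n_twofold > cfg$fold_frac * N
  } else {
    n_twofold >= cfg$fold_frac * N
  }
  data.frame(n_concordant = n_conc, n_twofold = n_twofold, n_pairs = N,
             direction = direction,
             consistent = pass_a & pass_b & !tie,
             row.names = rownames(lfc), stringsAsFactors = FALSE)
}

#' Consensus differential-expression calling with consistency filters
#'
#' Orchestrates the full DE stage on matched pairs: low-expression
#' prefilter, logCPM (plus quantile normalization in miRNA mode), the three
#' paired statistics, BH adjustment per method, the three-way consensus at
#' the FDR threshold, the mode's expression or fold-change gate, and the two
#' per-patient consistency criteria. All intermediate columns are retained
#' for audit.
#'
#' @param counts A [paired_counts()] object.
#' @param cfg A [de_config()].
#' @return Data frame with one row per prefilter-passing feature and columns
#'   `feature_id`, `avg_logcpm`, `avg_logfc`, `p_modt`, `p_wilcoxon`,
#'   `p_nbwald`, `q_modt`, `q_wilcoxon`, `q_nbwald`, `n_concordant`,
#'   `n_twofold`, `n_pairs`, `called`, `direction`. The attribute
#'   `step_counts` records the feature count surviving each step.
#' @export
#' @examples
#' sim <- simulate_paired_counts(n_features = 300, n_pairs = 12,
#'                               frac_de = 0.1, logfc_range = c(2, 3),
#'                               seed = 7)
#' de <- select_de_features(sim$counts, de_config("mirna"))
#' table(de$called, de$direction)
select_de_features <- function(counts, cfg = de_config("mirna")) {
  stopifnot(inherits(counts, "paired_counts"))
  cnt <- counts$counts
  n_input <- nrow(cnt)

  cpm <- t(t(cnt) / colSums(cnt)) * 1e6
  keep <- rowSums(cpm > cfg$prefilter_cpm) >=
    cfg$prefilter_frac * ncol(cnt)
  cnt_kept <- cnt[keep, , drop = FALSE]
  if (nrow(cnt_kept) == 0L) stop("no features pass the prefilter",
                                 call. = FALSE)

  expr <- log_cpm(cnt_kept, cfg$pseudocount)
  if (cfg$quantile_norm) expr <- quantile_normalize(expr)
  lfc <- per_pair_logfc(expr, counts$manifest)

  pvals <- run_de_tests(counts, expr)
  q <- data.frame(q_modt = bh_fdr(pvals$p_modt),
                  q_wilcoxon = bh_fdr(pvals$p_wilcoxon),
                  q_nbwald = bh_fdr(pvals$p_nbwald),
                  row.names = rownames(pvals))
  consensus <- consensus_select(q, cfg$fdr_threshold)

  avg_logcpm <- rowMeans(expr)
  avg_logfc <- rowMeans(lfc)
  gate <- if (cfg$mode == "mirna") {
    avg_logcpm >= cfg$min_avg_logcpm
  } else {
    abs(avg_logfc) > cfg$min_abs_avg_logfc
  }
  cons <- consistency_filter(lfc, cfg)
  called <- consensus & gate & cons$consistent

  out <- data.frame(feature_id = rownames(expr),
                    avg_logcpm = avg_logcpm,
                    avg_logfc = avg_logfc,
                    p_modt = pvals$p_modt,
                    p_wilcoxon = pvals$p_wilcoxon,
                    p_nbwald = pvals$p_nbwald,
                    q_modt = q$q_modt,
                    q_wilcoxon = q$q_wilcoxon,
                    q_nbwald = q$q_nbwald,
                    n_concordant = cons$n_concordant,
                    n_twofold = cons$n_twofold,
                    n_pairs = cons$n_pairs,
                    called = called,
                    direction = cons$direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "step_counts") <- c(
    input = n_input,
    prefilter = nrow(cnt_kept),
    consensus = sum(consensus),
    gate = sum(consensus & gate),
    called = sum(called)
  )
  attr(out, "mode") <- cfg$mode
  out
}
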