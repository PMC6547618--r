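#' Simulate matched tumor-normal count data with planted fold changes
#'
#' Draws a negative-binomial feature-by-sample count matrix for `n_pairs`
#' patients, each contributing one tumor and one normal sample. A fraction
#' `frac_de` of features carries a planted tumor/normal log2 fold change with
#' random sign; all remaining features are null. Each patient has a log-scale
#' factor (sd `patient_sd`) shared exactly by the patient's two samples, so
#' the matched design is informative, and each sample has its own library
#' size drawn from `libsize_range` and applied through the per-sample
#' abundance share. The mean model for feature f in sample s is
#' `log mu = baseline_f + patient_j + cond * lfc_f * log(2) + log(share * L_s)`
#' with NB variance `mu + dispersion * mu^2`.
#'
#' @param n_features,n_pairs Positive integers: number of features and of
#'   patient pairs (samples = `2 * n_pairs`).
#' @param frac_de Fraction in \[0,1\] of features planted as differentially
#'   expressed.
#' @param logfc_range Length-2 numeric: min and max planted |log2 fold
#'   change| (uniform draw, sign random).
#' @param mean_log_range Length-2 numeric: span of the baseline natural-log
#'   abundance. With the default `c(2, 8)` and library sizes around 1e6,
#'   expression covers roughly logCPM 3-11.
#' @param dispersion NB dispersion phi (variance `mu + phi mu^2`); `0` gives
#'   Poisson counts.
#' @param patient_sd Standard deviation of the per-patient log-scale factor.
#' @param libsize_range Length-2 positive numeric: library sizes drawn
#'   uniformly in this range.
#' @param seed Single integer controlling all randomness in the call.
#' @param feature_prefix Prefix for generated feature ids.
#'
#' @return A list with elements `counts` (a [paired_counts()] object) and
#'   `truth` (data frame `feature_id`, `log2fc` with the planted signed
#'   log2 fold change, zero for null features).
#' @export
#' @examples
#' sim <- simulate_paired_counts(n_features = 50, n_pairs = 6, seed = 1)
#' sim$counts
#' head(sim$truth)
simulate_paired_counts <- function(n_features = 2000, n_pairs = 48,
                                   frac_de = 0.05,
                                   logfc_range = c(1.5, 3),
                                   mean_log_range = c(2, 8),
                                   dispersion = 0.1,
                                   patient_sd = 0.3,
                                   libsize_range = c(5e5, 2e6),
                                   seed,
                                   feature_prefix = "feat") {
  for (nm in c("n_features", "n_pairs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  stopifnot_scalar_number(frac_de, "frac_de", nonnegative = TRUE)
  if (frac_de > 1) stop("`frac_de` must be in [0,1]", call. = FALSE)
  stopifnot_scalar_number(dispersion, "dispersion", nonnegative = TRUE)
  stopifnot_scalar_number(patient_sd, "patient_sd", nonnegative = TRUE)
  if (length(logfc_range) != 2L || logfc_range[1] > logfc_range[2] ||
      any(logfc_range < 0)) {
    stop("`logfc_range` must be (min, max) with 0 <= min <= max",
         call. = FALSE)
  }
  if (length(mean_log_range) != 2L || mean_log_range[1] > mean_log_range[2]) {
    stop("`mean_log_range` must be (min, max)", call. = FALSE)
  }
  if (length(libsize_range) != 2L || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stop("`libsize_range` must be positive (min, max)", call. = FALSE)
  }

  with_seed(seed, {
    f <- as.integer(n_features); J <- as.integer(n_pairs)
    feature_ids <- sprintf("%s_%04d", feature_prefix, seq_len(f))
    patients <- sprintf("patient_%02d", seq_len(J))
    tumor_ids <- paste0(patients, "_T")
    normal_ids <- paste0(patients, "_N")

    baseline <- runif(f, mean_log_range[1], mean_log_range[2])
    n_de <- round(frac_de * f)
    lfc <- numeric(f)
    if (n_de > 0) {
      de_idx <- sample.int(f, n_de)
      lfc[de_idx] <- runif(n_de, logfc_range[1], logfc_range[2]) *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    patient_fac <- rnorm(J, 0, patient_sd)
    libsizes <- round(runif(2L * J, libsize_range[1], libsize_range[2]))

    w_normal <- exp(baseline)                      # relative intensities
    w_tumor <- exp(baseline + lfc * log(2))
    share_normal <- w_normal / sum(w_normal)
    share_tumor <- w_tumor / sum(w_tumor)

    mu <- matrix(0, f, 2L * J)
    for (j in seq_len(J)) {
      mu[, j] <- exp(patient_fac[j]) * share_tumor * libsizes[j]
      mu[, J + j] <- exp(patient_fac[j]) * share_normal * libsizes[J + j]
    }
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), f)
    } else {
      matrix(rpois(length(mu), mu), f)
    }
    dimnames(counts) <- list(feature_ids, c(tumor_ids, normal_ids))
    manifest <- data.frame(patient_id = patients,
                           tumor_sample = tumor_ids,
                           normal_sample = normal_ids,
                           stringsAsFactors = FALSE)
    list(counts = paired_counts(counts, manifest),
         truth = data.frame(feature_id = feature_ids, log2fc = lfc,
                            stringsAsFactors = FALSE))
  })
}

# -- sequence universe --------------------------------------------------------

.rna_alphabet <- c("A", "C", "G", "U")

random_rna <- function(n_len) {
  vapply(n_len, function(L)
    paste(sample(.rna_alphabet, L, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a miRNA / 3'UTR sequence universe with planted seed sites
#'
#' Generates uniform-random RNA sequences: mature miRNAs of length 20-23 nt
#' and 3'UTRs with lengths drawn from `utr_len_range`. Each UTR receives a
#' Poisson(`sites_per_utr`) number of planted seed sites; a planted site is
#' the exact UTR pattern demanded by a randomly chosen site type (8mer,
#' 7mer-m8 or 7mer-A1) for a randomly chosen miRNA, written into the UTR at a
#' random non-overlapping position. Bases adjacent to a planted site are
#' adjusted where needed so the site's declared type is exactly what
#' [scan_seed_sites()] reports (e.g. a planted 7mer-m8 is never accidentally
#' followed by an A, which would upgrade it to an 8mer).
#'
#' @param n_mirnas,n_utrs Numbers of miRNA and UTR sequences.
#' @param utr_len_range Length-2 integer range of UTR lengths; minimum 30 nt.
#' @param sites_per_utr Poisson mean of planted sites per UTR (0 plants
#'   nothing).
#' @param seed Single integer seed.
#'
#' @return List with `mirnas` and `utrs` (named character vectors of RNA
#'   sequences) and `planted_sites` (data frame `mirna_id`, `utr_id`,
#'   `start` 0-based, `site_type`).
#' @export
simulate_sequence_universe <- function(n_mirnas = 20, n_utrs = 100,
                                       utr_len_range = c(200, 1000),
                                       sites_per_utr = 1,
                                       seed) {
  if (length(utr_len_range) != 2L || utr_len_range[1] > utr_len_range[2]) {
    stop("`utr_len_range` must be (min, max)", call. = FALSE)
  }
  if (utr_len_range[1] < 30) {
    stop("UTR length below 30 nt: too short for a seed site plus flanks",
         call. = FALSE)
  }
  stopifnot_scalar_number(sites_per_utr, "sites_per_utr", nonnegative = TRUE)

  with_seed(seed, {
    mirna_ids <- sprintf("mir_%03d", seq_len(n_mirnas))
    utr_ids <- sprintf("utr_%03d", seq_len(n_utrs))
    mirnas <- setNames(random_rna(sample(20:23, n_mirnas, replace = TRUE)),
                       mirna_ids)
    utr_len <- sample(seq(utr_len_range[1], utr_len_range[2]), n_utrs,
                      replace = TRUE)
    utrs <- setNames(random_rna(utr_len), utr_ids)

    planted <- list()
    for (u in seq_len(n_utrs)) {
      n_sites <- rpois(1L, sites_per_utr)
      if (n_sites == 0L) next
      occupied <- integer(0)  # positions covered by earlier plants (+margin)
      useq <- strsplit(utrs[[u]], "", fixed = TRUE)[[1]]
      L <- length(useq)
      for (k in seq_len(n_sites)) {
        mi <- sample.int(n_mirnas, 1L)
        type <- sample(c("8mer", "7mer-m8", "7mer-A1"), 1L)
        pat <- seed_site_pattern(mirnas[[mi]], type)
        # degenerate seeds where the 7mer-A1 pattern equals the 7mer-m8
        # pattern would be reported as 7mer-m8 by the type-priority rule
        if (type == "7mer-A1" &&
            pat == seed_site_pattern(mirnas[[mi]], "7mer-m8")) {
          type <- "7mer-m8"
          pat <- seed_site_pattern(mirnas[[mi]], type)
        }
        len <- nchar(pat)
        placed <- FALSE
        for (try in seq_len(25L)) {
          s <- sample.int(L - len - 1L, 1L) + 1L   # 1-based, keep 1 nt margin
          span <- (s - 1L):(s + len)               # site plus margins
          if (any(span %in% occupied)) next
          useq[s:(s + len - 1L)] <- strsplit(pat, "", fixed = TRUE)[[1]]
          # guard the margins so the planted type is scanned as declared
          pat7 <- seed_site_pattern(mirnas[[mi]], "7mer-m8")
          if (type == "7mer-m8" && s + len <= L && useq[s + len] == "A") {
            useq[s + len] <- sample(c("C", "G", "U"), 1L)
          }
          if (type == "7mer-A1" && s > 1L) {
            # an 8mer one base upstream would subsume this site
            m8c <- substr(pat7, 1L, 1L)
            if (useq[s - 1L] == m8c) {
              useq[s - 1L] <- sample(setdiff(.rna_alphabet, m8c), 1L)
            }
          }
          occupied <- c(occupied, span)
          planted[[length(planted) + 1L]] <-
            data.frame(mirna_id = mirna_ids[mi], utr_id = utr_ids[u],
                       start = s - 1L, site_type = type,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) next
      }
      utrs[[u]] <- paste(useq, collapse = "")
    }
    planted_sites <- if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(mirna_id = character(0), utr_id = character(0),
                 start = integer(0), site_type = character(0),
                 stringsAsFactors = FALSE)
    }
    list(mirnas = mirnas, utrs = utrs, planted_sites = planted_sites)
  })
}

#' Simulate site-level repression responses linear in the context features
#'
#' Observed repression (log2 mRNA change; negative = repressed) is the linear
#' combination of the four context features under `model` plus Gaussian
#' noise. Used to validate [fit_mlr_coefficients()] recovery.
#'
#' @param features Data frame with columns `au`, `utr_len`, `ta`, `sps`,
#'   or `NULL` to generate `n` random feature rows spanning realistic
#'   ranges (AU in \[0,1\], log10 UTR length in \[2,3.5\], log10 TA in
#'   \[0,2\], SPS in \[-20,-5\] kcal/mol).
#' @param n Number of rows to generate when `features` is `NULL`.
#' @param model An [mlr_model()] supplying intercept and coefficients.
#' @param noise_sd Non-negative Gaussian noise sd.
#' @param seed Single integer seed.
#'
#' @return Data frame: the features plus a `repression` column.
#' @export
simulate_repression_data <- function(features = NULL, n = 500,
                                     model = default_mlr_model(),
                                     noise_sd = 0.1, seed) {
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  with_seed(seed, {
    if (is.null(features)) {
      features <- data.frame(au = runif(n),
                             utr_len = runif(n, 2, 3.5),
                             ta = runif(n, 0, 2),
                             sps = runif(n, -20, -5))
    }
    need <- c("au", "utr_len", "ta", "sps")
    if (!all(need %in% names(features))) {
      stop("`features` must have exactly the four context columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    X <- as.matrix(features[, need])
    mu <- model$intercept + drop(X %*% model$coefficients[need])
    features$repression <- mu + rnorm(nrow(X), 0, noise_sd)
    features
  })
}

#' Simulate a survival cohort with expression-linked hazards
#'
#' Event times are exponential with subject hazard
#' `baseline_hazard * hazard_ratio^(expression > median)`, so subjects in the
#' upper half of a simulated standard-normal expression value carry the
#' hazard ratio. Censoring is independent: each subject is censored with
#' probability `censor_rate`, in which case the follow-up time is uniform on
#' (0, event time).
#'
#' @param n Cohort size, at least 10.
#' @param hazard_ratio Positive hazard ratio of the high-expression half.
#' @param censor_rate Fraction in \[0,1\) of subjects censored.
#' @param baseline_hazard Positive baseline exponential hazard.
#' @param seed Single integer seed.
#'
#' @return Data frame `subject_id`, `time`, `event` (1 = death observed),
#'   `expression`.
#' @export
simulate_survival_cohort <- function(n = 200, hazard_ratio = 2,
                                     censor_rate = 0.3,
                                     baseline_hazard = 0.1, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 10 || n != round(n)) {
    stop("`n` must be an integer >= 10", call. = FALSE)
  }
  stopifnot_scalar_number(hazard_ratio, "hazard_ratio", positive = TRUE)
  stopifnot_scalar_number(baseline_hazard, "baseline_hazard", positive = TRUE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    expression <- rnorm(n)
    high <- expression > median(expression)
    hazard <- baseline_hazard * hazard_ratio^high
    t_event <- rexp(n, hazard)
    censored <- rbinom(n, 1L, censor_rate) == 1L
    time <- t_event
    time[censored] <- runif(sum(censored)) * t_event[censored]
    data.frame(subject_id = sprintf("subj_%04d", seq_len(n)),
               time = time,
               event = as.integer(!censored),
               expression = expression,
               stringsAsFactors = FALSE)
  })
}
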