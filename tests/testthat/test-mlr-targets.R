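test_that("MLR score is the linear combination, thresholded strictly", {
  m0 <- mlr_model(intercept = -0.5,
                  coefficients = c(au = 0, utr_len = 0, ta = 0, sps = 0))
  f <- data.frame(au = 0.7, utr_len = 2.2, ta = 1.1, sps = -12)
  expect_equal(mlr_score(f, m0), -0.5)
  m1 <- mlr_model(intercept = 0,
                  coefficients = c(au = -0.4, utr_len = 0.05, ta = 0.1,
                                   sps = 0.02))
  f1 <- data.frame(au = 1.0, utr_len = 3.0, ta = 1.0, sps = -9.0)
  expect_equal(mlr_score(f1, m1), -0.33)
  # the putative-target rule is score < threshold
  expect_true(-0.31 < m1$score_threshold)
  expect_false(-0.29 < m1$score_threshold)
})

test_that("OLS fitting: exact noiseless recovery, noisy recovery, guards", {
  truth <- default_mlr_model()
  tr0 <- simulate_repression_data(n = 100, model = truth, noise_sd = 0,
                                  seed = 50)
  fit0 <- fit_mlr_coefficients(tr0)
  expect_equal(fit0$coefficients, truth$coefficients, tolerance = 1e-8)
  expect_equal(fit0$intercept, truth$intercept, tolerance = 1e-8)
  tr <- simulate_repression_data(n = 500, model = truth, noise_sd = 0.1,
                                 seed = 51)
  fit <- fit_mlr_coefficients(tr)
  expect_lt(max(abs(fit$coefficients - truth$coefficients)), 0.05)
  expect_lt(abs(fit$intercept - truth$intercept), 0.05)
  tr$au <- 1  # constant column
  expect_error(fit_mlr_coefficients(tr), "singular")
  expect_error(fit_mlr_coefficients(tr[1:10, ]), "20")
})

test_that("predict_targets runs scan -> features -> score -> aggregate", {
  u <- simulate_sequence_universe(n_mirnas = 6, n_utrs = 40,
                                  sites_per_utr = 1.5, seed = 60)
  model <- default_mlr_model()
  map <- predict_targets(u$mirnas, u$utrs, model = model)
  sites <- attr(map, "sites")
  expect_true(nrow(sites) >= nrow(u$planted_sites))
  # per-site scores equal a direct recomputation through the public pieces
  recheck <- mlr_score(compute_site_features(
    sites[, c("mirna_id", "utr_id", "start", "end", "site_type")],
    u$mirnas, u$utrs, flank = 30), model)
  expect_equal(sites$mlr_score, recheck, tolerance = 1e-12)
  # every relation's aggregated score is below the threshold
  expect_true(all(map$score < model$score_threshold))
  expect_true(all(map$provenance == "mlr"))
  # aggregation: sum of that pair's site scores
  if (nrow(map) > 0) {
    i <- 1
    s <- sites[sites$mirna_id == map$mirna_id[i] &
                 sites$utr_id == map$gene_id[i], ]
    expect_equal(map$score[i], sum(s$mlr_score), tolerance = 1e-12)
  }
  # sites agree with the single-pair scanner
  for (k in head(seq_len(nrow(sites)), 10)) {
    single <- scan_seed_sites(u$mirnas[[sites$mirna_id[k]]],
                              u$utrs[[sites$utr_id[k]]])
    expect_true(any(single$start == sites$start[k] &
                      single$site_type == sites$site_type[k]))
  }
})

test_that("loosening the score threshold only grows the target set", {
  u <- simulate_sequence_universe(n_mirnas = 5, n_utrs = 30,
                                  sites_per_utr = 1, seed = 61)
  tight <- default_mlr_model()
  loose <- mlr_model(tight$intercept, tight$coefficients,
                     score_threshold = 0)
  map_t <- predict_targets(u$mirnas, u$utrs, model = tight)
  map_l <- predict_targets(u$mirnas, u$utrs, model = loose)
  key <- function(m) paste(m$mirna_id, m$gene_id)
  expect_true(all(key(map_t) %in% key(map_l)))
  # empty inputs give an empty map
  expect_equal(nrow(predict_targets(character(0), u$utrs)), 0)
})

test_that("merge honours the support rule, knowledgebases, and scores", {
  tm <- function(m, g, prov, score = NA_real_) {
    target_map(data.frame(mirna_id = m, gene_id = g, provenance = prov,
                          score = score))
  }
  pred <- list(tm(c("m1", "m2"), c("g1", "g2"), "predicted:a"),
               tm(c("m1", "m2"), c("g1", "g3"), "predicted:b"),
               tm("m1", "g1", "predicted:c"))
  val <- list(tm("m9", "g9", "validated"))
  sc <- tm(c("m5", "m6"), c("g5", "g6"), "predicted:ts",
           score = c(0.5, 0.1))
  merged <- merge_target_maps(val, pred, sc, min_support = 3,
                              ts_threshold = 0.2)
  key <- unique(paste(merged$mirna_id, merged$gene_id))
  expect_setequal(key, c("m1 g1", "m9 g9", "m5 g5"))
  # relation in only 2 programs is excluded; validated-only is kept
  expect_false("m2 g2" %in% key)
  expect_true("m9 g9" %in% key)
  # comparison direction is configurable
  merged_lt <- merge_target_maps(list(), list(), sc, min_support = 3,
                                 ts_threshold = 0.2,
                                 ts_keep_greater = FALSE)
  expect_equal(paste(merged_lt$mirna_id, merged_lt$gene_id), "m6 g6")
  expect_error(merge_target_maps(val, pred, sc, min_support = 0), ">= 1")
})

test_that("random merges equal the brute-force set-comprehension oracle", {
  set.seed(70)
  ids <- function(n, p) paste0(p, sample(1:15, n, replace = TRUE))
  for (rep in 1:10) {
    mk <- function(prov, scored = FALSE) {
      n <- sample(5:20, 1)
      target_map(data.frame(mirna_id = ids(n, "m"), gene_id = ids(n, "g"),
                            provenance = prov,
                            score = if (scored) runif(n, -0.5, 0.8)
                                    else NA_real_))
    }
    val <- list(mk("validated"))
    pred <- lapply(paste0("predicted:", letters[1:4]), mk)
    sc <- mk("predicted:ts", scored = TRUE)
    got <- merge_target_maps(val, pred, sc, min_support = 3,
                             ts_threshold = 0.2)
    want <- oracle_merge(val, pred, sc, 3, 0.2)
    expect_setequal(unique(paste(got$mirna_id, got$gene_id)), want)
  }
})

test_that("target_map collapses duplicate triples and round-trips TSV", {
  df <- data.frame(mirna_id = c("m1", "m1", "m1"),
                   gene_id = c("g1", "g1", "g1"),
                   provenance = c("mlr", "mlr", "validated"),
                   score = c(-0.4, -0.4, NA))
  tmap <- target_map(df)
  expect_equal(nrow(tmap), 2)
  path <- tempfile(fileext = ".tsv")
  write_target_map_tsv(tmap, path)
  back <- read_target_map_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(tmap))
})
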