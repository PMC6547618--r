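test_that("paired count simulation is deterministic under a fixed seed", {
  a <- simulate_paired_counts(n_features = 100, n_pairs = 6, seed = 5)
  b <- simulate_paired_counts(n_features = 100, n_pairs = 6, seed = 5)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_paired_counts(n_features = 100, n_pairs = 6, seed = 6)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("null simulation plants nothing and is centred at zero logFC", {
  sim <- simulate_paired_counts(n_features = 500, n_pairs = 48,
                                frac_de = 0, seed = 2)
  expect_true(all(sim$truth$log2fc == 0))
  expr <- log_cpm(sim$counts)
  lfc <- per_pair_logfc(expr, sim$counts$manifest)
  # grand mean of per-pair log2FC over 48 pairs is ~0 within MC error
  expect_lt(abs(mean(rowMeans(lfc))), 0.05)
})

test_that("planted fold changes are recovered by empirical per-pair logFC", {
  sim <- simulate_paired_counts(n_features = 2000, n_pairs = 48,
                                frac_de = 0.05, logfc_range = c(1, 3),
                                dispersion = 0.1, seed = 3)
  expr <- log_cpm(sim$counts)
  lfc <- rowMeans(per_pair_logfc(expr, sim$counts$manifest))
  planted <- sim$truth$log2fc != 0
  err <- abs(lfc[planted] - sim$truth$log2fc[planted])
  expect_gte(mean(err <= 0.3), 0.90)
})

test_that("counts are NB over-dispersed when dispersion > 0", {
  sim <- simulate_paired_counts(n_features = 200, n_pairs = 200,
                                frac_de = 0, patient_sd = 0,
                                dispersion = 0.2,
                                mean_log_range = c(4, 6),
                                libsize_range = c(1e6, 1e6), seed = 8)
  cnt <- sim$counts$counts
  # with equal library sizes and no patient effect, each feature row is iid
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  expect_gt(mean(v > mu), 0.95)
  # moment estimate of phi near the planted value
  phi_hat <- median((v - mu) / mu^2)
  expect_equal(phi_hat, 0.2, tolerance = 0.1)
})

test_that("parameter validation rejects bad generator inputs", {
  expect_error(simulate_paired_counts(n_features = -1, seed = 1),
               "positive integer")
  expect_error(simulate_paired_counts(n_features = 10.5, seed = 1),
               "positive integer")
  expect_error(simulate_paired_counts(frac_de = 2, seed = 1), "frac_de")
  expect_error(simulate_paired_counts(libsize_range = c(0, 10), seed = 1),
               "libsize_range")
  expect_error(simulate_paired_counts(n_features = 10, seed = "a"),
               "seed")
})

test_that("sequence universe: determinism, empty planting, alphabet", {
  a <- simulate_sequence_universe(n_mirnas = 5, n_utrs = 10, seed = 4)
  b <- simulate_sequence_universe(n_mirnas = 5, n_utrs = 10, seed = 4)
  expect_identical(a, b)
  expect_true(all(grepl("^[ACGU]+$", a$mirnas)))
  expect_true(all(grepl("^[ACGU]+$", a$utrs)))
  expect_true(all(nchar(a$mirnas) >= 20 & nchar(a$mirnas) <= 23))
  none <- simulate_sequence_universe(n_mirnas = 5, n_utrs = 10,
                                     sites_per_utr = 0, seed = 4)
  expect_equal(nrow(none$planted_sites), 0)
  expect_error(simulate_sequence_universe(utr_len_range = c(10, 20),
                                          seed = 1), "30 nt")
})

test_that("every planted site is a literal pattern match at its offset", {
  u <- simulate_sequence_universe(n_mirnas = 8, n_utrs = 40,
                                  sites_per_utr = 2, seed = 10)
  for (i in seq_len(nrow(u$planted_sites))) {
    ps <- u$planted_sites[i, ]
    pat <- seed_site_pattern(u$mirnas[[ps$mirna_id]], ps$site_type)
    seg <- substr(u$utrs[[ps$utr_id]], ps$start + 1,
                  ps$start + nchar(pat))
    expect_identical(seg, pat)
  }
})

test_that("repression generator: noiseless limit and constant model", {
  m0 <- mlr_model(intercept = -0.5,
                  coefficients = c(au = 0, utr_len = 0, ta = 0, sps = 0))
  tr <- simulate_repression_data(n = 50, model = m0, noise_sd = 0,
                                 seed = 12)
  expect_true(all(tr$repression == -0.5))
  m1 <- default_mlr_model()
  tr1 <- simulate_repression_data(n = 50, model = m1, noise_sd = 0,
                                  seed = 12)
  expect_equal(tr1$repression, mlr_score(tr1, m1), tolerance = 1e-12)
  bad <- data.frame(au = 1, utr_len = 2, ta = 3)
  expect_error(simulate_repression_data(features = bad, model = m1,
                                        noise_sd = 0, seed = 1),
               "four context columns")
})

test_that("survival cohort generator honours censoring and hazard inputs", {
  ch <- simulate_survival_cohort(n = 100, hazard_ratio = 2,
                                 censor_rate = 0, seed = 20)
  expect_true(all(ch$event == 1))
  expect_error(simulate_survival_cohort(n = 100, hazard_ratio = -1,
                                        seed = 1), "hazard_ratio")
  expect_error(simulate_survival_cohort(n = 5, hazard_ratio = 1, seed = 1),
               ">= 10")
  # higher-expression half dies faster on average when HR > 1
  ch2 <- simulate_survival_cohort(n = 2000, hazard_ratio = 4,
                                  censor_rate = 0, seed = 21)
  hi <- ch2$expression > median(ch2$expression)
  expect_lt(mean(ch2$time[hi]), mean(ch2$time[!hi]))
})
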