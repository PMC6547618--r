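test_that("per-pair logFC is tumor minus normal logCPM", {
  expr <- matrix(c(5, 1, 3, 1, 7, 2, 2, 1), nrow = 2,
                 dimnames = list(c("f1", "f2"),
                                 c("p1_T", "p1_N", "p2_T", "p2_N")))
  man <- data.frame(patient_id = c("p1", "p2"),
                    tumor_sample = c("p1_T", "p2_T"),
                    normal_sample = c("p1_N", "p2_N"))
  lfc <- per_pair_logfc(expr, man)
  expect_equal(lfc, matrix(c(2, 0, 5, 1), 2,
                           dimnames = list(c("f1", "f2"), c("p1", "p2"))))
  man$tumor_sample[2] <- "missing"
  expect_error(per_pair_logfc(expr, man), "p2")
})

test_that("moderated t returns p = 1 for identically zero fold changes", {
  set.seed(1)
  d <- matrix(rnorm(20 * 10), 20)
  d[3, ] <- 0
  res <- moderated_t_test(d)
  expect_equal(res$p[3], 1)
  expect_equal(res$t[3], 0)
})

test_that("vectorised Wilcoxon matches wilcox.test in both regimes", {
  set.seed(2)
  # exact branch (n <= 25, no ties)
  d_small <- matrix(rnorm(30 * 12, mean = 0.3), 30)
  ours <- wilcoxon_signed_rank(d_small)
  ref <- apply(d_small, 1, function(x)
    wilcox.test(x, exact = TRUE)$p.value)
  expect_equal(ours$p, unname(ref), tolerance = 1e-12)
  # normal-approximation branch (n = 48)
  d_big <- matrix(rnorm(20 * 48, mean = 0.2), 20)
  ours2 <- wilcoxon_signed_rank(d_big)
  ref2 <- apply(d_big, 1, function(x)
    wilcox.test(x, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(ours2$p, unname(ref2), tolerance = 1e-10)
})

test_that("NB Wald recovers planted fold changes and needs 3 pairs", {
  sim <- simulate_paired_counts(n_features = 300, n_pairs = 24,
                                frac_de = 0.1, logfc_range = c(1.5, 2.5),
                                seed = 30)
  nb <- nb_wald_test(sim$counts)
  planted <- sim$truth$log2fc != 0
  expect_gt(cor(nb$log2fc[planted], sim$truth$log2fc[planted]), 0.97)
  expect_lt(median(nb$p[planted]), 1e-8)
  sim2 <- simulate_paired_counts(n_features = 20, n_pairs = 2, seed = 1)
  expect_error(nb_wald_test(sim2$counts), "3 pairs")
})

test_that("BH q-values: hand step-up cases and input checks", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0,1\\]")
})

test_that("consensus selection is the three-way intersection", {
  q <- data.frame(q_modt = c(1e-6, 1e-6, 1e-3),
                  q_wilcoxon = c(1e-6, 1e-6, 1e-6),
                  q_nbwald = c(1e-6, 1e-4, 1e-6))
  expect_equal(consensus_select(q, 1e-5), c(TRUE, FALSE, FALSE))
  expect_error(consensus_select(q[, 1:2], 1e-5), "three methods")
})

test_that("consistency filter implements the two patient criteria", {
  cfg <- de_config("mirna")  # >80% direction, >=70% twofold
  # N=10: nine pairs at +1.5, one at -0.2 -> 9 > 8 and 9 >= 7, direction up
  lfc <- matrix(c(rep(1.5, 9), -0.2), 1)
  res <- consistency_filter(lfc, cfg)
  expect_true(res$consistent)
  expect_equal(res$direction, "up")
  expect_equal(res$n_concordant, 9)
  expect_equal(res$n_twofold, 9)
  # exact zeros count against both criteria
  lfc0 <- matrix(c(rep(-1.5, 8), 0, 0), 1)
  res0 <- consistency_filter(lfc0, cfg)
  expect_equal(res0$n_concordant, 8)
  expect_equal(res0$n_twofold, 8)
  expect_equal(res0$direction, "down")
  # a positive/negative tie has no direction and never passes
  tie <- matrix(c(rep(2, 5), rep(-2, 5)), 1)
  rest <- consistency_filter(tie, de_config("mirna", direction_frac = 0.3))
  expect_equal(rest$direction, "none")
  expect_false(rest$consistent)
  expect_error(consistency_filter(matrix(numeric(0), 1, 0), cfg),
               "evaluable")
})

test_that("full DE selection: planted recall at moderate scale", {
  sim <- simulate_paired_counts(n_features = 600, n_pairs = 48,
                                frac_de = 0.05, logfc_range = c(2, 3),
                                seed = 31)
  de <- select_de_features(sim$counts, de_config("mirna"))
  planted <- sim$truth$feature_id[sim$truth$log2fc != 0]
  called <- de$feature_id[de$called]
  expect_gte(mean(planted %in% called), 0.85)
  expect_lte(sum(!(called %in% planted)), 0.05 * max(length(called), 1))
  # audit columns present and coherent
  expect_true(all(c("q_modt", "n_concordant", "n_twofold", "called",
                    "direction") %in% names(de)))
  expect_true(all(de$q_modt >= de$p_modt))
  expect_true(all(de$direction[de$called] != "none"))
  sc <- attr(de, "step_counts")
  expect_true(all(diff(sc) <= 0))  # each step can only shrink the set
  # planted sign matches reported direction
  up_called <- de$feature_id[de$called & de$direction == "up"]
  expect_true(all(sim$truth$log2fc[match(up_called,
                                         sim$truth$feature_id)] > 0))
})

test_that("flipping tumor/normal labels negates logFC and swaps directions", {
  sim <- simulate_paired_counts(n_features = 300, n_pairs = 12,
                                frac_de = 0.1, logfc_range = c(2, 3),
                                seed = 32)
  de1 <- select_de_features(sim$counts, de_config("mirna"))
  flipped <- paired_counts(sim$counts$counts,
                           data.frame(patient_id = sim$counts$manifest$patient_id,
                                      tumor_sample = sim$counts$manifest$normal_sample,
                                      normal_sample = sim$counts$manifest$tumor_sample))
  de2 <- select_de_features(flipped, de_config("mirna"))
  expect_equal(de2$avg_logfc, -de1$avg_logfc, tolerance = 1e-10)
  expect_identical(de1$feature_id[de1$called], de2$feature_id[de2$called])
  swap <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(swap[de1$direction]), de2$direction)
})

test_that("permuting patient order leaves DE output identical", {
  sim <- simulate_paired_counts(n_features = 200, n_pairs = 10,
                                frac_de = 0.1, logfc_range = c(2, 3),
                                seed = 33)
  de1 <- select_de_features(sim$counts, de_config("mirna"))
  perm <- sample(nrow(sim$counts$manifest))
  shuffled <- paired_counts(sim$counts$counts,
                            sim$counts$manifest[perm, ])
  de2 <- select_de_features(shuffled, de_config("mirna"))
  expect_equal(de1[, setdiff(names(de1), "feature_id")],
               de2[, setdiff(names(de2), "feature_id")],
               tolerance = 1e-10)
})

test_that("relaxing thresholds never shrinks the called set", {
  sim <- simulate_paired_counts(n_features = 300, n_pairs = 12,
                                frac_de = 0.15, logfc_range = c(1, 3),
                                seed = 34)
  strict <- select_de_features(sim$counts, de_config("mirna"))
  relaxed <- select_de_features(
    sim$counts,
    de_config("mirna", fdr_threshold = 1e-3, min_avg_logcpm = 0,
              direction_frac = 0.6, fold_frac = 0.5))
  expect_true(all(strict$feature_id[strict$called] %in%
                    relaxed$feature_id[relaxed$called]))
})
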