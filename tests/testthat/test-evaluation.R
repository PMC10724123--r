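test_that("indicator binarization applies the strict clinical cuts", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     nugent = c(8, 7, NA, 2),
                     ph = c(5.6, 5.5, 4.0, NA),
                     amsel_positive = c(TRUE, FALSE, NA, TRUE))
  hn <- binarize_indicator(meta, "high_nugent")
  expect_identical(unname(hn), c(TRUE, FALSE, NA, FALSE))
  expect_identical(unname(binarize_indicator(meta, "high_nugent",
                                             nugent_ge = TRUE))[2], TRUE)
  ep <- binarize_indicator(meta, "elevated_ph")
  expect_identical(unname(ep), c(TRUE, FALSE, FALSE, NA))
  expect_identical(unname(binarize_indicator(meta, "positive_amsel")),
                   c(TRUE, FALSE, NA, TRUE))
  expect_error(binarize_indicator(meta, "whiff"), "lacks column")
  expect_error(binarize_indicator(meta, "no_such"), "unknown indicator")
})

test_that("ROC handles worked examples and label inversion", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, pairwise_auc(c(0.9, 0.8, 0.2, 0.1),
                                    c(TRUE, FALSE, TRUE, FALSE)))
  r3 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r3$auc, 1 - r2$auc)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both positive and negative")
  # curve endpoints and monotonicity
  expect_equal(r2$points$fpr[1], 0)
  expect_equal(r2$points$tpr[1], 0)
  expect_equal(r2$points$fpr[nrow(r2$points)], 1)
  expect_equal(r2$points$tpr[nrow(r2$points)], 1)
  expect_true(all(diff(r2$points$fpr) >= 0))
  expect_true(all(diff(r2$points$tpr) >= 0))
})

test_that("threshold-sweep AUC equals brute-force pairwise AUC with ties", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- runif(n) < 0.4
    if (sum(labels) == 0 || sum(!labels) == 0) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, pairwise_auc(scores, labels), tolerance = 1e-9)
    trap <- sum(diff(r$points$fpr) *
                  (r$points$tpr[-1] + r$points$tpr[-nrow(r$points)]) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(62)
  scores <- rnorm(100)
  labels <- runif(100) < plogis(scores)
  r <- roc_auc(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         direction = "<"))))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("shuffled null is seeded, centered, and +1-corrected", {
  set.seed(63)
  scores <- runif(500)
  labels <- runif(500) < 0.3
  n1 <- shuffled_null(scores, labels, 100, seed = 9)
  n2 <- shuffled_null(scores, labels, 100, seed = 9)
  expect_identical(n1$null_aucs, n2$null_aucs)
  expect_gte(mean(n1$null_aucs), 0.45)
  expect_lte(mean(n1$null_aucs), 0.55)
  # perfectly separable scores: with 10 positives among 20 samples the
  # chance of a shuffle re-creating the perfect split is ~1/184756
  sep <- shuffled_null(seq(1, 0.05, by = -0.05),
                       rep(c(TRUE, FALSE), each = 10), 100, seed = 10)
  expect_equal(sep$observed_auc, 1.0)
  expect_equal(sep$empirical_p, 1 / 101)
})

test_that("per-arm tests find planted associations and handle degeneracy", {
  coh <- generate_cross_sectional(synthetic_config(n_samples = 400L,
                                                   seed = 71L))
  h <- shannon_index(coh$table$relabund)
  pt <- stats::setNames(coh$truth$latent_b, coh$truth$sample_id)  # ideal label
  arms <- stats::setNames(coh$truth$true_arm, coh$truth$sample_id)
  res <- pseudotime_indicator_tests(pt, coh$metadata, arms, shannon = h,
                                    min_n = 30)
  sh <- res[res$variable %in% "shannon" & !res$excluded, ]
  expect_true(all(sh$estimate > 0))
  expect_true(all(sh$fdr < 0.05))
  # BH is monotone in the raw p-values
  tested <- res[!is.na(res$p_value), ]
  expect_true(all(diff(tested$fdr[order(tested$p_value)]) >= -1e-12))
  # constant pseudotime: correlation undefined, reported NA
  ptc <- stats::setNames(rep(0.5, 40), coh$truth$sample_id[1:40])
  resc <- pseudotime_indicator_tests(ptc, coh$metadata, arms[1:40],
                                     shannon = h[1:40], min_n = 10)
  expect_true(all(is.na(resc$estimate[resc$variable %in% "shannon"])))
  # permuted responses stay non-significant
  set.seed(72)
  hp <- stats::setNames(sample(h), names(h))
  resp <- pseudotime_indicator_tests(pt, coh$metadata, arms, shannon = hp,
                                     min_n = 30)
  shp <- resp[resp$variable %in% "shannon" & !resp$excluded, ]
  expect_true(all(abs(shp$estimate) < 0.2))
  # small arms are excluded, not fatal
  rese <- pseudotime_indicator_tests(pt, coh$metadata, arms, shannon = h,
                                     min_n = 1e5)
  expect_true(all(rese$excluded))
})

test_that("amine contrasts recover the planted significant/flat split", {
  coh <- generate_cross_sectional(synthetic_config(seed = 73L))
  pt <- stats::setNames(coh$truth$latent_b, coh$truth$sample_id)
  am <- coh$metadata[, c("sample_id", "cadaverine", "putrescine", "tyramine",
                         "spermidine", "spermine")]
  res <- amine_contrast(pt, am)
  expect_identical(res$amine[res$fdr < 0.05],
                   c("cadaverine", "putrescine", "tyramine"))
  expect_true(all(res$fdr[res$amine %in% c("spermidine", "spermine")] > 0.05))
  # the >0.9 cut is strict
  pt2 <- stats::setNames(c(0.95, 0.9, 0.1, 0.05), c("a", "b", "c", "d"))
  am2 <- data.frame(sample_id = c("a", "b", "c", "d"), x = c(5, 1, 1, 1))
  r2 <- amine_contrast(pt2, am2)
  expect_identical(r2$n_high, 1L)
})

test_that("sliding windows cover [0,1] in 81 half-open steps", {
  rel <- matrix(0.25, 101, 4,
                dimnames = list(sprintf("s%03d", 0:100), letters[1:4]))
  tab <- composition_table(relabund = rel)
  pt <- stats::setNames(seq(0, 1, by = 0.01), rownames(rel))
  arms <- stats::setNames(rep("I", 101), rownames(rel))
  prof <- arm_abundance_profiles(tab, pt, arms, arms_to_profile = "I")
  expect_identical(length(unique(prof$window_start)), 81L)
  # constant abundance gives constant window means
  expect_true(all(abs(prof$mean_abundance - 0.25) < 1e-12))
  # half-open windows: a sample at 0.20 is not in [0.00, 0.20)
  first <- prof[prof$window_start == 0 & prof$taxon == "a", ]
  expect_identical(first$n_samples, 20L)
  # the closing window [0.80, 1.00] includes the sample at exactly 1
  last <- prof[abs(prof$window_start - 0.8) < 1e-9 & prof$taxon == "a", ]
  expect_identical(last$n_samples, 21L)
  # window means of any table stay inside the observed abundance range
  coh <- generate_cross_sectional(synthetic_config(n_samples = 200L,
                                                   seed = 74L))
  ptc <- stats::setNames(coh$truth$latent_b, coh$truth$sample_id)
  armsc <- stats::setNames(coh$truth$true_arm, coh$truth$sample_id)
  pc <- arm_abundance_profiles(coh$table, ptc, armsc)
  g <- pc[pc$taxon == "Gardnerella_vaginalis" & !is.na(pc$mean_abundance), ]
  rng <- range(coh$table$relabund[, "Gardnerella_vaginalis"])
  expect_true(all(g$mean_abundance >= rng[1] - 1e-12 &
                    g$mean_abundance <= rng[2] + 1e-12))
})
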