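test_that("generation is deterministic given the seed", {
  a <- generate_cross_sectional(synthetic_config(n_samples = 60L, seed = 7L))
  b <- generate_cross_sectional(synthetic_config(n_samples = 60L, seed = 7L))
  expect_identical(a$table$relabund, b$table$relabund)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_cross_sectional(synthetic_config(n_samples = 60L, seed = 8L))
  expect_false(identical(a$table$relabund, c$table$relabund))
  l1 <- generate_longitudinal(synthetic_config(
    n_subjects_longitudinal = 3L, days_per_subject = 10L, seed = 7L))
  l2 <- generate_longitudinal(synthetic_config(
    n_subjects_longitudinal = 3L, days_per_subject = 10L, seed = 7L))
  expect_identical(l1$table$relabund, l2$table$relabund)
  expect_identical(l1$metadata, l2$metadata)
})

test_that("compositions are valid simplex rows with one truth record each", {
  coh <- generate_cross_sectional(synthetic_config(n_samples = 150L, seed = 2L))
  rel <- coh$table$relabund
  expect_true(all(rel >= 0))
  expect_equal(unname(rowSums(rel)), rep(1, nrow(rel)), tolerance = 1e-9)
  expect_identical(coh$truth$sample_id, rownames(rel))
  expect_identical(coh$metadata$sample_id, rownames(rel))
  expect_true(all(coh$truth$latent_b >= 0 & coh$truth$latent_b <= 1))
})

test_that("Amsel's test equals the three-of-four criteria rule", {
  coh <- generate_cross_sectional(synthetic_config(n_samples = 300L, seed = 5L))
  m <- coh$metadata
  n_pos <- m$whiff + m$clue_cells + m$abnormal_fluid + m$elevated_ph_criterion
  expect_identical(m$amsel_positive, n_pos >= 3)
  lg <- generate_longitudinal(synthetic_config(
    n_subjects_longitudinal = 4L, days_per_subject = 20L, seed = 5L))
  m <- lg$metadata
  n_pos <- m$whiff + m$clue_cells + m$abnormal_fluid + m$elevated_ph_criterion
  expect_identical(m$amsel_positive, n_pos >= 3)
})

test_that("noiseless limit reproduces the arm centroid", {
  cfg <- synthetic_config(n_samples = 40L, seed = 3L,
                          dirichlet_concentration = 1e8)
  coh <- generate_cross_sectional(cfg)
  prof <- synthetic_profiles(cfg)
  low <- which(coh$truth$latent_b < 0.05)
  expect_gt(length(low), 0)
  for (i in low) {
    sc <- coh$truth$true_subcst[i]
    expected <- (1 - coh$truth$latent_b[i]) * prof$centroids[sc, ] +
      coh$truth$latent_b[i] * prof$bv_profile
    expect_equal(unname(coh$table$relabund[i, ]), unname(expected),
                 tolerance = 1e-3)
  }
})

test_that("dominant taxon matches the true arm and diversity rises with b", {
  coh <- generate_cross_sectional(synthetic_config(seed = 11L))
  rel <- coh$table$relabund
  dom <- colnames(rel)[max.col(rel)]
  expect_gte(mean(dom == arm_dominant[coh$truth$true_arm]), 0.9)
  h <- shannon_index(rel)
  expect_gte(cor(h, coh$truth$latent_b, method = "spearman"), 0.6)
})

test_that("metadata tracks the latent progression parameter", {
  coh <- generate_cross_sectional(synthetic_config(seed = 13L))
  b <- coh$truth$latent_b
  m <- coh$metadata
  expect_gt(cor(m$nugent, b, method = "spearman"), 0.8)
  expect_gt(cor(m$ph, b), 0.8)
  expect_true(all(m$nugent >= 0 & m$nugent <= 10))
  # amine shift: planted for cadaverine, absent for spermine
  hi <- b > 0.9
  expect_gt(median(m$cadaverine[hi]) / median(m$cadaverine[!hi]), 2)
  expect_lt(abs(log(median(m$spermine[hi]) / median(m$spermine[!hi]))), 0.5)
})

test_that("stable archetype with zero noise yields a constant trajectory", {
  cfg <- synthetic_config(n_subjects_longitudinal = 3L, days_per_subject = 15L,
                          archetype_weights = c(stable = 1, cyclic = 0,
                                                erratic = 0),
                          stable_noise_sd = 0, medication_episode_rate = 0,
                          seed = 4L)
  lg <- generate_longitudinal(cfg)
  for (w in unique(lg$truth$subject_id)) {
    b <- lg$truth$latent_b[lg$truth$subject_id == w]
    expect_equal(b, rep(b[1], length(b)))
  }
})

test_that("cyclic archetype raises b inside the menses window", {
  cfg <- synthetic_config(n_subjects_longitudinal = 6L, days_per_subject = 70L,
                          archetype_weights = c(stable = 0, cyclic = 1,
                                                erratic = 0),
                          medication_episode_rate = 0, seed = 6L)
  lg <- generate_longitudinal(cfg)
  tr <- lg$truth
  md <- lg$metadata
  inw <- logical(nrow(md))
  for (w in unique(md$subject_id)) {
    idx <- md$subject_id == w
    days <- md$day[idx]
    flagged <- days[md$menses_day[idx] != "none"]
    runs <- split(flagged, cumsum(c(TRUE, diff(flagged) > 1)))
    for (r in runs) {
      inw[idx][days >= min(r) - 2 & days <= max(r)] <- TRUE
    }
  }
  expect_gt(mean(tr$latent_b[inw]), mean(tr$latent_b[!inw]))
})

test_that("medication episodes force a monotone decrease in b", {
  cfg <- synthetic_config(n_subjects_longitudinal = 10L,
                          days_per_subject = 70L,
                          medication_episode_rate = 0.02, seed = 9L)
  lg <- generate_longitudinal(cfg)
  md <- lg$metadata
  tr <- lg$truth
  found <- 0
  for (w in unique(md$subject_id)) {
    idx <- which(md$subject_id == w)
    flagged <- md$day[idx][md$medication_day[idx]]
    if (length(flagged) == 0) next
    runs <- split(flagged, cumsum(c(TRUE, diff(flagged) > 1)))
    for (r in runs) {
      b_ep <- tr$latent_b[idx][md$day[idx] %in% r]
      if (length(b_ep) >= 2) {
        found <- found + 1
        expect_true(all(diff(b_ep) < 0))
      }
    }
  }
  expect_gt(found, 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_taxa = 5L), "n_taxa")
  expect_error(synthetic_config(dirichlet_concentration = 0), "positive")
  expect_error(synthetic_config(archetype_weights = c(stable = 0.5,
                                                      cyclic = 0.5,
                                                      erratic = 0.5)),
               "sum to 1")
  expect_error(generate_longitudinal(synthetic_config(days_per_subject = 1L)),
               "days_per_subject")
})
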