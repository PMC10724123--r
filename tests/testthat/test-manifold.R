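test_that("root selection is the strict conjunction of Amsel and diversity", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     amsel_positive = c(TRUE, TRUE, FALSE, TRUE))
  h <- c(a = 3.6, b = 3.5, c = 4.0, d = NA)
  expect_identical(select_roots(meta, h[1:3]), "a")
  meta2 <- data.frame(sample_id = "c", amsel_positive = FALSE)
  expect_error(select_roots(meta2, h["c"]), "no root samples")
  expect_error(select_roots(data.frame(sample_id = "a"), h["a"]),
               "amsel_positive")
})

test_that("identical samples sit at zero graph distance and chains stay chains", {
  m <- matrix(rep(c(0.5, 0.5), each = 3), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  g <- build_graph(composition_table(relabund = m),
                   manifold_config(k_neighbors = 2))
  expect_equal(max(dist(g$pc_scores)), 0)
  off <- g$kernel[upper.tri(g$kernel)]
  expect_true(all(off > 0))
  expect_equal(max(off) - min(off), 0)
  # well-separated 1-D chain: each inner node's nearest two neighbors are
  # its chain neighbors
  tab <- chain_table(20)
  g2 <- build_graph(tab, manifold_config(k_neighbors = 2))
  for (i in 2:19) {
    nb <- order(g2$kernel[i, ], decreasing = TRUE)[1:2]
    expect_setequal(nb, c(i - 1, i + 1))
  }
  expect_error(build_graph(chain_table(5), manifold_config(k_neighbors = 5)),
               "k_neighbors")
})

test_that("disconnected clusters are bridged by a single closest edge", {
  set.seed(31)
  a <- random_simplex(12, 6, seed = 31)
  b <- a
  b[, 1] <- b[, 1] + 50   # push cluster b far away before renormalizing
  b <- b / rowSums(b)
  m <- rbind(a, b)
  rownames(m) <- sprintf("s%02d", 1:24)
  colnames(m) <- sprintf("t%d", 1:6)
  g <- suppressMessages(build_graph(composition_table(relabund = m),
                                    manifold_config(k_neighbors = 3)))
  expect_identical(nrow(g$bridges), 1L)
  gr <- igraph::graph_from_adjacency_matrix(g$kernel > 0, mode = "undirected")
  expect_equal(igraph::components(gr)$no, 1)
})

test_that("transition matrix is stochastic with a unit leading eigenpair", {
  tab <- toy_table(random_simplex(40, 10, seed = 41))
  g <- build_graph(tab, manifold_config(k_neighbors = 5))
  tm <- g$kernel / rowSums(g$kernel)
  expect_equal(unname(rowSums(tm)), rep(1, 40), tolerance = 1e-12)
  eig <- diffusion_pseudotime(g$kernel, sample_ids(tab)[1], 10)
  expect_equal(eig$values[1], 1, tolerance = 1e-9)
  v1 <- eig$vectors[, 1]
  expect_lt(stats::sd(v1 / mean(v1)), 1e-6)  # constant first eigenvector
  expect_true(all(diff(eig$values) <= 1e-12))  # sorted descending
})

test_that("DPT agrees with an independent dense eigendecomposition oracle", {
  tab <- toy_table(random_simplex(50, 20, seed = 5))
  g <- build_graph(tab, manifold_config(k_neighbors = 5))
  for (m in c(10, 15)) {
    d_pkg <- dpt_distances(g$kernel, m)
    d_oracle <- dense_dpt_oracle(g$kernel, m)
    expect_lt(max(abs(d_pkg - unname(d_oracle))), 1e-8)
  }
})

test_that("DPT increases monotonically along a chain from its root", {
  tab <- chain_table(30)
  g <- build_graph(tab, manifold_config(k_neighbors = 3))
  eig <- diffusion_pseudotime(g$kernel, "c01", 15)
  expect_identical(unname(eig$dpt_raw["c01"]), 0)
  expect_true(all(diff(eig$dpt_raw) > 0))
})

test_that("normalization inverts and bounds pseudo-time", {
  expect_equal(normalize_invert(c(0, 2, 4)), c(1, 0.5, 0))
  x <- c(0, runif(50, 0, 10))
  pt <- normalize_invert(x)
  expect_true(all(pt >= 0 & pt <= 1))
  expect_identical(order(pt), rev(order(x)))
  expect_error(normalize_invert(c(0, 0)), "zero")
  expect_error(normalize_invert(c(-1, 2)), "non-negative")
})

test_that("root aggregation min gives zero raw DPT at every root", {
  tab <- toy_table(random_simplex(30, 8, seed = 51))
  g <- build_graph(tab, manifold_config(k_neighbors = 4))
  roots <- sample_ids(tab)[c(2, 9, 17)]
  eig <- diffusion_pseudotime(g$kernel, roots, 10)
  expect_equal(unname(eig$dpt_raw[roots]), rep(0, 3), tolerance = 1e-12)
})

test_that("arm partition flags BV-associated arms", {
  asg <- data.frame(sample_id = c("a", "b", "c"),
                    subcst = c("III-B", "IV-B", "I-A"))
  pa <- partition_arms(asg)
  expect_identical(pa$arm, c("III", "IV-B", "I"))
  expect_identical(pa$bv_associated, c(FALSE, TRUE, FALSE))
})

test_that("layout separates arms, is deterministic, and never feeds pseudo-time", {
  coh <- generate_cross_sectional(synthetic_config(n_samples = 300L, seed = 15L))
  m1 <- fit_manifold(coh$table, coh$metadata)
  m2 <- fit_manifold(coh$table, coh$metadata)
  expect_identical(m1$layout, m2$layout)
  expect_identical(m1$pseudotime, m2$pseudotime)
  # two dominant arms should be farther apart in the layout than within
  arm <- coh$truth$true_arm
  i_idx <- which(arm == "I")[1:40]
  iii_idx <- which(arm == "III")[1:40]
  d <- as.matrix(dist(m1$layout))
  between <- mean(d[i_idx, iii_idx])
  within <- mean(c(d[i_idx, i_idx], d[iii_idx, iii_idx]))
  expect_gt(between, within)
  # perturbing the layout leaves pseudo-time untouched
  m1$layout <- m1$layout + 100
  expect_identical(m1$pseudotime, m2$pseudotime)
  # external embeddings pass through unchanged
  ext <- matrix(seq_len(2 * nrow(m1$layout)), ncol = 2)
  expect_identical(unname(embed_layout(NULL, external = ext)), ext)
})

test_that("fitted models persist to a directory and read back", {
  coh <- generate_cross_sectional(synthetic_config(n_samples = 120L, seed = 16L))
  m <- fit_manifold(coh$table, coh$metadata)
  dir <- withr::local_tempdir()
  write_manifold(m, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "pc_scores.tsv", "edges.tsv", "spectrum.tsv", "eigenvectors.tsv",
    "pseudotime.tsv", "layout.tsv")))))
  back <- read_manifold(dir)
  expect_equal(back$pseudotime$pseudotime,
               unname(m$pseudotime[back$pseudotime$sample_id]),
               tolerance = 1e-9)
  expect_identical(back$pseudotime$is_root,
                   back$pseudotime$sample_id %in% m$root_ids)
})
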