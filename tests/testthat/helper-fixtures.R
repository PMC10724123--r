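# Shared fixtures and independent oracles for the test suite.

# Small composition table from a plain matrix.
toy_table <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  composition_table(relabund = m / rowSums(m))
}

# Random points on the simplex.
random_simplex <- function(n, k, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rgamma(n * k, shape = 2), n, k,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("t%03d", seq_len(k))))
  x / rowSums(x)
}

# Independent dense DPT oracle: eigendecomposes the non-symmetric
# transition matrix directly with base eigen() and applies the DPT formula
# from scratch. Shares no code with the package's symmetric-conjugation
# path.
dense_dpt_oracle <- function(w, m) {
  tm <- w / rowSums(w)
  e <- eigen(tm)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord][seq_len(m)]
  vecs <- Re(e$vectors)[, ord, drop = FALSE][, seq_len(m), drop = FALSE]
  vecs <- apply(vecs, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  wts <- vals[-1] / (1 - vals[-1])
  phi <- vecs[, -1, drop = FALSE] *
    matrix(wts, nrow(w), length(wts), byrow = TRUE)
  as.matrix(stats::dist(phi))
}

# A 1-D chain in two-taxon composition space: sample i sits at fraction
# (i-1)/(n-1) of taxon A.
chain_table <- function(n = 30) {
  p <- seq(0, 1, length.out = n)
  m <- cbind(A = p, B = 1 - p)
  rownames(m) <- sprintf("c%02d", seq_len(n))
  composition_table(relabund = m)
}

# Brute-force AUC over all positive-negative pairs (ties count one half).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Expected dominant taxon per synthetic arm.
arm_dominant <- c(I = "Lactobacillus_crispatus",
                  II = "Lactobacillus_gasseri",
                  III = "Lactobacillus_iners",
                  V = "Lactobacillus_jensenii",
                  "IV-B" = "Gardnerella_vaginalis")
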