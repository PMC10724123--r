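#' Configuration for manifold fitting
#'
#' @param n_pcs number of principal components (capped at n_taxa - 1 and
#'   n_samples - 1).
#' @param k_neighbors neighbors per sample in the kNN graph (>= 2).
#' @param n_diffusion_components number of eigenpairs of the transition
#'   matrix used for diffusion pseudo-time (>= 2).
#' @param root_shannon_threshold Shannon diversity a root sample must
#'   strictly exceed (in addition to a positive Amsel's test).
#' @param clr apply a centered log-ratio transform before PCA (off by
#'   default; the pipeline operates on plain relative abundances).
#' @param density_normalize apply the anisotropic (alpha = 1) kernel
#'   normalization of diffusion maps, dividing each edge weight by the
#'   product of its endpoint degrees. This removes the dependence of the
#'   diffusion operator on sampling density — important when dense daily
#'   longitudinal series sit alongside sparser cross-sectional samples.
#'   Default `TRUE`.
#' @param root_aggregation distance of a sample to the root set: minimum
#'   (default) or mean over roots.
#' @param seed integer seed for any stochastic layout backend.
#' @return A list of class `manifold_config`.
#' @export
manifold_config <- function(n_pcs = 50L, k_neighbors = 15L,
                            n_diffusion_components = 15L,
                            root_shannon_threshold = 3.5,
                            clr = FALSE,
                            density_normalize = TRUE,
                            root_aggregation = c("min", "mean"),
                            seed = 1L) {
  root_aggregation <- match.arg(root_aggregation)
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  if (n_diffusion_components < 2) stop("n_diffusion_components must be >= 2")
  structure(list(n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 n_diffusion_components = as.integer(n_diffusion_components),
                 root_shannon_threshold = root_shannon_threshold,
                 clr = clr,
                 density_normalize = isTRUE(density_normalize),
                 root_aggregation = root_aggregation,
                 seed = as.integer(seed)),
            class = "manifold_config")
}

#' Select BV root samples
#'
#' Root samples anchor the pseudo-time at the BV state: samples with a
#' positive Amsel's test and Shannon diversity strictly above the threshold.
#'
#' @param meta metadata data frame with `sample_id` and `amsel_positive`.
#' @param shannon named per-sample Shannon diversity vector.
#' @param threshold diversity threshold (default 3.5, strict).
#' @return Character vector of root sample identifiers.
#' @export
select_roots <- function(meta, shannon, threshold = 3.5) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  if (!"amsel_positive" %in% names(meta)) {
    stop("metadata lacks 'amsel_positive'; roots cannot be selected")
  }
  amsel <- meta$amsel_positive[match(names(shannon), meta$sample_id)]
  roots <- names(shannon)[!is.na(amsel) & amsel & shannon > threshold]
  if (length(roots) == 0) {
    stop("no root samples found; review the Amsel flags and the Shannon ",
         "threshold (currently ", threshold, ")")
  }
  roots
}

#' Build the PCA basis and kNN kernel graph
#'
#' Centers the relative abundances, computes principal components, and
#' builds a k-nearest-neighbor graph on the PC scores under Euclidean
#' distance. The graph is symmetrized by union and edges are weighted by an
#' adaptive Gaussian kernel, `exp(-d^2 / (sigma_i * sigma_j))`, where
#' `sigma_i` is sample i's distance to its k-th neighbor. If the graph is
#' disconnected, components are bridged by the single closest cross-component
#' pair until connected; every added edge is recorded. Unless disabled in
#' the config, the kernel is finally density-normalized (divided by the
#' endpoint degree product) so the diffusion geometry does not depend on
#' local sampling density.
#'
#' @param x a `composition_table` with relative abundances.
#' @param config a `manifold_config`.
#' @return List with `pc_scores`, dense symmetric `kernel` matrix, `sigma`,
#'   and a data frame `bridges` of edges added for connectivity.
#' @export
build_graph <- function(x, config = manifold_config()) {
  stopifnot(inherits(x, "composition_table"))
  if (is.null(x$relabund)) stop("relative abundances required")
  rel <- x$relabund
  n <- nrow(rel)
  k <- config$k_neighbors
  if (k >= n) stop("k_neighbors must be smaller than the number of samples")
  dat <- rel
  if (isTRUE(config$clr)) {
    pc <- min(dat[dat > 0]) / 2
    dat <- log(dat + pc)
    dat <- dat - rowMeans(dat)
  }
  n_pcs <- min(config$n_pcs, ncol(dat) - 1L, n - 1L)
  pr <- stats::prcomp(dat, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- rownames(rel)

  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  sigma <- d[cbind(seq_len(n), nn[, k])]
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), k), as.vector(nn))] <- TRUE
  adj <- adj | t(adj)

  ss <- pmax(outer(sigma, sigma), .Machine$double.xmin)
  w <- exp(-d^2 / ss)
  w[d == 0] <- 1
  w[!adj] <- 0
  diag(w) <- 0

  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  bridges <- data.frame(from = character(0), to = character(0),
                        distance = numeric(0), weight = numeric(0),
                        stringsAsFactors = FALSE)
  while (length(unique(comp)) > 1) {
    dmask <- d
    dmask[outer(comp, comp, "==")] <- Inf
    idx <- arrayInd(which.min(dmask), dim(dmask))
    i <- idx[1]; j <- idx[2]
    wt <- max(exp(-d[i, j]^2 / ss[i, j]), 1e-6)
    w[i, j] <- w[j, i] <- wt
    bridges <- rbind(bridges, data.frame(
      from = rownames(rel)[i], to = rownames(rel)[j],
      distance = d[i, j], weight = wt, stringsAsFactors = FALSE))
    comp[comp == comp[j]] <- comp[i]
  }
  if (nrow(bridges) > 0) {
    message("bridged ", nrow(bridges), " disconnected component pair(s)")
  }
  if (isTRUE(config$density_normalize)) {
    q <- rowSums(w)
    w <- w / outer(q, q)
  }
  dimnames(w) <- list(rownames(rel), rownames(rel))
  list(pc_scores = scores, kernel = w, sigma = sigma, bridges = bridges)
}

# Top-m eigenpairs of the row-stochastic transition matrix T = D^-1 W,
# obtained through the symmetric conjugate S = D^-1/2 W D^-1/2. Right
# eigenvectors are normalized to unit Euclidean norm with the
# largest-magnitude entry forced positive.
transition_spectrum <- function(w, m) {
  deg <- rowSums(w)
  if (any(deg <= 0)) stop("graph has isolated node(s)")
  s <- 1 / sqrt(deg)
  sym <- w * outer(s, s)
  e <- eigen(sym, symmetric = TRUE)
  m <- min(m, nrow(w))
  vals <- e$values[seq_len(m)]
  psi <- e$vectors[, seq_len(m), drop = FALSE] * s
  psi <- apply(psi, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  rownames(psi) <- rownames(w)
  list(values = vals, vectors = psi)
}

# Diffusion-weighted coordinates: psi_i scaled by lambda_i / (1 - lambda_i)
# for i >= 2; squared differences of these give DPT^2.
dpt_coords <- function(spec) {
  vals <- spec$values
  if (length(vals) < 2) stop("need at least two diffusion components")
  if (vals[2] >= 1 - 1e-12) {
    stop("second eigenvalue is 1: the graph is effectively disconnected")
  }
  wts <- vals[-1] / (1 - vals[-1])
  spec$vectors[, -1, drop = FALSE] *
    matrix(wts, nrow(spec$vectors), length(wts), byrow = TRUE)
}

#' Diffusion pseudo-time distances from a root set
#'
#' Row-normalizes the kernel into a transition matrix, computes its top
#' eigenpairs, and measures the diffusion pseudo-time (DPT) distance
#' `dpt(x, y)^2 = sum_{i>=2} (lambda_i / (1 - lambda_i))^2 *
#' (psi_i(x) - psi_i(y))^2`. A sample's raw DPT is its minimum (or mean)
#' DPT distance to the root set.
#'
#' @param w symmetric kernel matrix from [build_graph()].
#' @param roots sample identifiers (or indices) of the root set.
#' @param n_components number of eigenpairs (including the trivial first).
#' @param root_aggregation `"min"` (default) or `"mean"` over roots.
#' @return List with `dpt_raw` (0 at roots under `"min"`), `values`
#'   (eigenvalues, descending, first ~1) and `vectors` (unit-norm right
#'   eigenvectors of the transition matrix).
#' @export
diffusion_pseudotime <- function(w, roots, n_components = 15L,
                                 root_aggregation = c("min", "mean")) {
  root_aggregation <- match.arg(root_aggregation)
  if (length(roots) == 0) stop("empty root set")
  if (is.character(roots)) {
    ridx <- match(roots, rownames(w))
    if (anyNA(ridx)) stop("unknown root sample(s)")
  } else {
    ridx <- as.integer(roots)
  }
  spec <- transition_spectrum(w, n_components)
  phi <- dpt_coords(spec)
  dmat <- vapply(ridx, function(r) {
    sqrt(rowSums((phi - matrix(phi[r, ], nrow(phi), ncol(phi),
                               byrow = TRUE))^2))
  }, numeric(nrow(phi)))
  dpt_raw <- if (root_aggregation == "min") {
    apply(dmat, 1, min)
  } else {
    rowMeans(dmat)
  }
  names(dpt_raw) <- rownames(w)
  list(dpt_raw = dpt_raw, values = spec$values, vectors = spec$vectors)
}

#' Full pairwise DPT distance matrix
#'
#' @param w symmetric kernel matrix.
#' @param n_components number of eigenpairs.
#' @return Dense samples x samples matrix of DPT distances.
#' @export
dpt_distances <- function(w, n_components = 15L) {
  spec <- transition_spectrum(w, n_components)
  as.matrix(stats::dist(dpt_coords(spec)))
}

#' Normalize and invert raw DPT into pseudo-time
#'
#' pseudotime = 1 - dpt_raw / max(dpt_raw): roots sit at 1 (the BV state)
#' and the farthest, healthiest sample at 0.
#'
#' @param dpt_raw non-negative raw DPT vector with positive maximum.
#' @return Pseudo-time vector in \[0, 1\].
#' @export
normalize_invert <- function(dpt_raw) {
  if (any(dpt_raw < 0)) stop("dpt_raw must be non-negative")
  mx <- max(dpt_raw)
  if (mx == 0) stop("all DPT distances are zero; cannot normalize")
  1 - dpt_raw / mx
}

#' Attach arm labels from CST assignments
#'
#' @param assignments data frame from [assign_cst()].
#' @return Data frame with `sample_id`, `arm` and logical `bv_associated`
#'   (arms IV-A, IV-B, IV-C).
#' @export
partition_arms <- function(assignments) {
  stopifnot(all(c("sample_id", "subcst") %in% names(assignments)))
  arm <- merge_to_arm(assignments$subcst)
  data.frame(sample_id = assignments$sample_id,
             arm = arm,
             bv_associated = arm %in% bv_arms(),
             stringsAsFactors = FALSE)
}

#' Two-dimensional layout of the manifold
#'
#' Visualization only: the default spectral layout places samples by the
#' second and third eigenvectors of the transition operator (equivalently,
#' the leading non-trivial eigenvectors of the normalized graph Laplacian).
#' An externally computed embedding (e.g. UMAP coordinates) may be passed
#' through instead. Pseudo-time never reads these coordinates.
#'
#' @param spec eigen-decomposition (`values`, `vectors`) as returned by
#'   [diffusion_pseudotime()].
#' @param external optional samples x 2 matrix to pass through.
#' @return Samples x 2 matrix with columns `x`, `y`.
#' @export
embed_layout <- function(spec, external = NULL) {
  if (!is.null(external)) {
    stopifnot(is.matrix(external), ncol(external) == 2)
    colnames(external) <- c("x", "y")
    return(external)
  }
  if (ncol(spec$vectors) < 3) stop("need at least three eigenvectors")
  xy <- spec$vectors[, 2:3, drop = FALSE]
  colnames(xy) <- c("x", "y")
  xy
}

#' Fit the composition manifold and pseudo-time
#'
#' End-to-end manifold stage: Shannon diversity, root selection, kNN kernel
#' graph on PC scores, diffusion pseudo-time from the roots, inversion and
#' normalization into \[0, 1\], arm labels (when CST assignments are given)
#' and a 2-D spectral layout.
#'
#' @param x a `composition_table` with relative abundances.
#' @param meta metadata data frame (needs `amsel_positive` for roots).
#' @param config a `manifold_config`.
#' @param assignments optional data frame from [assign_cst()].
#' @return An object of class `bv_manifold`.
#' @export
fit_manifold <- function(x, meta, config = manifold_config(),
                         assignments = NULL) {
  stopifnot(inherits(x, "composition_table"))
  validate_metadata(x, meta)
  shannon <- shannon_index(x$relabund)
  roots <- select_roots(meta, shannon, config$root_shannon_threshold)
  graph <- build_graph(x, config)
  eig <- diffusion_pseudotime(graph$kernel, roots,
                              config$n_diffusion_components,
                              config$root_aggregation)
  pt <- normalize_invert(eig$dpt_raw)
  arms <- if (!is.null(assignments)) {
    pa <- partition_arms(assignments)
    pa$arm[match(sample_ids(x), pa$sample_id)]
  } else {
    rep(NA_character_, nrow(x$relabund))
  }
  layout <- embed_layout(eig)
  structure(list(sample_ids = sample_ids(x),
                 config = config,
                 pc_scores = graph$pc_scores,
                 kernel = graph$kernel,
                 bridges = graph$bridges,
                 eigenvalues = eig$values,
                 eigenvectors = eig$vectors,
                 root_ids = roots,
                 shannon = shannon,
                 dpt_raw = eig$dpt_raw,
                 pseudotime = pt,
                 arms = arms,
                 layout = layout),
            class = "bv_manifold")
}

#' @export
print.bv_manifold <- function(x, ...) {
  cat(sprintf(paste0("bv_manifold: %d samples, %d PCs, %d diffusion ",
                     "components, %d root(s)\n"),
              length(x$sample_ids), ncol(x$pc_scores),
              length(x$eigenvalues), length(x$root_ids)))
  cat(sprintf("  pseudotime: min %.3f / median %.3f / max %.3f\n",
              min(x$pseudotime), stats::median(x$pseudotime),
              max(x$pseudotime)))
  invisible(x)
}

#' Persist a fitted manifold model as a directory of TSV files
#'
#' Writes `pc_scores.tsv`, `edges.tsv` (i, j, weight for every kernel
#' edge), `spectrum.tsv` (eigenvalues), `eigenvectors.tsv`,
#' `pseudotime.tsv` (sample_id, dpt_raw, pseudotime, arm, is_root) and
#' `layout.tsv`.
#'
#' @param model a `bv_manifold`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_manifold <- function(model, dir) {
  stopifnot(inherits(model, "bv_manifold"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(data.frame(sample_id = model$sample_ids, model$pc_scores,
                check.names = FALSE), "pc_scores.tsv")
  ut <- which(upper.tri(model$kernel) & model$kernel > 0, arr.ind = TRUE)
  wt(data.frame(i = model$sample_ids[ut[, 1]],
                j = model$sample_ids[ut[, 2]],
                weight = model$kernel[ut]), "edges.tsv")
  wt(data.frame(component = seq_along(model$eigenvalues),
                eigenvalue = model$eigenvalues), "spectrum.tsv")
  wt(data.frame(sample_id = model$sample_ids, model$eigenvectors,
                check.names = FALSE), "eigenvectors.tsv")
  wt(data.frame(sample_id = model$sample_ids,
                dpt_raw = model$dpt_raw,
                pseudotime = model$pseudotime,
                arm = model$arms,
                is_root = model$sample_ids %in% model$root_ids),
     "pseudotime.tsv")
  wt(data.frame(sample_id = model$sample_ids, model$layout,
                check.names = FALSE), "layout.tsv")
  invisible(dir)
}

#' Load the per-sample outputs of a persisted manifold
#'
#' Reads back the pseudo-time and layout tables of a model directory; this
#' is the information [project_samples()] needs alongside the reference
#' composition table.
#'
#' @param dir model directory written by [write_manifold()].
#' @return List with `pseudotime` and `layout` data frames.
#' @export
read_manifold <- function(dir) {
  pt <- utils::read.delim(file.path(dir, "pseudotime.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  lay <- utils::read.delim(file.path(dir, "layout.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  list(pseudotime = pt, layout = lay)
}
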