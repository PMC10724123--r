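#' Yue-Clayton theta similarity
#'
#' theta = sum(a*b) / (sum(a^2) + sum(b^2) - sum(a*b)), the community
#' similarity used for centroid-based CST assignment. Equals 1 for identical
#' compositions and 0 for disjoint supports.
#'
#' @param a,b aligned non-negative abundance vectors.
#' @return Similarity in \[0, 1\].
#' @export
yue_clayton_theta <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("negative abundances")
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) stop("both vectors are all-zero")
  ab / denom
}

#' Fit CST centroids from labeled samples
#'
#' Each centroid is the arithmetic mean of the relative abundances of the
#' samples carrying that label, re-normalized to sum to 1. This enables
#' closed-loop testing on labeled synthetic cohorts; the published reference
#' centroids can be loaded instead with [read_centroids()].
#'
#' @param x a `composition_table` with relative abundances.
#' @param labels subCST (or arm) label per sample, in sample order.
#' @return A `centroid_set`: list with `labels` and a labels x taxa
#'   `centroids` matrix.
#' @export
fit_centroids <- function(x, labels) {
  stopifnot(inherits(x, "composition_table"))
  if (is.null(x$relabund)) stop("relative abundances required")
  rel <- x$relabund
  if (length(labels) != nrow(rel)) stop("one label per sample required")
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain NA")
  uls <- sort(unique(labels))
  cen <- t(vapply(uls, function(l) {
    colMeans(rel[labels == l, , drop = FALSE])
  }, numeric(ncol(rel))))
  cen <- cen / rowSums(cen)
  rownames(cen) <- uls
  structure(list(labels = uls, centroids = cen), class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d centroids over %d taxa (%s)\n",
              length(x$labels), ncol(x$centroids),
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}

#' Read and write centroid sets as CSV
#'
#' Format: a `label` column followed by one column per taxon, matching the
#' layout of published VALENCIA-style reference centroid files.
#'
#' @param path file path.
#' @return `read_centroids` returns a `centroid_set`.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "label") stop("first column must be 'label'")
  cen <- as.matrix(df[, -1, drop = FALSE])
  rownames(cen) <- as.character(df$label)
  cen <- cen / rowSums(cen)
  structure(list(labels = rownames(cen), centroids = cen),
            class = "centroid_set")
}

#' @rdname read_centroids
#' @param refs a `centroid_set`.
#' @export
write_centroids <- function(refs, path) {
  stopifnot(inherits(refs, "centroid_set"))
  df <- data.frame(label = rownames(refs$centroids), refs$centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge subCST labels into manifold arms
#'
#' I-A and I-B merge to I; III-A and III-B to III; IV-C0..IV-C4 to IV-C;
#' all other known labels (II, IV-A, IV-B, V, and already-merged labels)
#' map to themselves.
#'
#' @param subcst character vector of subCST labels.
#' @return Character vector of arm labels.
#' @examples
#' merge_to_arm(c("I-B", "IV-C3", "V"))
#' @export
merge_to_arm <- function(subcst) {
  map <- c("I-A" = "I", "I-B" = "I", "II" = "II",
           "III-A" = "III", "III-B" = "III",
           "IV-A" = "IV-A", "IV-B" = "IV-B",
           "IV-C0" = "IV-C", "IV-C1" = "IV-C", "IV-C2" = "IV-C",
           "IV-C3" = "IV-C", "IV-C4" = "IV-C", "V" = "V",
           "I" = "I", "III" = "III", "IV-C" = "IV-C")
  subcst <- as.character(subcst)
  unknown <- setdiff(unique(subcst), names(map))
  if (length(unknown) > 0) {
    stop("unknown subCST label(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[subcst])
}

#' Arms considered healthy / BV-associated
#'
#' Healthy arms are the Lactobacillus-dominated I, II, III and V; the
#' BV-associated arms are IV-A, IV-B and IV-C.
#' @return Character vector of arm labels.
#' @export
healthy_arms <- function() c("I", "II", "III", "V")

#' @rdname healthy_arms
#' @export
bv_arms <- function() c("IV-A", "IV-B", "IV-C")

#' Assign community state types by centroid similarity
#'
#' Each sample is compared to every reference centroid and assigned the
#' label of the most similar one. Taxa present in the reference but missing
#' from the table count as zero; taxa absent from the reference are dropped
#' and the sample re-normalized, so both vectors live on a shared simplex.
#' Ties are broken by centroid label order with a warning.
#'
#' @param x a `composition_table` with relative abundances.
#' @param refs a `centroid_set`.
#' @param metric `"yue_clayton"` (default) or `"bray_curtis"` (similarity
#'   taken as 1 - dissimilarity).
#' @return Data frame with columns `sample_id`, `subcst`, `cst_arm`,
#'   `similarity`.
#' @export
assign_cst <- function(x, refs, metric = c("yue_clayton", "bray_curtis")) {
  stopifnot(inherits(x, "composition_table"), inherits(refs, "centroid_set"))
  metric <- match.arg(metric)
  if (length(refs$labels) == 0) stop("empty centroid set")
  if (is.null(x$relabund)) stop("relative abundances required")
  ref_taxa <- colnames(refs$centroids)
  rel <- matrix(0, nrow(x$relabund), length(ref_taxa),
                dimnames = list(rownames(x$relabund), ref_taxa))
  shared <- intersect(colnames(x$relabund), ref_taxa)
  if (length(shared) == 0) stop("no taxa shared with the centroid set")
  rel[, shared] <- x$relabund[, shared, drop = FALSE]
  rs <- rowSums(rel)
  if (any(rs == 0)) {
    stop("sample(s) share no taxa with the centroids: ",
         paste(utils::head(rownames(rel)[rs == 0], 5), collapse = ", "))
  }
  rel <- rel / rs
  cen <- refs$centroids
  if (metric == "yue_clayton") {
    cross <- rel %*% t(cen)
    denom <- outer(rowSums(rel^2), rowSums(cen^2), "+") - cross
    sim <- cross / denom
  } else {
    # rows of rel and cen both sum to 1, so 1 - BC reduces to sum(pmin)
    sim <- vapply(seq_len(nrow(cen)), function(j) {
      rowSums(pmin(rel, matrix(cen[j, ], nrow(rel), ncol(rel), byrow = TRUE)))
    }, numeric(nrow(rel)))
    dimnames(sim) <- list(rownames(rel), rownames(cen))
  }
  best <- max.col(sim, ties.method = "first")
  n_best <- rowSums(sim == sim[cbind(seq_len(nrow(sim)), best)])
  if (any(n_best > 1)) {
    warning(sum(n_best > 1),
            " sample(s) had tied centroid similarities; first label kept")
  }
  subcst <- rownames(cen)[best]
  data.frame(sample_id = rownames(rel),
             subcst = subcst,
             cst_arm = merge_to_arm(subcst),
             similarity = sim[cbind(seq_len(nrow(sim)), best)],
             stringsAsFactors = FALSE)
}
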