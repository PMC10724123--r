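#' Project new samples onto a fitted manifold
#'
#' Each query is matched to its nearest reference sample under Bray-Curtis
#' dissimilarity on the full relative-abundance vectors (not PC scores) and
#' inherits that sample's pseudo-time, arm and layout coordinates. Queries
#' are first aligned to the reference taxon list: missing taxa are
#' zero-filled, extra taxa dropped, and rows re-normalized. Ties are broken
#' by reference sample order and reported.
#'
#' @param queries a `composition_table` of new samples (relative abundances).
#' @param model a fitted `bv_manifold`.
#' @param reference the `composition_table` the model was fitted on.
#' @param k number of neighbors; the default 1 matches the single
#'   nearest-neighbor rule. With k > 1 the inherited pseudo-time is the mean
#'   over the k nearest references (arm and layout come from the nearest).
#' @return Data frame with `query_id`, `matched_id`, `distance`,
#'   `pseudotime`, `arm`, `layout_x`, `layout_y`.
#' @export
project_samples <- function(queries, model, reference, k = 1L) {
  stopifnot(inherits(queries, "composition_table"),
            inherits(model, "bv_manifold"),
            inherits(reference, "composition_table"))
  if (is.null(queries$relabund) || is.null(reference$relabund)) {
    stop("relative abundances required for projection")
  }
  ref <- reference$relabund
  if (nrow(ref) == 0) stop("empty reference table")
  if (!identical(rownames(ref), model$sample_ids)) {
    stop("reference samples do not match the fitted model")
  }
  qt <- matrix(0, nrow(queries$relabund), ncol(ref),
               dimnames = list(rownames(queries$relabund), colnames(ref)))
  shared <- intersect(colnames(queries$relabund), colnames(ref))
  if (length(shared) == 0) stop("queries share no taxa with the reference")
  qt[, shared] <- queries$relabund[, shared, drop = FALSE]
  rs <- rowSums(qt)
  if (any(rs == 0)) {
    stop("query sample(s) share no taxa with the reference: ",
         paste(utils::head(rownames(qt)[rs == 0], 5), collapse = ", "))
  }
  # renormalize only queries that actually lost mass in the alignment, so a
  # query identical to a reference sample stays bit-identical to it
  renorm <- abs(rs - 1) > 1e-9
  qt[renorm, ] <- qt[renorm, , drop = FALSE] / rs[renorm]

  n_ties <- 0L
  res <- lapply(seq_len(nrow(qt)), function(i) {
    q <- matrix(qt[i, ], nrow(ref), ncol(ref), byrow = TRUE)
    # full Bray-Curtis form: exactly 0 when a query equals a reference row
    d <- 1 - 2 * rowSums(pmin(ref, q)) / (rowSums(ref) + sum(qt[i, ]))
    best <- which.min(d)
    if (sum(d == d[best]) > 1) n_ties <<- n_ties + 1L
    pt <- if (k > 1) {
      mean(model$pseudotime[order(d)[seq_len(min(k, length(d)))]])
    } else {
      model$pseudotime[best]
    }
    list(best = best, distance = d[best], pseudotime = pt)
  })
  if (n_ties > 0) {
    message(n_ties, " query sample(s) had tied nearest neighbors; ",
            "first reference kept")
  }
  best <- vapply(res, `[[`, integer(1), "best")
  data.frame(query_id = rownames(qt),
             matched_id = model$sample_ids[best],
             distance = vapply(res, `[[`, numeric(1), "distance"),
             pseudotime = vapply(res, `[[`, numeric(1), "pseudotime"),
             arm = model$arms[best],
             layout_x = model$layout[best, "x"],
             layout_y = model$layout[best, "y"],
             stringsAsFactors = FALSE)
}
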