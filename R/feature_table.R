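#' Construct a composition table
#'
#' A composition table holds a samples x taxa abundance matrix, either as raw
#' read counts, relative abundances (rows summing to 1), or both. Sample and
#' taxon identifiers are carried as dimnames and must be unique.
#'
#' @param counts optional non-negative numeric matrix of read counts with
#'   sample row names and taxon column names.
#' @param relabund optional matrix of relative abundances; each row must sum
#'   to 1 within 1e-9.
#' @return An object of class `composition_table`.
#' @examples
#' m <- matrix(c(2, 2, 3, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("tA", "tB")))
#' tab <- composition_table(counts = m)
#' to_relative(tab)
#' @export
composition_table <- function(counts = NULL, relabund = NULL) {
  if (is.null(counts) && is.null(relabund)) {
    stop("supply at least one of 'counts' or 'relabund'")
  }
  check <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m)) {
      stop(what, " must be a numeric matrix")
    }
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop(what, " must carry sample row names and taxon column names")
    }
    if (anyDuplicated(rownames(m)) > 0) stop("duplicate sample identifiers")
    if (anyDuplicated(colnames(m)) > 0) stop("duplicate taxon identifiers")
    if (any(m < 0)) stop(what, " contains negative values")
    m
  }
  if (!is.null(counts)) counts <- check(counts, "'counts'")
  if (!is.null(relabund)) {
    relabund <- check(relabund, "'relabund'")
    bad <- abs(rowSums(relabund) - 1) > 1e-9
    if (any(bad)) {
      stop("relative-abundance rows must sum to 1; offending samples: ",
           paste(utils::head(rownames(relabund)[bad], 5), collapse = ", "))
    }
  }
  if (!is.null(counts) && !is.null(relabund) &&
      !identical(dimnames(counts), dimnames(relabund))) {
    stop("'counts' and 'relabund' must share identical dimnames")
  }
  structure(list(counts = counts, relabund = relabund),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  m <- if (!is.null(x$relabund)) x$relabund else x$counts
  cat(sprintf("composition_table: %d samples x %d taxa (%s%s)\n",
              nrow(m), ncol(m),
              if (!is.null(x$counts)) "counts" else "",
              if (!is.null(x$relabund)) {
                if (!is.null(x$counts)) " + relabund" else "relabund"
              } else ""))
  invisible(x)
}

#' Sample and taxon identifiers of a composition table
#' @param x a `composition_table`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  rownames(if (!is.null(x$relabund)) x$relabund else x$counts)
}

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  colnames(if (!is.null(x$relabund)) x$relabund else x$counts)
}

#' Filter samples and taxa by sequencing depth
#'
#' Drops samples whose total read count is not strictly greater than
#' `min_sample_reads`, then taxa whose total count (over the retained
#' samples) is not strictly greater than `min_taxon_reads`. Thresholds are
#' strict: a sample with exactly 1000 reads, or a taxon with exactly 100
#' reads, is dropped. The identifiers removed at each step are attached as
#' attributes `dropped_samples` and `dropped_taxa`.
#'
#' @param x a `composition_table` carrying counts.
#' @param min_sample_reads samples must exceed this total to be kept.
#' @param min_taxon_reads taxa must exceed this total to be kept.
#' @return Filtered `composition_table` (counts only).
#' @export
filter_by_depth <- function(x, min_sample_reads = 1000, min_taxon_reads = 100) {
  stopifnot(inherits(x, "composition_table"))
  if (is.null(x$counts)) stop("depth filtering requires read counts")
  keep_s <- rowSums(x$counts) > min_sample_reads
  dropped_samples <- rownames(x$counts)[!keep_s]
  cnt <- x$counts[keep_s, , drop = FALSE]
  if (nrow(cnt) == 0) {
    warning("depth filter removed every sample")
    out <- structure(list(counts = cnt, relabund = NULL),
                     class = "composition_table")
    attr(out, "dropped_samples") <- dropped_samples
    attr(out, "dropped_taxa") <- character(0)
    return(out)
  }
  keep_t <- colSums(cnt) > min_taxon_reads
  dropped_taxa <- colnames(cnt)[!keep_t]
  cnt <- cnt[, keep_t, drop = FALSE]
  if (ncol(cnt) == 0) warning("depth filter removed every taxon")
  out <- composition_table(counts = cnt)
  attr(out, "dropped_samples") <- dropped_samples
  attr(out, "dropped_taxa") <- dropped_taxa
  out
}

#' Transform counts to relative abundances
#'
#' @param x a `composition_table` carrying counts.
#' @return The table with `relabund` set to counts divided by per-sample
#'   totals; every row sums to 1.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  if (is.null(x$counts)) stop("'counts' required to compute relative abundances")
  tot <- rowSums(x$counts)
  if (any(tot == 0)) {
    stop("zero-total sample(s): ",
         paste(utils::head(rownames(x$counts)[tot == 0], 5), collapse = ", "))
  }
  rel <- x$counts / tot
  composition_table(counts = x$counts, relabund = rel)
}

#' Remove rare taxa by prevalence and mean abundance
#'
#' Keeps a taxon only if its prevalence (fraction of samples in which it is
#' non-zero) strictly exceeds `min_prevalence` and (by default) its mean
#' relative abundance across all samples strictly exceeds
#' `min_mean_abundance`. Rows are re-normalized to sum to 1 afterwards.
#'
#' @param x a `composition_table` carrying relative abundances.
#' @param min_prevalence prevalence must exceed this value (default 1e-4).
#' @param min_mean_abundance mean relative abundance must exceed this value
#'   (default 5e-5).
#' @param combine `"and"` (default) keeps taxa passing both rules; `"or"`
#'   keeps taxa passing either.
#' @return Filtered, re-normalized `composition_table` (relative abundances;
#'   counts, when present, are subset without re-normalization). Dropped
#'   taxa are attached as attribute `dropped_taxa`.
#' @export
filter_rare_taxa <- function(x, min_prevalence = 1e-4,
                             min_mean_abundance = 5e-5,
                             combine = c("and", "or")) {
  stopifnot(inherits(x, "composition_table"))
  combine <- match.arg(combine)
  if (is.null(x$relabund)) stop("rare-taxon filtering requires relative abundances")
  rel <- x$relabund
  prev <- colMeans(rel > 0)
  mab <- colMeans(rel)
  keep <- if (combine == "and") {
    prev > min_prevalence & mab > min_mean_abundance
  } else {
    prev > min_prevalence | mab > min_mean_abundance
  }
  dropped <- colnames(rel)[!keep]
  rel <- rel[, keep, drop = FALSE]
  if (ncol(rel) == 0) {
    warning("rare-taxon filter removed every taxon")
    out <- structure(list(counts = NULL, relabund = rel),
                     class = "composition_table")
    attr(out, "dropped_taxa") <- dropped
    return(out)
  }
  rs <- rowSums(rel)
  if (any(rs == 0)) {
    stop("sample(s) left empty after rare-taxon removal: ",
         paste(utils::head(rownames(rel)[rs == 0], 5), collapse = ", "))
  }
  rel <- rel / rs
  cnt <- if (!is.null(x$counts)) x$counts[, keep, drop = FALSE] else NULL
  # counts and relabund no longer agree row-wise after re-normalization, so
  # bypass the cross-consistency check of the constructor.
  out <- structure(list(counts = cnt, relabund = rel),
                   class = "composition_table")
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Shannon diversity index
#'
#' H = -sum(p * ln p) over the non-zero entries of a relative-abundance
#' vector (natural logarithm). For a matrix, the index is computed row-wise.
#'
#' @param p relative-abundance vector, or a samples x taxa matrix.
#' @return A single value, or a named vector for matrix input.
#' @examples
#' shannon_index(rep(0.25, 4))  # ln(4)
#' @export
shannon_index <- function(p) {
  if (is.matrix(p)) {
    if (any(p < 0)) stop("negative abundances")
    h <- -rowSums(p * log(ifelse(p > 0, p, 1)))
    names(h) <- rownames(p)
    return(h)
  }
  if (any(p < 0)) stop("negative abundances")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' d = 1 - 2 * sum(min(a, b)) / (sum(a) + sum(b)); 0 for identical vectors,
#' 1 for disjoint supports.
#'
#' @param a,b non-negative abundance vectors over the same taxon ordering.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("negative abundances")
  s <- sum(a) + sum(b)
  if (s == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(a, b)) / s
}

#' Read and write composition tables as TSV
#'
#' Tables are stored with samples as rows: the first column is `sample_id`,
#' the remaining columns are taxa. Identifier order is preserved on a
#' round-trip.
#'
#' @param path file path.
#' @param type `"auto"` treats an all-integer table as counts, otherwise as
#'   relative abundances; or force with `"counts"` / `"relabund"`.
#' @return `read_composition` returns a `composition_table`.
#' @export
read_composition <- function(path, type = c("auto", "counts", "relabund")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$sample_id)
  if (type == "auto") {
    type <- if (all(m == round(m)) && max(m) > 1) "counts" else "relabund"
  }
  if (type == "counts") composition_table(counts = m)
  else composition_table(relabund = m)
}

#' @rdname read_composition
#' @param x a `composition_table`.
#' @param what which matrix to write when both are present.
#' @export
write_composition <- function(x, path, what = c("relabund", "counts")) {
  stopifnot(inherits(x, "composition_table"))
  what <- match.arg(what)
  m <- x[[what]]
  if (is.null(m)) stop("table does not carry '", what, "'")
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample metadata as TSV
#'
#' Metadata carries one row per sample with a `sample_id` column and any of
#' the clinical and longitudinal covariates used downstream (`subject_id`,
#' `day`, `nugent`, `ph`, `amsel_positive`, the four Amsel criteria,
#' `menses_day`, `medication_day`, amine concentrations, `dataset_id`).
#'
#' @param path file path.
#' @return `read_metadata` returns a data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_metadata
#' @param meta a data frame with a `sample_id` column.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a BIOM-format table
#'
#' Thin wrapper over the biomformat package; returns the table oriented
#' samples x taxa as a `composition_table` of counts.
#'
#' @param path path to a BIOM file.
#' @return A `composition_table`.
#' @export
read_biom_composition <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("package 'biomformat' is required for BIOM import")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  composition_table(counts = m)
}

#' Check that metadata matches a composition table
#'
#' @param x a `composition_table`.
#' @param meta a metadata data frame.
#' @return Invisibly `TRUE`; errors when samples are missing from `meta` or
#'   when a present `nugent`/`ph` value is out of range.
#' @export
validate_metadata <- function(x, meta) {
  ids <- sample_ids(x)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing) > 0) {
    stop("metadata missing for samples: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if ("nugent" %in% names(meta)) {
    n <- meta$nugent[!is.na(meta$nugent)]
    if (any(n < 0 | n > 10)) stop("nugent scores must lie in [0, 10]")
  }
  if ("ph" %in% names(meta)) {
    p <- meta$ph[!is.na(meta$ph)]
    if (any(p <= 0)) stop("pH values must be positive")
  }
  invisible(TRUE)
}
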