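#' Binarize a clinical BV indicator
#'
#' `high_nugent` is Nugent > 7 (strict; switch with `nugent_ge`),
#' `elevated_ph` is pH > 5.5 (strict); `positive_amsel`, `whiff`,
#' `clue_cells` and `abnormal_fluid` pass through the stored booleans.
#' Missing values stay `NA` and are excluded by downstream analyses, never
#' imputed.
#'
#' @param meta metadata data frame with a `sample_id` column.
#' @param indicator one of `"high_nugent"`, `"positive_amsel"`,
#'   `"elevated_ph"`, `"whiff"`, `"clue_cells"`, `"abnormal_fluid"`.
#' @param nugent_ge use the conventional Nugent >= 7 rule instead of the
#'   strict > 7 rule.
#' @return Named logical vector (NA where the source value is missing).
#' @export
binarize_indicator <- function(meta, indicator, nugent_ge = FALSE) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  need <- function(col) {
    if (!col %in% names(meta)) {
      stop("metadata lacks column '", col, "' needed for indicator '",
           indicator, "'")
    }
    meta[[col]]
  }
  v <- switch(indicator,
    high_nugent = if (nugent_ge) need("nugent") >= 7 else need("nugent") > 7,
    positive_amsel = as.logical(need("amsel_positive")),
    elevated_ph = need("ph") > 5.5,
    whiff = as.logical(need("whiff")),
    clue_cells = as.logical(need("clue_cells")),
    abnormal_fluid = as.logical(need("abnormal_fluid")),
    stop("unknown indicator: ", indicator)
  )
  names(v) <- meta$sample_id
  v
}

#' All supported indicator names
#' @return Character vector.
#' @export
indicator_names <- function() {
  c("high_nugent", "positive_amsel", "elevated_ph", "whiff", "clue_cells",
    "abnormal_fluid")
}

# Rank (Mann-Whitney) AUC with ties counted one half.
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC for predicting a binary indicator from pseudo-time
#'
#' Sweeps the classification threshold over the observed scores (a sample
#' is called positive when its score is at least the threshold) to build
#' the ROC curve, and computes the AUC by the Mann-Whitney rank formulation
#' with ties counted one half. The trapezoid area of the swept curve equals
#' the rank AUC; both are checked for internal consistency.
#'
#' @param scores numeric per-sample scores (pseudo-time).
#' @param labels logical indicator values; NA pairs are dropped.
#' @return Object of class `roc_result`: list with `points` (threshold,
#'   fpr, tpr), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both positive and negative labels are required")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  pts <- data.frame(threshold = s[last_of_tie],
                    fpr = fp[last_of_tie] / n_neg,
                    tpr = tp[last_of_tie] / n_pos)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  auc <- auc_rank(scores, labels)
  trap <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  if (abs(trap - auc) > 1e-9) {
    stop("internal ROC inconsistency: trapezoid and rank AUC disagree")
  }
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Shuffled-label null distribution for an AUC
#'
#' Permutes the indicator labels `n_shuffles` times, recomputing the AUC
#' each time. The empirical p-value uses the +1 correction,
#' `(1 + #\{null >= observed\}) / (n_shuffles + 1)`, so it is never zero.
#'
#' @inheritParams roc_auc
#' @param n_shuffles number of label permutations (default 100).
#' @param seed optional integer seed.
#' @return List with `observed_auc`, `null_aucs`, `empirical_p`.
#' @export
shuffled_null <- function(scores, labels, n_shuffles = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  obs <- roc_auc(scores, labels)$auc
  null_aucs <- vapply(seq_len(n_shuffles), function(i) {
    auc_rank(scores, sample(labels))
  }, numeric(1))
  list(observed_auc = obs,
       null_aucs = null_aucs,
       empirical_p = (1 + sum(null_aucs >= obs)) / (n_shuffles + 1))
}

#' Per-arm association tests between pseudo-time and BV indicators
#'
#' For each arm with at least `min_n` samples: Spearman correlation for
#' continuous variables (Shannon diversity, Nugent score, pH) and two-sided
#' Wilcoxon rank-sum tests for binary indicators, with Benjamini-Hochberg
#' FDR correction across the whole table. Arms below `min_n` are reported
#' with `excluded = TRUE` and no statistics.
#'
#' @param pseudotime named per-sample pseudo-time vector.
#' @param meta metadata data frame.
#' @param arms named per-sample arm label vector.
#' @param shannon optional named per-sample Shannon diversity vector.
#' @param min_n minimum per-arm sample count (default 30).
#' @param exact_max Wilcoxon switches from the exact to the normal
#'   approximation when either group exceeds this size (default 50).
#' @return Data frame: arm, variable, type, n, estimate, p_value, fdr,
#'   excluded.
#' @export
pseudotime_indicator_tests <- function(pseudotime, meta, arms,
                                       shannon = NULL, min_n = 30,
                                       exact_max = 50) {
  ids <- names(pseudotime)
  stopifnot(!is.null(ids), !is.null(names(arms)))
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  arm <- arms[ids]
  cont <- list()
  if (!is.null(shannon)) cont$shannon <- shannon[ids]
  if ("nugent" %in% names(m)) cont$nugent <- m$nugent
  if ("ph" %in% names(m)) cont$ph <- m$ph
  bin_cols <- intersect(c("amsel_positive", "whiff", "clue_cells",
                          "abnormal_fluid"), names(m))
  rows <- list()
  for (a in sort(unique(arm[!is.na(arm)]))) {
    in_arm <- !is.na(arm) & arm == a
    if (sum(in_arm) < min_n) {
      rows[[length(rows) + 1]] <- data.frame(
        arm = a, variable = NA_character_, type = NA_character_,
        n = sum(in_arm), estimate = NA_real_, p_value = NA_real_,
        excluded = TRUE, stringsAsFactors = FALSE)
      next
    }
    pt <- pseudotime[in_arm]
    for (v in names(cont)) {
      x <- cont[[v]][in_arm]
      ok <- !is.na(x)
      est <- p <- NA_real_
      if (sum(ok) >= 3 && stats::sd(pt[ok]) > 0 && stats::sd(x[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(pt[ok], x[ok], method = "spearman", exact = FALSE))
        est <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        arm = a, variable = v, type = "spearman", n = sum(ok),
        estimate = est, p_value = p, excluded = FALSE,
        stringsAsFactors = FALSE)
    }
    for (v in bin_cols) {
      x <- as.logical(m[[v]])[in_arm]
      ok <- !is.na(x)
      est <- p <- NA_real_
      if (sum(x[ok]) > 0 && sum(!x[ok]) > 0) {
        exact <- sum(x[ok]) <= exact_max && sum(!x[ok]) <= exact_max
        wt <- suppressWarnings(
          stats::wilcox.test(pt[ok][x[ok]], pt[ok][!x[ok]],
                             exact = exact))
        est <- mean(pt[ok][x[ok]]) - mean(pt[ok][!x[ok]])
        p <- wt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        arm = a, variable = v, type = "wilcoxon", n = sum(ok),
        estimate = est, p_value = p, excluded = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- !is.na(out$p_value)
  out$fdr[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out
}

#' Biogenic-amine contrasts between high and low pseudo-time
#'
#' Samples are split at pseudo-time > `threshold` (default 0.9) and each
#' amine is compared between the two groups with a two-sided Wilcoxon
#' rank-sum test, BH-corrected across amines. Amines with an empty group
#' are skipped with a warning.
#'
#' @param pseudotime named per-sample pseudo-time vector.
#' @param amines data frame with `sample_id` and one column per amine.
#' @param threshold high-group cut (strict >).
#' @return Data frame: amine, n_high, n_low, median_high, median_low,
#'   p_value, fdr.
#' @export
amine_contrast <- function(pseudotime, amines, threshold = 0.9) {
  stopifnot(is.data.frame(amines), "sample_id" %in% names(amines))
  ids <- intersect(names(pseudotime), amines$sample_id)
  if (length(ids) == 0) stop("no overlap between pseudotime and amine samples")
  pt <- pseudotime[ids]
  am <- amines[match(ids, amines$sample_id), setdiff(names(amines), "sample_id"),
               drop = FALSE]
  high <- pt > threshold
  rows <- lapply(names(am), function(a) {
    x <- am[[a]]
    ok <- !is.na(x)
    hi <- x[ok & high]
    lo <- x[ok & !high]
    if (length(hi) == 0 || length(lo) == 0) {
      warning("amine '", a, "' skipped: empty pseudo-time group")
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(hi, lo, exact =
      length(hi) <= 50 && length(lo) <= 50))
    data.frame(amine = a, n_high = length(hi), n_low = length(lo),
               median_high = stats::median(hi), median_low = stats::median(lo),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no amine could be tested")
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Sliding-window taxa profiles along pseudo-time
#'
#' Within each profiled arm, taxa abundances are averaged in windows of
#' width `window` (default 0.2 pseudo-time units) advanced in steps of
#' `step` (default 0.01): starts 0.00, 0.01, ..., 0.80, i.e. 81 windows
#' over \[0, 1\]. Windows are half-open `[start, start + window)`; the last
#' window is closed on the right so that a sample at pseudo-time 1 is
#' counted. Empty windows yield `NA` means with a count of 0.
#'
#' @param x a `composition_table` with relative abundances.
#' @param pseudotime named per-sample pseudo-time vector.
#' @param arms named per-sample arm labels.
#' @param arms_to_profile arms to profile (default the healthy arms).
#' @param window window width in pseudo-time units.
#' @param step sliding increment.
#' @return Long data frame: arm, window_start, taxon, mean_abundance,
#'   n_samples.
#' @export
arm_abundance_profiles <- function(x, pseudotime, arms,
                                   arms_to_profile = healthy_arms(),
                                   window = 0.2, step = 0.01) {
  stopifnot(inherits(x, "composition_table"))
  rel <- x$relabund
  if (is.null(rel)) stop("relative abundances required")
  ids <- rownames(rel)
  pt <- pseudotime[ids]
  arm <- arms[ids]
  starts <- seq(0, 1 - window, by = step)
  out <- list()
  for (a in arms_to_profile) {
    in_arm <- which(!is.na(arm) & arm == a & !is.na(pt))
    if (length(in_arm) == 0) next
    pa <- pt[in_arm]
    ra <- rel[in_arm, , drop = FALSE]
    for (s in starts) {
      hi <- s + window
      inw <- if (abs(hi - 1) < 1e-12) {
        pa >= s & pa <= hi
      } else {
        pa >= s & pa < hi
      }
      n <- sum(inw)
      mu <- if (n > 0) colMeans(ra[inw, , drop = FALSE]) else
        rep(NA_real_, ncol(ra))
      out[[length(out) + 1]] <- data.frame(
        arm = a, window_start = s, taxon = colnames(ra),
        mean_abundance = unname(mu), n_samples = n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no profiled arm contains samples")
  do.call(rbind, out)
}
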