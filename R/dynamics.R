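#' Build per-subject trajectories
#'
#' Groups longitudinal samples by subject and orders them by study day,
#' attaching pseudo-time and arm labels. Pseudo-time itself is computed
#' without any knowledge of subject identity or chronology; this step only
#' arranges already-computed labels.
#'
#' @param meta metadata data frame with `sample_id`, `subject_id`, `day`
#'   (and optionally `menses_day`, `medication_day`).
#' @param pseudotime named per-sample pseudo-time vector.
#' @param arms optional named per-sample arm labels.
#' @return Data frame of class `bv_trajectories`, ordered by subject then
#'   day, with columns subject_id, day, sample_id, pseudotime, arm, and any
#'   menses/medication flags present.
#' @export
build_trajectories <- function(meta, pseudotime, arms = NULL) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "subject_id", "day") %in% names(meta)))
  m <- meta[!is.na(meta$subject_id) & !is.na(meta$day), , drop = FALSE]
  m <- m[m$sample_id %in% names(pseudotime), , drop = FALSE]
  if (nrow(m) == 0) stop("no longitudinal samples with pseudo-time labels")
  key <- paste(m$subject_id, m$day, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (subject, day) pairs: ",
         paste(utils::head(gsub("\r", " day ", dup), 5), collapse = "; "))
  }
  m <- m[order(m$subject_id, m$day), , drop = FALSE]
  out <- data.frame(subject_id = m$subject_id,
                    day = m$day,
                    sample_id = m$sample_id,
                    pseudotime = unname(pseudotime[m$sample_id]),
                    arm = if (!is.null(arms)) unname(arms[m$sample_id]) else
                      NA_character_,
                    stringsAsFactors = FALSE)
  if ("menses_day" %in% names(m)) out$menses_day <- m$menses_day
  if ("medication_day" %in% names(m)) out$medication_day <- m$medication_day
  class(out) <- c("bv_trajectories", "data.frame")
  out
}

# Maximal runs of consecutive calendar days for which `flag` is TRUE,
# within one subject's day vector. Returns a data frame of start/end days.
flag_intervals <- function(days, flag) {
  d <- days[flag]
  if (length(d) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  d <- sort(d)
  grp <- cumsum(c(TRUE, diff(d) > 1))
  pieces <- split(d, factor(grp, levels = unique(grp)))
  data.frame(start = vapply(pieces, min, numeric(1)),
             end = vapply(pieces, max, numeric(1)),
             row.names = NULL)
}

#' Per-sample pseudo-time differences within subjects
#'
#' For every sample after a subject's first, the delta is the pseudo-time
#' at that sample minus at the subject's previous sample (a single
#' difference even across sampling gaps). Each delta is flagged as falling
#' inside a menses window when the sample's own day lies within
#' `[menses_start - lead_days, menses_end]` of any menstruation interval.
#'
#' @param traj a `bv_trajectories` data frame.
#' @param lead_days days before menses onset included in the window
#'   (default 2).
#' @return Data frame: subject_id, day, delta_pt, in_menses_window.
#' @export
pseudotime_deltas <- function(traj, lead_days = 2) {
  stopifnot(inherits(traj, "bv_trajectories"))
  has_menses <- "menses_day" %in% names(traj)
  rows <- lapply(split(seq_len(nrow(traj)), traj$subject_id), function(idx) {
    tt <- traj[idx, , drop = FALSE]
    if (nrow(tt) < 2) return(NULL)
    inw <- rep(NA, nrow(tt))
    if (has_menses) {
      flag <- menses_flag(tt$menses_day)
      iv <- flag_intervals(tt$day, flag)
      inw <- vapply(tt$day, function(d) {
        any(d >= iv$start - lead_days & d <= iv$end)
      }, logical(1))
    }
    data.frame(subject_id = tt$subject_id[-1],
               day = tt$day[-1],
               delta_pt = diff(tt$pseudotime),
               in_menses_window = inw[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no subject has two or more samples")
  }
  rownames(out) <- NULL
  out
}

# Interpret a menses column: logical as-is; character treats anything
# other than "none"/""/NA as a menses day.
menses_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & !(x %in% c("none", ""))
}

#' Menstrual-window fluctuation test
#'
#' Compares per-sample pseudo-time differences between (1) samples whose
#' day falls in the window from `lead_days` before a menstruation interval
#' to its end and (2) all other samples, using a one-sided Wilcoxon
#' rank-sum test of larger deltas in the window (a two-sided p is also
#' reported).
#'
#' @inheritParams pseudotime_deltas
#' @return List with `p_one_sided`, `p_two_sided`, group sizes, group mean
#'   deltas, and the `deltas` data frame.
#' @export
menses_fluctuation_test <- function(traj, lead_days = 2) {
  if (!"menses_day" %in% names(traj)) {
    stop("trajectories carry no menses information")
  }
  dl <- pseudotime_deltas(traj, lead_days = lead_days)
  if (all(is.na(dl$in_menses_window)) || !any(dl$in_menses_window, na.rm = TRUE)) {
    stop("no samples fall inside a menses window")
  }
  din <- dl$delta_pt[dl$in_menses_window]
  dout <- dl$delta_pt[!dl$in_menses_window]
  if (length(dout) == 0) stop("no samples outside the menses window")
  w1 <- suppressWarnings(
    stats::wilcox.test(din, dout, alternative = "greater", exact = FALSE))
  w2 <- suppressWarnings(
    stats::wilcox.test(din, dout, alternative = "two.sided", exact = FALSE))
  list(p_one_sided = w1$p.value,
       p_two_sided = w2$p.value,
       n_in = length(din), n_out = length(dout),
       mean_delta_in = mean(din), mean_delta_out = mean(dout),
       deltas = dl)
}

#' Pseudo-time response to BV medication episodes
#'
#' Episodes are maximal runs of consecutive medication-flagged days within
#' a subject. The analysis window spans one day before the first flagged
#' day to one day after the last. For each episode with at least two
#' in-window samples, reports the net pseudo-time change (window end minus
#' window start), the fraction of consecutive steps that decrease, the
#' "consistent decrease" call (net change < 0) and the stricter
#' all-steps-decreasing call.
#'
#' @param traj a `bv_trajectories` data frame with a `medication_day`
#'   column.
#' @return Data frame: subject_id, start_day, end_day, n_samples,
#'   net_change, frac_steps_decreasing, consistent_decrease,
#'   strict_decrease, evaluable.
#' @export
medication_response <- function(traj) {
  if (!"medication_day" %in% names(traj)) {
    stop("trajectories carry no medication information")
  }
  rows <- lapply(split(seq_len(nrow(traj)), traj$subject_id), function(idx) {
    tt <- traj[idx, , drop = FALSE]
    iv <- flag_intervals(tt$day, isTRUE_vec(tt$medication_day))
    if (nrow(iv) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(iv)), function(e) {
      w0 <- iv$start[e] - 1
      w1 <- iv$end[e] + 1
      inw <- tt$day >= w0 & tt$day <= w1
      pt <- tt$pseudotime[inw]
      if (length(pt) < 2) {
        return(data.frame(subject_id = tt$subject_id[1],
                          start_day = iv$start[e], end_day = iv$end[e],
                          n_samples = length(pt), net_change = NA_real_,
                          frac_steps_decreasing = NA_real_,
                          consistent_decrease = NA,
                          strict_decrease = NA, evaluable = FALSE,
                          stringsAsFactors = FALSE))
      }
      steps <- diff(pt)
      data.frame(subject_id = tt$subject_id[1],
                 start_day = iv$start[e], end_day = iv$end[e],
                 n_samples = length(pt),
                 net_change = pt[length(pt)] - pt[1],
                 frac_steps_decreasing = mean(steps < 0),
                 consistent_decrease = (pt[length(pt)] - pt[1]) < 0,
                 strict_decrease = all(steps < 0),
                 evaluable = TRUE,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no medication episodes found")
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
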