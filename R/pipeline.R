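#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: depth/rare-taxon filtering, CST
#' assignment, manifold fitting with pseudo-time, optional held-out
#' projection, cross-sectional evaluation (ROC per available indicator,
#' per-arm statistics, amine contrasts, sliding-window profiles) and
#' longitudinal dynamics. Every stage's outputs are written as TSV under
#' `outdir`, together with a `manifest.json` recording the seed,
#' configuration and per-stage row counts. Inputs are never mutated.
#'
#' @param composition a `composition_table` or path to a composition TSV.
#' @param metadata a metadata data frame or path to a metadata TSV.
#' @param centroids a `centroid_set` or path to a centroid CSV.
#' @param outdir output directory.
#' @param seed integer seed controlling the held-out split (and any other
#'   stochastic stage).
#' @param holdout_fraction fraction of samples held out of the manifold fit
#'   and projected back (0 disables projection).
#' @param manifold a `manifold_config`.
#' @param min_arm_n minimum per-arm size for the indicator tests.
#' @param evaluate,dynamics stage toggles.
#' @return Invisibly, a list with the fitted model, stage outputs and the
#'   manifest.
#' @export
run_all <- function(composition, metadata, centroids, outdir,
                    seed = 1L, holdout_fraction = 0,
                    manifold = manifold_config(),
                    min_arm_n = 30, evaluate = TRUE, dynamics = TRUE) {
  if (is.character(composition)) composition <- read_composition(composition)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(centroids)) centroids <- read_centroids(centroids)
  stopifnot(inherits(composition, "composition_table"),
            is.data.frame(metadata),
            inherits(centroids, "centroid_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "bvmanifold",
                   version = as.character(utils::packageVersion("bvmanifold")),
                   seed = seed, holdout_fraction = holdout_fraction,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] ", paste(names(list(...)), unlist(list(...)),
                                    sep = "=", collapse = " "))
  }

  # Stage 1: filtering
  tab <- composition
  dropped_samples <- character(0)
  dropped_taxa <- character(0)
  if (!is.null(tab$counts)) {
    tab <- filter_by_depth(tab)
    dropped_samples <- attr(tab, "dropped_samples")
    dropped_taxa <- attr(tab, "dropped_taxa")
    tab <- to_relative(tab)
  }
  if (is.null(tab$relabund)) stop("[filter] table has neither counts nor relabund")
  tab <- filter_rare_taxa(tab)
  dropped_taxa <- c(dropped_taxa, attr(tab, "dropped_taxa"))
  write_composition(tab, file.path(outdir, "filtered_composition.tsv"))
  if (length(c(dropped_samples, dropped_taxa)) > 0) {
    utils::write.table(
      data.frame(identifier = c(dropped_samples, dropped_taxa),
                 kind = c(rep("sample", length(dropped_samples)),
                          rep("taxon", length(dropped_taxa)))),
      file.path(outdir, "dropped.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  meta <- metadata[metadata$sample_id %in% sample_ids(tab), , drop = FALSE]
  note("filter", n_samples = nrow(tab$relabund), n_taxa = ncol(tab$relabund),
       dropped_samples = length(dropped_samples),
       dropped_taxa = length(dropped_taxa))

  # Stage 2: CST assignment
  assignments <- assign_cst(tab, centroids)
  utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("assign_cst", n_assigned = nrow(assignments),
       n_subcst = length(unique(assignments$subcst)))

  # Stage 3: manifold fit (on the training split)
  ids <- sample_ids(tab)
  set.seed(seed)
  held <- character(0)
  if (holdout_fraction > 0) {
    held <- sort(sample(ids, round(holdout_fraction * length(ids))))
  }
  train_ids <- setdiff(ids, held)
  keep <- rownames(tab$relabund) %in% train_ids
  train_tab <- structure(
    list(counts = if (!is.null(tab$counts))
           tab$counts[keep, , drop = FALSE] else NULL,
         relabund = tab$relabund[keep, , drop = FALSE]),
    class = "composition_table")
  model <- fit_manifold(train_tab, meta, manifold,
                        assignments = assignments[
                          assignments$sample_id %in% train_ids, ])
  write_manifold(model, file.path(outdir, "model"))
  note("fit", n_train = length(train_ids), n_roots = length(model$root_ids),
       n_bridges = nrow(model$bridges))

  # Stage 4: held-out projection
  projections <- NULL
  pt_all <- model$pseudotime
  arms_all <- stats::setNames(model$arms, model$sample_ids)
  if (length(held) > 0) {
    qtab <- structure(list(counts = NULL,
                           relabund = tab$relabund[held, , drop = FALSE]),
                      class = "composition_table")
    projections <- project_samples(qtab, model, train_tab)
    utils::write.table(projections, file.path(outdir, "projections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pt_all <- c(pt_all,
                stats::setNames(projections$pseudotime, projections$query_id))
    arms_all <- c(arms_all,
                  stats::setNames(projections$arm, projections$query_id))
    note("project", n_queries = nrow(projections))
  } else {
    note("project", n_queries = 0L)
  }

  # Stage 5: evaluation
  if (evaluate) {
    shannon <- shannon_index(tab$relabund)
    non_root <- setdiff(names(pt_all), model$root_ids)
    aucs <- list()
    for (ind in indicator_names()) {
      labels <- tryCatch(binarize_indicator(meta, ind), error = function(e) NULL)
      if (is.null(labels)) next
      lab <- labels[non_root]
      sc <- pt_all[non_root]
      ok <- !is.na(lab) & !is.na(sc)
      if (sum(lab[ok]) == 0 || sum(!lab[ok]) == 0) next
      roc <- roc_auc(sc[ok], lab[ok])
      nul <- shuffled_null(sc[ok], lab[ok], n_shuffles = 100,
                           seed = seed + 17L)
      utils::write.table(roc$points,
                         file.path(outdir, paste0("roc_", ind, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      aucs[[ind]] <- data.frame(indicator = ind, auc = roc$auc,
                                n_pos = roc$n_pos, n_neg = roc$n_neg,
                                null_auc_mean = mean(nul$null_aucs),
                                empirical_p = nul$empirical_p)
    }
    if (length(aucs) > 0) {
      utils::write.table(do.call(rbind, aucs),
                         file.path(outdir, "auc_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    arm_stats <- pseudotime_indicator_tests(
      pt_all, meta, arms_all, shannon = shannon, min_n = min_arm_n)
    utils::write.table(arm_stats, file.path(outdir, "arm_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    amine_cols <- intersect(c("cadaverine", "putrescine", "tyramine",
                              "spermidine", "spermine"), names(meta))
    if (length(amine_cols) > 0) {
      am <- meta[, c("sample_id", amine_cols), drop = FALSE]
      amine_stats <- tryCatch(amine_contrast(pt_all, am),
                              error = function(e) NULL)
      if (!is.null(amine_stats)) {
        utils::write.table(amine_stats, file.path(outdir, "amine_stats.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    profiles <- arm_abundance_profiles(tab, pt_all, arms_all)
    for (a in unique(profiles$arm)) {
      utils::write.table(profiles[profiles$arm == a, ],
                         file.path(outdir, paste0("profiles_", a, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("evaluate", n_indicators = length(aucs),
         n_arm_tests = sum(!is.na(arm_stats$p_value)),
         n_profiled_arms = length(unique(profiles$arm)))
  } else {
    note("evaluate", skipped = TRUE)
  }

  # Stage 6: longitudinal dynamics
  if (dynamics && all(c("subject_id", "day") %in% names(meta)) &&
      any(!is.na(meta$subject_id))) {
    traj <- build_trajectories(meta, pt_all, arms_all)
    utils::write.table(traj, file.path(outdir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_tests <- 0L
    if ("menses_day" %in% names(traj)) {
      mt <- tryCatch(menses_fluctuation_test(traj), error = function(e) NULL)
      if (!is.null(mt)) {
        utils::write.table(mt$deltas, file.path(outdir, "deltas.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(p_one_sided = mt$p_one_sided,
                     p_two_sided = mt$p_two_sided,
                     n_in = mt$n_in, n_out = mt$n_out,
                     mean_delta_in = mt$mean_delta_in,
                     mean_delta_out = mt$mean_delta_out),
          file.path(outdir, "menses_test.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        n_tests <- n_tests + 1L
      }
    }
    episodes <- NULL
    if ("medication_day" %in% names(traj)) {
      episodes <- tryCatch(medication_response(traj), error = function(e) NULL)
      if (!is.null(episodes)) {
        utils::write.table(episodes,
                           file.path(outdir, "medication_episodes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    note("dynamics", n_subjects = length(unique(traj$subject_id)),
         n_episodes = if (is.null(episodes)) 0L else nrow(episodes),
         menses_tested = n_tests > 0)
  } else {
    note("dynamics", skipped = TRUE)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, manifest = manifest,
                 projections = projections, outdir = outdir))
}

#' Build a small runnable demo fixture
#'
#' Generates a compact synthetic cohort (about 400 cross-sectional samples
#' plus 10 subjects followed for 40 days), fits subCST centroids on a
#' separate labeled training cohort from the same generator, and writes
#' everything [run_all()] needs into a directory.
#'
#' @param dir fixture directory.
#' @param seed master seed.
#' @return Invisibly, a list with the paths written.
#' @export
make_demo <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_x <- synthetic_config(n_samples = 400L, seed = seed)
  cfg_l <- synthetic_config(n_subjects_longitudinal = 10L,
                            days_per_subject = 40L, seed = seed + 1L)
  cross <- generate_cross_sectional(cfg_x)
  long <- generate_longitudinal(cfg_l)

  rel <- rbind(cross$table$relabund, long$table$relabund)
  tab <- composition_table(relabund = rel)
  meta_x <- cross$metadata
  meta_x$subject_id <- NA_character_
  meta_x$day <- NA_integer_
  meta_x$menses_day <- "none"
  meta_x$medication_day <- FALSE
  common <- union(names(meta_x), names(long$metadata))
  meta <- rbind(meta_x[, intersect(common, names(meta_x))],
                long$metadata[, intersect(common, names(meta_x))])
  truth <- merge(cross$truth, long$truth, all = TRUE, sort = FALSE)

  cfg_train <- synthetic_config(n_samples = 300L, seed = seed + 2L)
  train <- generate_cross_sectional(cfg_train)
  cen <- fit_centroids(train$table, train$truth$true_subcst)

  write_composition(tab, file.path(dir, "composition.tsv"))
  write_metadata(meta, file.path(dir, "metadata.tsv"))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_centroids(cen, file.path(dir, "centroids.csv"))
  jsonlite::write_json(list(seed = seed, n_cross = nrow(cross$truth),
                            n_longitudinal = nrow(long$truth)),
                       file.path(dir, "demo.json"), auto_unbox = TRUE)
  invisible(list(composition = file.path(dir, "composition.tsv"),
                 metadata = file.path(dir, "metadata.tsv"),
                 truth = file.path(dir, "truth.tsv"),
                 centroids = file.path(dir, "centroids.csv")))
}
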