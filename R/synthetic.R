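#' Configuration for the synthetic cohort generator
#'
#' The generator emulates CST-structured vaginal compositions with a latent
#' BV-progression parameter `b` in \[0, 1\] (0 = healthiest, 1 = BV). Each
#' sample draws a healthy source arm and a `b`; its expected profile is the
#' mixture `(1 - b) * arm_centroid + b * bv_profile`, where the BV profile
#' is a high-entropy mixture over anaerobe taxa shared by all arms, and the
#' realized composition is a Dirichlet draw around that profile. Clinical
#' metadata (Nugent, pH, Amsel criteria, amines) are generated conditionally
#' on `b`. Longitudinal subjects follow stable, cyclic (menses-linked) or
#' erratic trajectory archetypes.
#'
#' @param n_samples cross-sectional cohort size.
#' @param n_taxa number of taxa (>= 20): 4 Lactobacillus species, a
#'   G. vaginalis-like anaerobe, and the remainder split ~65/35 between
#'   further anaerobes and low-abundance commensals.
#' @param arms named list of healthy-arm specs; each has `dominant` (taxon),
#'   `prior` (arm probability) and `subcst` (named mixing prior over
#'   subCST labels). Defaults cover arms I, II, III, V.
#' @param dirichlet_concentration total concentration of the Dirichlet
#'   composition noise (larger = tighter around the expected profile).
#' @param latent_b_shape1,latent_b_shape2 Beta parameters of the
#'   cross-sectional `b` distribution (default Beta(1.2, 1.8), a
#'   healthy-skewed cohort).
#' @param indicator_link per-criterion logistic links on `b`: a list of
#'   `c(slope, midpoint)` for `whiff`, `clue_cells`, `abnormal_fluid`,
#'   `elevated_ph_criterion`.
#' @param sequencing_depth_mean when set, read counts are drawn per sample
#'   (negative binomial depth, multinomial composition) and relative
#'   abundances derive from the counts; when `NULL` (default) the Dirichlet
#'   composition is emitted directly.
#' @param n_subjects_longitudinal,days_per_subject longitudinal cohort
#'   shape (default 20 subjects x 70 daily samples).
#' @param archetype_weights probabilities of the stable / cyclic / erratic
#'   trajectory archetypes.
#' @param menses_period_days,menses_duration_days menstrual cycle shape.
#' @param medication_episode_rate per-day probability that a BV medication
#'   episode starts.
#' @param medication_duration_days length of a medication episode.
#' @param cyclic_bump added to `b` inside the menses window for cyclic
#'   subjects.
#' @param stable_noise_sd,erratic_noise_sd,erratic_jump_prob trajectory
#'   noise scales.
#' @param seed master seed; one sub-stream is derived per logical component
#'   (latents/trajectories, compositions, metadata).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 1200L,
                             n_taxa = 100L,
                             arms = default_arm_specs(),
                             dirichlet_concentration = 300,
                             latent_b_shape1 = 1.2,
                             latent_b_shape2 = 1.8,
                             indicator_link = default_indicator_links(),
                             sequencing_depth_mean = NULL,
                             n_subjects_longitudinal = 20L,
                             days_per_subject = 70L,
                             archetype_weights = c(stable = 0.5,
                                                   cyclic = 0.3,
                                                   erratic = 0.2),
                             menses_period_days = 28L,
                             menses_duration_days = 5L,
                             medication_episode_rate = 0.008,
                             medication_duration_days = 5L,
                             cyclic_bump = 0.35,
                             stable_noise_sd = 0.03,
                             erratic_noise_sd = 0.08,
                             erratic_jump_prob = 0.07,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (n_taxa < 20) stop("n_taxa must be >= 20")
  if (length(arms) == 0) stop("at least one arm is required")
  priors <- vapply(arms, `[[`, numeric(1), "prior")
  if (abs(sum(priors) - 1) > 1e-9) stop("arm priors must sum to 1")
  for (a in arms) {
    if (abs(sum(a$subcst) - 1) > 1e-9) stop("subCST priors must sum to 1")
  }
  if (abs(sum(archetype_weights) - 1) > 1e-9) {
    stop("archetype weights must sum to 1")
  }
  if (any(archetype_weights < 0) || any(priors < 0)) {
    stop("probabilities must be non-negative")
  }
  if (dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

#' Default healthy-arm specifications
#'
#' Arm I (L. crispatus) and III (L. iners) carry A/B subCST structure; II
#' (L. gasseri) and V (L. jensenii) are single groups. Priors reflect the
#' approximate prevalence of the Lactobacillus CSTs in reproductive-age
#' cohorts.
#' @return Named list of arm specs.
#' @export
default_arm_specs <- function() {
  list(
    I = list(dominant = "Lactobacillus_crispatus", prior = 0.45,
             subcst = c("I-A" = 0.7, "I-B" = 0.3)),
    II = list(dominant = "Lactobacillus_gasseri", prior = 0.15,
              subcst = c("II" = 1)),
    III = list(dominant = "Lactobacillus_iners", prior = 0.30,
               subcst = c("III-A" = 0.6, "III-B" = 0.4)),
    V = list(dominant = "Lactobacillus_jensenii", prior = 0.10,
             subcst = c("V" = 1))
  )
}

#' Default logistic links from latent b to the four Amsel criteria
#' @return Named list of `c(slope, midpoint)` pairs.
#' @export
default_indicator_links <- function() {
  list(whiff = c(slope = 10, midpoint = 0.70),
       clue_cells = c(slope = 10, midpoint = 0.65),
       abnormal_fluid = c(slope = 8, midpoint = 0.80),
       elevated_ph_criterion = c(slope = 10, midpoint = 0.70))
}

# Dominance of the focal Lactobacillus per subCST group: A-type subCSTs are
# strongly dominated, B-types less so; single-group arms sit in between.
subcst_dominance <- function(subcst) {
  switch(subcst,
         "I-A" = 0.90, "III-A" = 0.90,
         "I-B" = 0.65, "III-B" = 0.65,
         "II" = 0.85, "V" = 0.85,
         0.85)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

# Taxon panel: 4 Lactobacillus + G. vaginalis analogue + anaerobes +
# low-abundance commensals (~65/35 split of the remainder).
make_taxa <- function(n_taxa) {
  lacto <- c("Lactobacillus_crispatus", "Lactobacillus_gasseri",
             "Lactobacillus_iners", "Lactobacillus_jensenii")
  gvag <- "Gardnerella_vaginalis"
  rest <- n_taxa - 5L
  n_an <- round(rest * 0.65)
  n_co <- rest - n_an
  anaerobes <- sprintf("Anaerobe_%03d", seq_len(n_an))
  commensals <- sprintf("Commensal_%03d", seq_len(n_co))
  list(taxa = c(lacto, gvag, anaerobes, commensals),
       lacto = lacto,
       gvag = gvag,
       anaerobes = c(gvag, anaerobes),
       commensals = commensals)
}

#' Generative profiles of a synthetic cohort
#'
#' Returns, for a given configuration and its composition stream, the
#' deterministic subCST centroids and the cohort's shared BV endpoint
#' profile (a near-uniform mixture over the anaerobe taxa with an elevated
#' G. vaginalis-like weight, drawn once per cohort).
#'
#' @param config a `synthetic_config`.
#' @return List with `taxa` (panel bookkeeping), `centroids` (subCST x
#'   taxa), and `bv_profile`.
#' @export
synthetic_profiles <- function(config) {
  streams <- derive_streams(config$seed)
  build_profiles(config, streams$compositions)
}

# Sub-seeds for the per-component pseudo-random streams, derived from the
# master seed so that each logical component draws independently.
derive_streams <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3)
  list(latents = s[1], compositions = s[2], metadata = s[3])
}

build_profiles <- function(config, comp_seed) {
  tx <- make_taxa(config$n_taxa)
  set.seed(comp_seed)
  w <- rdirichlet1(rep(6, length(tx$anaerobes)))
  names(w) <- tx$anaerobes
  w[tx$gvag] <- w[tx$gvag] * 6
  w <- w / sum(w)
  bv <- stats::setNames(numeric(length(tx$taxa)), tx$taxa)
  bv[tx$anaerobes] <- w

  subcsts <- unlist(lapply(names(config$arms), function(a) {
    names(config$arms[[a]]$subcst)
  }))
  cen <- matrix(0, length(subcsts), length(tx$taxa),
                dimnames = list(subcsts, tx$taxa))
  for (a in names(config$arms)) {
    dom <- config$arms[[a]]$dominant
    for (sc in names(config$arms[[a]]$subcst)) {
      d <- subcst_dominance(sc)
      v <- stats::setNames(numeric(length(tx$taxa)), tx$taxa)
      v[dom] <- d
      v[tx$commensals] <- 0.9 * (1 - d) / length(tx$commensals)
      v[tx$anaerobes] <- v[tx$anaerobes] + 0.1 * (1 - d) / length(tx$anaerobes)
      cen[sc, ] <- v
    }
  }
  list(taxa = tx, centroids = cen, bv_profile = bv,
       subcst_arm = stats::setNames(
         rep(names(config$arms),
             vapply(config$arms, function(a) length(a$subcst), integer(1))),
         subcsts))
}

expected_profile <- function(profiles, subcst, b) {
  (1 - b) * profiles$centroids[subcst, ] + b * profiles$bv_profile
}

# Truth arm: the healthy source arm until the expected profile's dominant
# taxon leaves the focal Lactobacillus, after which the sample is a BV
# (IV-B, G. vaginalis-like dominated) community.
true_arm_of <- function(profiles, subcst, b) {
  p <- expected_profile(profiles, subcst, b)
  dom <- names(p)[which.max(p)]
  if (dom %in% profiles$taxa$anaerobes) "IV-B" else
    profiles$subcst_arm[[subcst]]
}

draw_compositions <- function(profiles, subcsts, bs, config) {
  n <- length(bs)
  conc <- config$dirichlet_concentration
  rel <- t(vapply(seq_len(n), function(i) {
    rdirichlet1(conc * expected_profile(profiles, subcsts[i], bs[i]))
  }, numeric(length(profiles$taxa$taxa))))
  colnames(rel) <- profiles$taxa$taxa
  counts <- NULL
  if (!is.null(config$sequencing_depth_mean)) {
    depth <- stats::rnbinom(n, mu = config$sequencing_depth_mean, size = 10)
    depth <- pmax(depth, 1L)
    counts <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1, depth[i], rel[i, ])[, 1]
    }, numeric(ncol(rel))))
    colnames(counts) <- colnames(rel)
    rel <- counts / rowSums(counts)
  }
  list(relabund = rel, counts = counts)
}

draw_metadata <- function(bs, config, dataset_id) {
  n <- length(bs)
  nugent <- pmin(pmax(round(10 * bs) + sample(-1:1, n, replace = TRUE), 0), 10)
  ph <- 4.0 + 2.5 * bs + stats::rnorm(n, 0, 0.3)
  ph <- pmax(ph, 3.5)
  crit <- vapply(names(config$indicator_link), function(cr) {
    l <- config$indicator_link[[cr]]
    p <- stats::plogis(l[["slope"]] * (bs - l[["midpoint"]]))
    stats::runif(n) < p
  }, logical(n))
  if (n == 1) crit <- matrix(crit, nrow = 1,
                             dimnames = list(NULL, names(config$indicator_link)))
  amsel <- rowSums(crit) >= 3
  shifted <- c("cadaverine", "putrescine", "tyramine")
  flat <- c("spermidine", "spermine")
  mu0 <- c(cadaverine = 2.0, putrescine = 2.5, tyramine = 1.5,
           spermidine = 2.0, spermine = 2.0)
  amines <- vapply(c(shifted, flat), function(a) {
    shift <- if (a %in% shifted) 1.5 * (bs > 0.9) else 0
    exp(stats::rnorm(n, mu0[[a]] + shift, 0.5))
  }, numeric(n))
  if (n == 1) amines <- matrix(amines, nrow = 1,
                               dimnames = list(NULL, c(shifted, flat)))
  data.frame(nugent = nugent, ph = ph,
             whiff = crit[, "whiff"],
             clue_cells = crit[, "clue_cells"],
             abnormal_fluid = crit[, "abnormal_fluid"],
             elevated_ph_criterion = crit[, "elevated_ph_criterion"],
             amsel_positive = amsel,
             amines,
             dataset_id = dataset_id,
             stringsAsFactors = FALSE)
}

#' Generate a cross-sectional synthetic cohort
#'
#' @param config a `synthetic_config`.
#' @return List with `table` (a `composition_table`), `metadata` (data
#'   frame) and `truth` (data frame with `sample_id`, `latent_b`,
#'   `source_arm`, `true_subcst`, `true_arm`).
#' @export
generate_cross_sectional <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  streams <- derive_streams(config$seed)
  profiles <- build_profiles(config, streams$compositions)
  n <- config$n_samples

  set.seed(streams$latents)
  arm_names <- names(config$arms)
  priors <- vapply(config$arms, `[[`, numeric(1), "prior")
  src <- sample(arm_names, n, replace = TRUE, prob = priors)
  subcst <- vapply(src, function(a) {
    sc <- config$arms[[a]]$subcst
    sample(names(sc), 1, prob = sc)
  }, character(1))
  bs <- stats::rbeta(n, config$latent_b_shape1, config$latent_b_shape2)

  set.seed(streams$compositions + 1L)
  comp <- draw_compositions(profiles, subcst, bs, config)
  ids <- sprintf("S%05d", seq_len(n))
  rownames(comp$relabund) <- ids
  if (!is.null(comp$counts)) rownames(comp$counts) <- ids

  set.seed(streams$metadata)
  meta <- draw_metadata(bs, config, "synthetic_cross_sectional")
  meta <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), meta)

  truth <- data.frame(
    sample_id = ids,
    latent_b = bs,
    source_arm = unname(src),
    true_subcst = NA_character_,
    true_arm = NA_character_,
    stringsAsFactors = FALSE)
  ta <- vapply(seq_len(n), function(i) {
    true_arm_of(profiles, subcst[i], bs[i])
  }, character(1))
  truth$true_arm <- ta
  truth$true_subcst <- ifelse(ta == "IV-B", "IV-B", unname(subcst))

  tab <- if (is.null(comp$counts)) {
    composition_table(relabund = comp$relabund)
  } else {
    composition_table(counts = comp$counts, relabund = comp$relabund)
  }
  list(table = tab, metadata = meta, truth = truth)
}

# One subject's latent trajectory: per-day b, arm/subCST, menses and
# medication flags. Archetypes: stable (mean-reverting noise at low b),
# cyclic (b bump spanning [menses_start - 2, menses_end]), erratic (jump
# process between arms). Medication episodes force b to decay
# geometrically, giving a strictly decreasing b across the episode.
simulate_subject <- function(config, archetype, arm0, subcst0, menses) {
  nd <- config$days_per_subject
  in_window <- rep(FALSE, nd)
  for (i in seq_len(nrow(menses$intervals))) {
    lo <- menses$intervals$start[i] - 2
    hi <- menses$intervals$end[i]
    in_window[seq_len(nd) >= lo & seq_len(nd) <= hi] <- TRUE
  }
  arm <- character(nd)
  subcst <- character(nd)
  b <- numeric(nd)
  med <- rep(FALSE, nd)
  cur_arm <- arm0
  cur_sub <- subcst0
  base <- switch(archetype,
                 stable = stats::runif(1, 0.05, 0.40),
                 cyclic = stats::runif(1, 0.15, 0.35),
                 erratic = stats::runif(1, 0.05, 0.60))
  cur_b <- if (archetype == "cyclic") {
    min(base + config$cyclic_bump * in_window[1], 1)
  } else {
    base
  }
  med_left <- 0L
  for (t in seq_len(nd)) {
    if (med_left == 0L && stats::runif(1) < config$medication_episode_rate &&
        t + config$medication_duration_days - 1 <= nd) {
      med_left <- config$medication_duration_days
      cur_b <- 0.65 * max(cur_b, 0.1)
    } else if (med_left > 0L) {
      cur_b <- 0.65 * cur_b
    }
    if (med_left > 0L) {
      med[t] <- TRUE
      med_left <- med_left - 1L
    } else if (t > 1) {
      cur_b <- switch(archetype,
        stable = cur_b + 0.2 * (base - cur_b) +
          stats::rnorm(1, 0, config$stable_noise_sd),
        cyclic = {
          target <- min(base + config$cyclic_bump * in_window[t], 1)
          cur_b + 0.5 * (target - cur_b) +
            stats::rnorm(1, 0, config$stable_noise_sd)
        },
        erratic = {
          if (stats::runif(1) < config$erratic_jump_prob) {
            arm_names <- names(config$arms)
            priors <- vapply(config$arms, `[[`, numeric(1), "prior")
            cur_arm <- sample(arm_names, 1, prob = priors)
            sc <- config$arms[[cur_arm]]$subcst
            cur_sub <- sample(names(sc), 1, prob = sc)
            stats::runif(1, 0, 0.95)
          } else {
            cur_b + stats::rnorm(1, 0, config$erratic_noise_sd)
          }
        })
    }
    cur_b <- min(max(cur_b, 0), 1)
    b[t] <- cur_b
    arm[t] <- cur_arm
    subcst[t] <- cur_sub
  }
  list(b = b, arm = arm, subcst = subcst, medication = med,
       menses_day = menses$intensity, archetype = archetype)
}

make_menses_schedule <- function(config) {
  nd <- config$days_per_subject
  onset <- sample.int(config$menses_period_days, 1)
  starts <- if (onset > nd) numeric(0) else
    seq(onset, nd, by = config$menses_period_days)
  intensity <- rep("none", nd)
  iv <- data.frame(start = numeric(0), end = numeric(0))
  for (s in starts) {
    e <- min(s + config$menses_duration_days - 1, nd)
    days <- s:e
    intensity[days] <- sample(c("spotting", "medium", "heavy"),
                              length(days), replace = TRUE,
                              prob = c(0.3, 0.4, 0.3))
    iv <- rbind(iv, data.frame(start = s, end = e))
  }
  list(intervals = iv, intensity = intensity)
}

#' Generate a longitudinal synthetic cohort
#'
#' Per-subject daily trajectories of the latent `b` follow one of three
#' archetypes (stable, cyclic, erratic); menstruation days are flagged with
#' an intensity and cyclic subjects receive a `b` bump spanning two days
#' before each menses interval through its end; medication episodes force a
#' monotone decrease of `b` across the episode window. Compositions and
#' metadata derive from the per-day `b` exactly as in the cross-sectional
#' generator.
#'
#' @param config a `synthetic_config` (`days_per_subject` must be >= 2).
#' @return List with `table`, `metadata` (including `subject_id`, `day`,
#'   `menses_day`, `medication_day`) and `truth` (including `archetype`).
#' @export
generate_longitudinal <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$days_per_subject < 2) stop("days_per_subject must be >= 2")
  if (config$n_subjects_longitudinal < 1) stop("need at least one subject")
  streams <- derive_streams(config$seed)
  profiles <- build_profiles(config, streams$compositions)

  set.seed(streams$latents + 1L)
  ns <- config$n_subjects_longitudinal
  nd <- config$days_per_subject
  arm_names <- names(config$arms)
  priors <- vapply(config$arms, `[[`, numeric(1), "prior")
  subjects <- sprintf("W%03d", seq_len(ns))
  per_subject <- lapply(subjects, function(w) {
    archetype <- sample(names(config$archetype_weights), 1,
                        prob = config$archetype_weights)
    arm0 <- sample(arm_names, 1, prob = priors)
    sc <- config$arms[[arm0]]$subcst
    subcst0 <- sample(names(sc), 1, prob = sc)
    menses <- make_menses_schedule(config)
    simulate_subject(config, archetype, arm0, subcst0, menses)
  })
  names(per_subject) <- subjects

  subj_col <- rep(subjects, each = nd)
  day_col <- rep(seq_len(nd), ns)
  bs <- unlist(lapply(per_subject, `[[`, "b"), use.names = FALSE)
  subcst <- unlist(lapply(per_subject, `[[`, "subcst"), use.names = FALSE)
  src <- unlist(lapply(per_subject, `[[`, "arm"), use.names = FALSE)
  med <- unlist(lapply(per_subject, `[[`, "medication"), use.names = FALSE)
  mens <- unlist(lapply(per_subject, `[[`, "menses_day"), use.names = FALSE)
  arch <- rep(vapply(per_subject, `[[`, character(1), "archetype"), each = nd)
  ids <- sprintf("%s_d%03d", subj_col, day_col)

  set.seed(streams$compositions + 2L)
  comp <- draw_compositions(profiles, subcst, bs, config)
  rownames(comp$relabund) <- ids
  if (!is.null(comp$counts)) rownames(comp$counts) <- ids

  set.seed(streams$metadata + 1L)
  meta <- draw_metadata(bs, config, "synthetic_longitudinal")
  meta <- cbind(data.frame(sample_id = ids,
                           subject_id = subj_col,
                           day = day_col,
                           menses_day = mens,
                           medication_day = med,
                           stringsAsFactors = FALSE),
                meta)

  ta <- vapply(seq_along(bs), function(i) {
    true_arm_of(profiles, subcst[i], bs[i])
  }, character(1))
  truth <- data.frame(sample_id = ids,
                      subject_id = subj_col,
                      day = day_col,
                      latent_b = bs,
                      source_arm = src,
                      true_subcst = ifelse(ta == "IV-B", "IV-B", subcst),
                      true_arm = ta,
                      archetype = arch,
                      stringsAsFactors = FALSE)

  tab <- if (is.null(comp$counts)) {
    composition_table(relabund = comp$relabund)
  } else {
    composition_table(counts = comp$counts, relabund = comp$relabund)
  }
  list(table = tab, metadata = meta, truth = truth)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `composition.tsv`, `metadata.tsv`, `truth.tsv` and `config.json`.
#'
#' @param cohort list returned by [generate_cross_sectional()] or
#'   [generate_longitudinal()].
#' @param config the `synthetic_config` used.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_composition(cohort$table, file.path(dir, "composition.tsv"),
                    what = if (!is.null(cohort$table$counts)) "counts" else
                      "relabund")
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$arms <- lapply(cfg$arms, function(a) {
    list(dominant = a$dominant, prior = a$prior, subcst = as.list(a$subcst))
  })
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
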