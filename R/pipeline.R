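#' Default run configuration
#'
#' All stage parameters in one list, mirroring the assay's printed
#' constants: 10 Hz nominal recording, 100 px minimum blob area, 200 px
#' despike threshold, 0.5-s smoothing, 15 mm/s movement threshold, 60-s /
#' 5% rest windows, 30-min bins, 10 PCA components, Ward cut at k = 3.
#' Serialises losslessly to YAML via [write_config()] / [read_config()].
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    fps = 10, min_area_px = 100, jump_threshold_px = 200,
    smooth_window_s = 0.5, background_window_min = 60,
    intensity_threshold = 40, px_per_mm = 2,
    movement_threshold_mms = 15, rest_window_s = 60, rest_max_frac = 0.05,
    bin_min = 30, n_components = 10, ward_k = 3,
    day_start = "07:00", day_end = "19:00", ramp_min = 30,
    glm_cutoff = 1e-5, pgls_top_frac = 1e-4,
    n_perm = 199, n_sim = 199, seed = 1), class = "run_config")
}

#' @rdname default_config
#' @param config A `run_config` list.
#' @param file YAML path.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname default_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' Simulate a full behavioural cohort with known ground truth
#'
#' Generates the study-shaped synthetic dataset: a pure-birth phylogeny, a
#' diel-guild history simulated under a bridge-constrained symmetric Mk
#' process (so the discrete-model analyses see their own generating
#' process), per-species activity templates with individual-level
#' variation, and multi-day tracks for every individual, reduced on the
#' fly to binned speed profiles and rest summaries.
#'
#' @param n_species Number of species, default 60.
#' @param n_per_species Individuals per species, default 8.
#' @param days Recording days per individual, default 6.
#' @param fps Sampling rate of the cohort tracks (Hz), default 1.
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param schedule Light schedule, default 12:12 with 30-min ramps.
#' @param bridge_rate Rate scale of the guild-generating Mk process.
#' @param root_guild Root state of the guild history; the default
#'   (diurnal) yields the day-active-majority composition typical of fish
#'   radiations, which also keeps the leading PCA axis aligned with the
#'   day-night contrast.
#' @return List of class `cohort_sim`: `profiles` (list of
#'   [daily_profile()]), `tree`, `guild_truth`, `total_rest` (measured,
#'   h/day per species), `rest_target` (analytic generator target),
#'   `total_rest_ind`, `templates`, `schedule`, `fps`, `seed`.
#' @export
simulate_cohort <- function(n_species = 60, n_per_species = 8, days = 6,
                            fps = 1, seed = 1,
                            schedule = make_light_schedule(),
                            bridge_rate = 0.04, root_guild = "diurnal") {
  set.seed(as.integer(seed))
  sub <- sample.int(2^20, 6)
  tree <- simulate_tree(n_species, seed = sub[1], depth = 10)
  states <- c("diurnal", "nocturnal", "crepuscular", "cathemeral")
  pat <- mk_pattern_matrix(states, "bridge-SYM")
  Q <- mk_build_q(rep(bridge_rate, attr(pat, "n_free")), pat)
  disc <- simulate_discrete(tree, Q, root_state = root_guild,
                            seed = sub[2])
  guilds <- disc$tip_states

  set.seed(sub[3])
  ind_seeds <- matrix(sample.int(2^28, n_species * n_per_species),
                      n_species, n_per_species)
  rest_scale <- exp(rnorm(n_species, 0, 0.35))
  base_jit <- exp(rnorm(n_species, 0, 0.15))
  profiles <- vector("list", n_species)
  rest_meas <- rest_tgt <- numeric(n_species)
  rest_ind <- vector("list", n_species)
  templates <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    tpl <- diel_template(as.character(guilds[i]))
    tpl$base_speed <- tpl$base_speed * base_jit[i]
    tpl$rest_bout_rate <- tpl$rest_bout_rate * rest_scale[i]
    templates[[i]] <- tpl
    binned <- vector("list", n_per_species)
    tr_i <- numeric(n_per_species)
    for (j in seq_len(n_per_species)) {
      sim <- simulate_track(tpl, schedule, days = days, fps = fps,
                            seed = ind_seeds[i, j])
      cal <- calibrate(sim$track)
      sp <- speed_series(cal)
      binned[[j]] <- bin30(sp$time, sp$speed)
      rest <- rest_flags(movement_flags(sp), fps = fps)
      tr_i[j] <- total_rest(rest, sp$time, fps = fps)
    }
    profiles[[i]] <- daily_profile(binned, species = tree$tip.label[i])
    rest_meas[i] <- mean(tr_i)
    rest_ind[[i]] <- tr_i
    rest_tgt[i] <- rest_target_hours(tpl, schedule)
  }
  names(rest_meas) <- names(rest_tgt) <- tree$tip.label
  structure(list(profiles = profiles, tree = tree, guild_truth = guilds,
                 total_rest = rest_meas, rest_target = rest_tgt,
                 total_rest_ind = rest_ind, templates = templates,
                 schedule = schedule, fps = fps, days = days,
                 seed = seed), class = "cohort_sim")
}

# expected rest hours/day of the two-state bout process (per light phase,
# equilibrium occupancy d / (d + 1/rate))
rest_target_hours <- function(template, schedule) {
  d <- template$rest_bout_mean_duration
  hrs <- c(day = (schedule$day_length - 2 * schedule$ramp_s) / 3600,
           ramp = 2 * schedule$ramp_s / 3600,
           night = 24 - schedule$day_length / 3600)
  r <- template$rest_bout_rate[c("day", "ramp", "night")] / 3600
  sum(hrs[c("day", "ramp", "night")] * d / (d + 1 / r))
}

#' Run the analysis chain on a simulated (or assembled) cohort
#'
#' Stages: diel classification (z-score, PCA, Ward + cathemeral rule),
#' phylogenetic comparative analyses of the PC loadings and total rest
#' (signal statistics, continuous model comparison, quadratic bridge fit,
#' discrete Mk model comparison), and optionally the allele-frequency GWAS
#' against a [simulate_genotype_likelihoods()] object.
#'
#' @param cohort A `cohort_sim` (or compatible list with `profiles`,
#'   `tree`, `total_rest`, `schedule`).
#' @param gwas Optional `gl_sim` object for the association stage.
#' @param config A [default_config()] list.
#' @param stages Character subset of `c("niche", "phylo", "gwas")`.
#' @return List of class `pipeline_run` with per-stage results and the
#'   resolved `config` and `seed`.
#' @export
run_pipeline <- function(cohort, gwas = NULL, config = default_config(),
                         stages = c("niche", "phylo", "gwas")) {
  res <- list(config = config, seed = config$seed)
  if ("niche" %in% stages) {
    cls <- classify_diel(cohort$profiles, schedule = cohort$schedule,
                         n_components = config$n_components)
    res$classification <- cls
  }
  if ("phylo" %in% stages) {
    if (is.null(res$classification))
      stop("phylo stage needs the niche stage output")
    tab <- res$classification$table
    pc1 <- setNames(tab$pc1, tab$species)
    pc2 <- setNames(tab$pc2, tab$species)
    tree <- cohort$tree
    z <- zscore_profiles(cohort$profiles)
    res$signal <- list(
      lambda_pc1 = pagel_lambda(tree, pc1),
      lambda_pc2 = pagel_lambda(tree, pc2),
      lambda_rest = pagel_lambda(tree, cohort$total_rest),
      k_pc1 = blomberg_k(tree, pc1, n_perm = config$n_perm,
                         seed = config$seed),
      k_pc2 = blomberg_k(tree, pc2, n_perm = config$n_perm,
                         seed = config$seed + 1),
      k_rest = blomberg_k(tree, cohort$total_rest, n_perm = config$n_perm,
                          seed = config$seed + 2),
      k_multi = blomberg_k(tree, t(z), n_perm = config$n_perm,
                           seed = config$seed + 3))
    fits1 <- lapply(setNames(c("BM", "OU", "EB"), c("BM", "OU", "EB")),
                    function(m) fit_continuous(tree, pc1, m,
                                               seed = config$seed))
    fits2 <- lapply(setNames(c("BM", "OU", "EB"), c("BM", "OU", "EB")),
                    function(m) fit_continuous(tree, pc2, m,
                                               seed = config$seed))
    res$continuous <- list(pc1 = compare_aic(fits1),
                           pc2 = compare_aic(fits2),
                           fits_pc1 = fits1, fits_pc2 = fits2)
    res$bridge <- quadratic_bridge_fit(pc1, pc2, tree)
    pats <- c("ER", "SYM", "ARD", "bridge-SYM", "bridge-ARD")
    guild <- setNames(as.character(tab$guild), tab$species)
    mk <- lapply(setNames(pats, pats), function(p)
      fit_mk(tree, guild, pattern = p,
             states = c("diurnal", "nocturnal", "crepuscular",
                        "cathemeral"),
             seed = config$seed))
    res$mk <- list(table = compare_aic(mk), fits = mk)
  }
  if ("gwas" %in% stages && !is.null(gwas)) {
    keep <- site_selection(gwas$sites, gwas$pl)
    af <- af_posterior_table(gwas$pl[keep, , , drop = FALSE],
                             gwas$ind_species)
    scan <- gwas_scan(gwas$trait, af, gwas$tree)
    hav <- call_havs(data.frame(glm_p = scan$glm_p,
                                pgls_p = scan$pgls_p),
                     glm_cutoff = config$glm_cutoff,
                     pgls_top_frac = config$pgls_top_frac)
    res$gwas <- list(keep = keep, af = af, scan = scan, hav = hav,
                     kept_idx = which(keep))
  }
  class(res) <- "pipeline_run"
  res
}

#' Summarise a pipeline run
#'
#' @param run A [run_pipeline()] result.
#' @param cohort The `cohort_sim` it was run on (for ground-truth recovery
#'   metrics); omit for runs without ground truth.
#' @param gwas The `gl_sim` used, if any.
#' @return List: `guild_counts`, `confusion` (when truth available),
#'   `guild_accuracy`, `continuous_aic`, `mk_aic`, `hav_count`,
#'   `hav_recall`/`hav_precision` (when planted sites known).
#' @export
report_run <- function(run, cohort = NULL, gwas = NULL) {
  out <- list()
  if (!is.null(run$classification)) {
    tab <- run$classification$table
    out$guild_counts <- table(tab$guild)
    if (!is.null(cohort)) {
      truth <- factor(as.character(cohort$guild_truth),
                      levels = levels(tab$guild))
      out$confusion <- table(truth = truth, called = tab$guild)
      out$guild_accuracy <- mean(as.character(truth) ==
                                   as.character(tab$guild))
    }
  }
  if (!is.null(run$continuous))
    out$continuous_aic <- list(pc1 = run$continuous$pc1,
                               pc2 = run$continuous$pc2)
  if (!is.null(run$mk)) out$mk_aic <- run$mk$table
  if (!is.null(run$gwas)) {
    out$hav_count <- sum(run$gwas$hav)
    if (!is.null(gwas) && length(gwas$assoc)) {
      called <- run$gwas$kept_idx[run$gwas$hav]
      out$hav_recall <- mean(gwas$assoc %in% called)
      out$hav_precision <- if (length(called))
        mean(called %in% gwas$assoc) else NA_real_
    }
  }
  out
}

#' Write a small cohort fixture to disk
#'
#' Serialises a complete fixture (per-individual track CSVs with YAML
#' metadata, Newick tree, trait table, VCF, ground-truth tables) for
#' file-based runs. Intended for small cohorts; the in-memory pipeline is
#' preferred at study scale.
#'
#' @param dir Output directory.
#' @param cohort A `cohort_sim` built with `keep_tracks = TRUE` semantics —
#'   tracks are regenerated here from the stored seeds, so any cohort works.
#' @param gwas Optional `gl_sim` to include as VCF + truth tables.
#' @param force Overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, cohort, gwas = NULL, force = FALSE) {
  if (dir.exists(dir) && !force) stop("directory exists; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree(cohort$tree, file.path(dir, "tree.nwk"))
  prof <- do.call(rbind, lapply(cohort$profiles, function(p) p$profile))
  rownames(prof) <- vapply(cohort$profiles, function(p) p$species,
                           character(1))
  write.csv(prof, file.path(dir, "species_profiles.csv"))
  traits <- data.frame(species = names(cohort$total_rest),
                       total_rest_h = as.numeric(cohort$total_rest),
                       guild_truth = as.character(cohort$guild_truth))
  write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = cohort$seed, fps = cohort$fps,
                        days = cohort$days,
                        n_species = length(cohort$profiles)),
                   file.path(dir, "metadata.yaml"))
  if (!is.null(gwas)) {
    write_sites_vcf(gwas, file.path(dir, "sites.vcf"))
    write.csv(data.frame(site = seq_len(nrow(gwas$sites)),
                         keep = gwas$sites$keep,
                         assoc = seq_len(nrow(gwas$sites)) %in% gwas$assoc),
              file.path(dir, "site_truth.csv"), row.names = FALSE)
    write.csv(gwas$true_af, file.path(dir, "true_af.csv"))
  }
  invisible(dir)
}

#' Write one trajectory as the assay's CSV + YAML pair
#'
#' @param track Trajectory data.frame.
#' @param csv Output CSV path (columns `timestamp`, `x`, `y`, `area`); a
#'   YAML metadata file with the same stem records species, fps and pixel
#'   scale.
#' @param species Species code for the metadata.
#' @return `csv`, invisibly.
#' @export
write_track_csv <- function(track, csv, species = "unknwn") {
  df <- data.frame(timestamp = track$time, x = track$x, y = track$y,
                   area = track$area)
  write.csv(df, csv, row.names = FALSE)
  meta <- list(species = species, fps = attr(track, "fps"),
               px_per_mm = attr(track, "px_per_mm"),
               units = attr(track, "units"))
  yaml::write_yaml(meta, sub("\\.csv$", ".yaml", csv))
  invisible(csv)
}

#' Read a trajectory CSV (+ YAML metadata) written by [write_track_csv()]
#'
#' @param csv CSV path.
#' @return Trajectory data.frame with metadata attributes restored.
#' @export
read_track_csv <- function(csv) {
  df <- read.csv(csv)
  out <- data.frame(time = df$timestamp, x = df$x, y = df$y,
                    area = df$area,
                    missing = !is.finite(df$x))
  yml <- sub("\\.csv$", ".yaml", csv)
  if (file.exists(yml)) {
    meta <- yaml::read_yaml(yml)
    attr(out, "fps") <- meta$fps
    attr(out, "px_per_mm") <- meta$px_per_mm
    attr(out, "units") <- meta$units
    attr(out, "species") <- meta$species
  }
  out
}
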