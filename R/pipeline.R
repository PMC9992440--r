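# end-to-end study: synthesize inputs, backtrack each collection date,
# cluster into sub-origins, run the compositional and environmental tests

#' Default collection dates
#'
#' Two sampling dates per month (the 5th and the 20th) over one year: 24
#' collection days, mirroring an opportunistic monthly beach-sampling
#' effort.
#'
#' @param year Calendar year of the synthetic campaign.
#' @return Sorted `Date` vector of length 24.
#' @export
default_collection_dates <- function(year = 2021) {
  sort(as.Date(sprintf("%d-%02d-%02d", year,
                       rep(1:12, each = 2), c(5, 20))))
}

#' Study configuration
#'
#' Bundles every knob of the end-to-end study. All randomness derives from
#' `seed`: each simulation gets a stable per-date sub-seed, so the study is
#' bit-reproducible and individual simulations can be rerun independently.
#'
#' @param seed Global integer seed.
#' @param field A [field_config()].
#' @param calendar A [regime_calendar()].
#' @param composition A [composition_params()].
#' @param dates Collection dates ([default_collection_dates()] if omitted).
#' @param track A [track_config()] (per-date seeds are derived from
#'   `seed`).
#' @param n_perm Permutations for all tests.
#' @param area_km2 Environmental box area.
#' @param run_dispersal Also run the forward dispersal experiment.
#' @param dispersal_box,dispersal_particles,dispersal_days Forward
#'   dispersal experiment settings (bloom-region-like box).
#' @param rebuild_from_drifters If `TRUE`, the tracking climatology is
#'   rebuilt from synthetic drifter fixes via [build_climatology()]
#'   (`n_drifters`, `drifter_days` control the fleet) instead of using the
#'   generated field directly.
#' @param n_drifters,drifter_days Synthetic drifter fleet size/length when
#'   rebuilding.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L,
                         field = field_config(),
                         calendar = default_regime_calendar(),
                         composition = composition_params(),
                         dates = default_collection_dates(),
                         track = track_config(),
                         n_perm = 999,
                         area_km2 = 93500,
                         run_dispersal = TRUE,
                         dispersal_box = c(-45, -32, 0, 8),
                         dispersal_particles = 200,
                         dispersal_days = 365,
                         rebuild_from_drifters = FALSE,
                         n_drifters = 500, drifter_days = 90) {
  if (length(dates) == 0) stop("study_config: need at least one collection date")
  structure(list(seed = as.integer(seed), field = field, calendar = calendar,
                 composition = composition, dates = as.Date(dates),
                 track = track, n_perm = n_perm, area_km2 = area_km2,
                 run_dispersal = run_dispersal, dispersal_box = dispersal_box,
                 dispersal_particles = dispersal_particles,
                 dispersal_days = dispersal_days,
                 rebuild_from_drifters = rebuild_from_drifters,
                 n_drifters = n_drifters, drifter_days = drifter_days),
            class = "study_config")
}

#' Run the full synthetic study
#'
#' Pipeline: generate current/wind fields (optionally re-gridded through
#' synthetic drifter fixes), generate morphotype samples, backtrack one
#' 100-particle ensemble per collection date, reduce to trajectory
#' metrics, partition into sub-origin pathways by K-means and label them,
#' test morphotype composition between pathways (nested PERMANOVA +
#' dispersion homogeneity), extract environmental records at origins and
#' midpoints and test them (two-factor PERMANOVA), and optionally run the
#' forward dispersal experiment.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return A `study_report` list with elements `metrics`, `assignment`,
#'   `samples`, `monthly_composition`, `composition_permanova`,
#'   `dispersion`, `env_records`, `env_permanova`, `dispersal`,
#'   `recovery` (agreement of recovered labels with the planted regimes)
#'   and a `provenance` block.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (length(config$dates) == 0) stop("no collection dates configured")
  say <- function(...) if (verbose) message(...)

  say("generating current and wind fields")
  fields <- generate_current_field(config$field, config$calendar)
  currents <- fields$currents
  if (config$rebuild_from_drifters) {
    say("re-gridding through synthetic drifter fixes")
    fixes <- generate_drifter_fixes(currents, config$n_drifters,
                                    config$drifter_days,
                                    seed = derive_seed(config$seed, "drifters"))
    currents <- build_climatology(fixes, config$field$res,
                                  lon_range = config$field$lon_range,
                                  lat_range = config$field$lat_range,
                                  land = currents$land)
  }

  say("generating morphotype samples")
  samples <- generate_morphotype_samples(
    config$dates, config$calendar, config$composition,
    seed = derive_seed(config$seed, "samples"))

  say("backtracking ", length(config$dates), " collection dates")
  results <- lapply(config$dates, function(d) {
    cfg <- config$track
    cfg$seed <- derive_seed(config$seed, as.character(d))
    backtrack_sample(config$field$target[1], config$field$target[2], d,
                     currents, fields$wind, cfg)
  })
  names(results) <- as.character(config$dates)

  say("clustering trajectory metrics")
  metrics <- compute_track_metrics(results)
  assignment <- partition_kmeans(metrics, k = 2,
                                 seed = derive_seed(config$seed, "kmeans"))
  assignment <- label_suborigins(assignment, metrics)

  planted <- regime_of_yearday(config$calendar, date_to_yearday(config$dates))
  names(planted) <- as.character(config$dates)
  recovery <- mean(assignment$label[names(planted)] == planted)

  say("compositional statistics")
  z <- ilr_bivariate(to_relative_abundance(sample_volumes(samples)))
  sample_dates <- factor(as.character(samples$date))
  comp_perm <- permanova_nested(
    z, sample_dates, assignment$label,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "permanova"))
  disp <- dispersion_homogeneity(
    z, assignment$label[as.character(samples$date)],
    n_perm = config$n_perm, seed = derive_seed(config$seed, "betadisper"))
  monthly <- aggregate_date_then_month(samples)

  say("environmental statistics")
  env_grid <- generate_env_fields(config$field,
                                  seed = derive_seed(config$seed, "env"))
  env_records <- extract_env_records(results, assignment, env_grid,
                                     config$area_km2)
  env_perm <- env_permanova(env_records, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "envperm"))

  dispersal <- NULL
  if (config$run_dispersal) {
    say("forward dispersal experiment")
    dcfg <- config$track
    dcfg$seed <- derive_seed(config$seed, "dispersal")
    dispersal <- forward_dispersal(config$dispersal_box,
                                   config$dispersal_particles,
                                   config$dispersal_days,
                                   currents, fields$wind, dcfg)
  }

  cfg_hash <- local({
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(config, f)
    unname(tools::md5sum(f))
  })
  structure(list(
    metrics = metrics, assignment = assignment, results = results,
    samples = samples, monthly_composition = monthly,
    composition_permanova = comp_perm, dispersion = disp,
    env_records = env_records, env_permanova = env_perm,
    dispersal = dispersal, planted_regime = planted, recovery = recovery,
    provenance = list(package_version = as.character(utils::packageVersion("sargdrift")),
                      seed = config$seed, config_md5 = cfg_hash,
                      n_dates = length(config$dates))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Sargassum sub-origin study report\n")
  cat(sprintf("  %d collection dates; seed %d\n",
              x$provenance$n_dates, x$provenance$seed))
  cat(sprintf("  pathway recovery vs planted regimes: %.1f%%\n",
              100 * x$recovery))
  print(x$assignment$cluster_summary, row.names = FALSE)
  ct <- x$composition_permanova$aov_tab
  et <- x$env_permanova$aov_tab
  cat(sprintf("  composition PERMANOVA: F = %.3f, p = %.4g\n",
              ct$F.Model[1], ct$p[1]))
  cat(sprintf("  dispersion homogeneity: F = %.3f, p = %.4g\n",
              x$dispersion$F, x$dispersion$p))
  cat(sprintf("  environment PERMANOVA: suborigin p = %.4g, period p = %.4g, interaction p = %.4g\n",
              et$p[et$term == "suborigin"], et$p[et$term == "period"],
              et$p[et$term == "period:suborigin"]))
  if (!is.null(x$dispersal))
    cat(sprintf("  dispersal: %.1f%% dispersed by day %d\n",
                100 * (1 - x$dispersal$fraction[nrow(x$dispersal)]),
                x$dispersal$day[nrow(x$dispersal)]))
  invisible(x)
}
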