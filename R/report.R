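# File-writing entry points tying the pipeline together:
# simulate -> estimate -> metrics -> tables. These back the thin
# command-line wrapper shipped under inst/cli/.

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a survey and write its tables
#'
#' Writes `sites.csv`, `transects.csv`, a per-stratum `truth.csv` (true mean
#' densities and totals) and a `run.json` log (seed and every parameter used)
#' to `out_dir`. The tables are schema-identical to real survey data, so they
#' feed straight back into [read_sites()] and [run_estimate()].
#'
#' @param out_dir Output directory (created if needed).
#' @inheritParams simulate_survey
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, config = sim_config(),
                         frame = skagerrak_frame(),
                         n_per_stratum = skagerrak_site_counts(),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_survey(config, frame, n_per_stratum, seed = seed)
  paths <- list(
    sites = file.path(out_dir, "sites.csv"),
    transects = file.path(out_dir, "transects.csv"),
    truth = file.path(out_dir, "truth.csv"),
    log = file.path(out_dir, "run.json")
  )
  readr::write_csv(sim$sites, paths$sites, progress = FALSE)
  readr::write_csv(sim$transects, paths$transects, progress = FALSE)
  readr::write_csv(sim$population$truth, paths$truth, progress = FALSE)
  write_json(list(
    command = "simulate", seed = seed,
    n_sites = nrow(sim$sites),
    true_total_living = sim$population$true_total_living,
    true_total_dead = sim$population$true_total_dead,
    config = unclass(config)
  ), paths$log)
  invisible(paths)
}

#' Estimate a population from survey tables and write the results
#'
#' Writes `breakdown.csv` (one row per stratum with partial totals and SEs),
#' `estimate_grid.csv` (the domain-by-depth reporting grid in millions) and
#' `summary.json` (total, SE, extent) to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param sites A validated site tibble (or a path to a sites CSV).
#' @param frame A frame tibble (or a path to a strata YAML).
#' @inheritParams estimate_population
#' @return The `population_estimate`, invisibly.
#' @export
run_estimate <- function(out_dir, sites, frame = skagerrak_frame(),
                         which = "living", allow_missing_strata = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(frame)) frame <- load_strata(frame)
  if (is.character(sites)) sites <- read_sites(sites, frame = frame)
  est <- estimate_population(sites, frame, which = which,
                             allow_missing_strata = allow_missing_strata)
  readr::write_csv(
    mutate(est$breakdown,
           se_density = sqrt(.data$var_density / .data$n_sites)) |>
      select(all_of(c("survey_id", "area_label", "depth_label", "n_sites",
                      "mean_density", "se_density", "partial_total",
                      "partial_se"))),
    file.path(out_dir, "breakdown.csv"), progress = FALSE)
  readr::write_csv(estimate_grid(est), file.path(out_dir, "estimate_grid.csv"),
                   progress = FALSE)
  write_json(list(command = "estimate", which = which,
                  validation = site_validation(sites)[c("n_accepted", "n_rejected")],
                  total = est$total, se_total = est$se_total, N_m2 = est$N_m2,
                  mean_density = est$mean_density),
             file.path(out_dir, "summary.json"))
  invisible(est)
}

#' Compute the derived stock metrics and write the report
#'
#' Computes occurrence frequencies and living ratios by depth band, the
#' cumulative density curve (written as `curve.csv`), the bed share at the
#' chosen threshold, the detection-corrected total, biomass, exploitation
#' rates, and habitat-restricted totals under both built-in predicates;
#' everything lands in `metrics.json`. If the site table lacks dead counts
#' the dead-based metrics are skipped with a warning.
#'
#' @param out_dir Output directory.
#' @param sites A validated site tibble.
#' @param transects Optional transect tibble (used for the density curve;
#'   falls back to site-level densities when `NULL`).
#' @param frame A frame tibble.
#' @param threshold Bed density threshold, per m^2.
#' @param mean_weight_g Mean individual weight, g.
#' @param correction_factor Detection-efficiency correction factor.
#' @param landings Annual landings, individuals.
#' @param multiplier Scenario multiplier on landings.
#' @inheritParams estimate_population
#' @return Invisibly, the metrics list written to JSON.
#' @export
run_metrics <- function(out_dir, sites, transects = NULL,
                        frame = skagerrak_frame(), threshold = 5,
                        mean_weight_g = 63, correction_factor = 1.25,
                        landings = 88000, multiplier = 1,
                        allow_missing_strata = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  have_dead <- "dead_count" %in% names(sites) && !anyNA(sites$dead_count)
  if (!have_dead) {
    warn("no usable dead counts; reporting living-based metrics only")
    sites$dead_count <- 0L
  }

  est <- estimate_population(sites, frame, which = "living",
                             allow_missing_strata = allow_missing_strata)
  corrected <- detection_correction(est, correction_factor)
  bio <- biomass(est, mean_weight_g)
  expl <- exploitation_rate(est, landings, 1)
  expl2 <- exploitation_rate(est, landings, multiplier = 2 * multiplier)

  curve <- if (!is.null(transects)) {
    cumulative_density_curve(transects, "living", unit = "transect")
  } else {
    cumulative_density_curve(sites, "living", unit = "site")
  }
  readr::write_csv(curve[c("density", "count", "cum_fraction")],
                   file.path(out_dir, "curve.csv"), progress = FALSE)
  beds <- bed_share(curve, threshold)

  restricted <- list()
  if (have_dead) {
    restricted$living_or_dead_present <- glance(habitat_restricted_estimate(
      sites, frame, "living_or_dead_present", on_single = "drop",
      allow_missing_strata = allow_missing_strata))
  }
  if (all(c("sub_mud", "sub_sand", "sub_gravel", "sub_shell", "sub_rock") %in%
          names(sites))) {
    restricted$mobile_majority <- glance(habitat_restricted_estimate(
      sites, frame, "mobile_majority", on_single = "drop",
      allow_missing_strata = allow_missing_strata))
  }

  metrics <- list(
    command = "metrics",
    occurrence_living = occurrence_frequency(sites, "living"),
    occurrence_dead = if (have_dead) occurrence_frequency(sites, "dead"),
    living_ratio = if (have_dead) living_ratio(sites),
    bed_share = beds,
    total = est$total, se_total = est$se_total,
    corrected_total = corrected$total, corrected_se = corrected$se_total,
    correction_factor = correction_factor,
    biomass_tonnes = bio$total_tonnes, biomass_se_tonnes = bio$se_tonnes,
    exploitation_percent = expl$rate_percent,
    exploitation_doubled_percent = expl2$rate_percent,
    habitat_restricted = restricted
  )
  write_json(metrics, file.path(out_dir, "metrics.json"))
  invisible(metrics)
}

#' Estimate and metrics in one run
#'
#' @inheritParams run_metrics
#' @inheritParams run_estimate
#' @return Invisibly, a list with the estimate and the metrics.
#' @export
run_report <- function(out_dir, sites, transects = NULL,
                       frame = skagerrak_frame(), which = "living",
                       threshold = 5, mean_weight_g = 63,
                       correction_factor = 1.25, landings = 88000,
                       multiplier = 1, allow_missing_strata = FALSE) {
  est <- run_estimate(out_dir, sites, frame, which = which,
                      allow_missing_strata = allow_missing_strata)
  metrics <- run_metrics(out_dir, sites, transects, frame,
                         threshold = threshold, mean_weight_g = mean_weight_g,
                         correction_factor = correction_factor,
                         landings = landings, multiplier = multiplier,
                         allow_missing_strata = allow_missing_strata)
  invisible(list(estimate = est, metrics = metrics))
}
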