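# Synthetic populations and towed-video observation: ground-truth patchy
# densities over a stratified frame, plus the observation process (Poisson
# counts over the filmed area, thinned by imperfect detection), so the
# estimator can be validated against known truth.

#' Simulation configuration
#'
#' Parameters of the synthetic oyster population and of the towed-video
#' observation process. Per-depth arguments accept a scalar (recycled) or a
#' vector named by the depth bands (see [depth_bands()]).
#'
#' The default parameterisation ("skagerrak-like") emulates the Swedish
#' Skagerrak flat-oyster population: site occupancy declining with depth
#' (0.25 / 0.19 / 0.06), a heavy-tailed lognormal density among occupied
#' cells (sdlog 1.8) whose conditional means (1.68 / 1.03 / 0.28 per m^2)
#' put the stratum mean densities at the magnitudes the frame supports, a
#' dead-shell load increasing with depth, and 80% detection efficiency.
#' These defaults are illustrative calibration anchors, not fitted values.
#'
#' @param occupancy Probability that a cell holds any living oysters, per
#'   depth band.
#' @param conditional_mean Mean living density (per m^2) among occupied
#'   cells, per depth band.
#' @param sdlog Lognormal log-scale SD of the conditional density (heavier
#'   tail = patchier population), per depth band.
#' @param dead_per_living Expected dead-shell density per unit living density
#'   in occupied cells, per depth band (increasing with depth: shells persist
#'   and accumulate downslope).
#' @param dead_only_occupancy Probability that a cell *without* living
#'   oysters holds dead shells, per depth band.
#' @param dead_only_mean Mean dead density among such dead-only cells, per
#'   m^2.
#' @param detection_efficiency Probability that an individual present in the
#'   filmed strip is counted by the video reader (default 0.8, i.e. a 20%
#'   miss rate; the reciprocal 1.25 is the standard correction factor).
#' @param undetectable_fraction Fraction of individuals below the minimum
#'   detectable size class (roughly 4 cm on video). Default 0: the simulated
#'   truth is the detectable (adult) population.
#' @param transects_per_site,transect_length_m,frame_width_m Observation
#'   geometry; defaults give the standard 32 m^2 filmed per site.
#' @param cells_per_stratum Number of equal-area cells discretising each
#'   stratum; candidate sites are drawn from these without replacement.
#' @param family Conditional-density family: `"lognormal"` or `"constant"`
#'   (degenerate at `conditional_mean`, useful for exact closed-form checks).
#' @param mobile_fraction Probability that a simulated site is dominated by
#'   mobile substrates (mud/sand/gravel/shell) rather than rock.
#' @return A `sim_config` list.
#' @export
sim_config <- function(occupancy = c("0.5-3" = 0.25, "3-6" = 0.19, "6-10" = 0.06),
                       conditional_mean = c("0.5-3" = 1.68, "3-6" = 1.03, "6-10" = 0.28),
                       sdlog = 1.8,
                       dead_per_living = c("0.5-3" = 0.55, "3-6" = 1.0, "6-10" = 2.5),
                       dead_only_occupancy = c("0.5-3" = 0.15, "3-6" = 0.16, "6-10" = 0.14),
                       dead_only_mean = 0.3,
                       detection_efficiency = 0.8,
                       undetectable_fraction = 0,
                       transects_per_site = 2,
                       transect_length_m = 20,
                       frame_width_m = 0.8,
                       cells_per_stratum = 2000,
                       family = "lognormal",
                       mobile_fraction = 0.85) {
  per_depth <- function(x, name) {
    if (is.null(names(x))) {
      if (!length(x) %in% c(1L, 3L)) {
        abort(paste0(name, " must be scalar or one value per depth band"))
      }
      x <- setNames(rep_len(x, 3), depth_bands())
    }
    missing <- setdiff(depth_bands(), names(x))
    if (length(missing) > 0) {
      abort(paste0(name, " missing depth band(s): ", paste(missing, collapse = ", ")))
    }
    x[depth_bands()]
  }
  prob_ok <- function(x) all(is.finite(x) & x >= 0 & x <= 1)
  if (!family %in% c("lognormal", "constant")) {
    abort(paste0("unknown conditional-density family: ", family),
          class = "seastrat_validation_error")
  }
  cfg <- list(
    occupancy = per_depth(occupancy, "occupancy"),
    conditional_mean = per_depth(conditional_mean, "conditional_mean"),
    sdlog = per_depth(sdlog, "sdlog"),
    dead_per_living = per_depth(dead_per_living, "dead_per_living"),
    dead_only_occupancy = per_depth(dead_only_occupancy, "dead_only_occupancy"),
    dead_only_mean = dead_only_mean,
    detection_efficiency = detection_efficiency,
    undetectable_fraction = undetectable_fraction,
    transects_per_site = as.integer(transects_per_site),
    transect_length_m = transect_length_m,
    frame_width_m = frame_width_m,
    cells_per_stratum = as.integer(cells_per_stratum),
    family = family,
    mobile_fraction = mobile_fraction
  )
  if (!prob_ok(cfg$occupancy) || !prob_ok(cfg$dead_only_occupancy) ||
      !prob_ok(cfg$detection_efficiency) || !prob_ok(cfg$undetectable_fraction) ||
      !prob_ok(cfg$mobile_fraction)) {
    abort("probabilities must lie in [0, 1]", class = "seastrat_validation_error")
  }
  if (any(cfg$sdlog <= 0 & family == "lognormal") ||
      any(cfg$conditional_mean < 0) || cfg$cells_per_stratum < 1) {
    abort("scale parameters must be positive", class = "seastrat_validation_error")
  }
  structure(cfg, class = "sim_config")
}

#' Expected densities implied by a simulation configuration
#'
#' Closed forms used as oracles in tests: the expected living density of a
#' cell is `occupancy * conditional_mean` (the lognormal is parameterised by
#' its conditional mean, `meanlog = log(mean) - sdlog^2/2`); the expected
#' dead density adds the coupled dead load in occupied cells and the
#' dead-only background.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per depth band.
#' @export
sim_expected_density <- function(config) {
  tibble(
    depth_label = depth_bands(),
    occupancy = unname(config$occupancy),
    conditional_mean = unname(config$conditional_mean),
    expected_living = unname(config$occupancy * config$conditional_mean),
    expected_dead = unname(
      config$occupancy * config$conditional_mean * config$dead_per_living +
        (1 - config$occupancy) * config$dead_only_occupancy * config$dead_only_mean
    )
  )
}

#' Generate a ground-truth population over a stratified frame
#'
#' Discretises every stratum into `cells_per_stratum` equal-area cells and
#' draws a zero-inflated heavy-tailed living density per cell: occupied with
#' the depth band's occupancy probability, and lognormal given occupancy.
#' Overdispersion (patchiness) lives entirely in this density field; counting
#' noise is added later by [observe_site()]. The dead-shell density couples
#' to the living density in occupied cells and has an independent background
#' in empty cells, so the living/(living+dead) ratio declines with depth.
#'
#' @param config A [sim_config()].
#' @param frame A frame tibble (default [skagerrak_frame()]).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `synthetic_population`: list with `cells` (one row per cell:
#'   labels, `cell_area_m2`, `living_density`, `dead_density`), `frame`,
#'   `config`, `true_total_living`, `true_total_dead`, and a per-stratum
#'   `truth` tibble.
#' @export
generate_population <- function(config = sim_config(), frame = skagerrak_frame(),
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  frame <- as_frame(frame)
  if (!is.null(seed)) withr::local_seed(seed)

  n <- config$cells_per_stratum
  cells <- frame[rep(seq_len(nrow(frame)), each = n), ]
  cells$cell_index <- rep(seq_len(n), times = nrow(frame))
  cells$cell_id <- sprintf("%s|%s|%04d", cells$area_label, cells$depth_label,
                           cells$cell_index)
  cells$cell_area_m2 <- cells$areal_extent_m2 / n

  depth <- cells$depth_label
  occ <- runif(nrow(cells)) < config$occupancy[depth]
  cond <- switch(config$family,
    lognormal = rlnorm(nrow(cells),
                       meanlog = log(config$conditional_mean[depth]) -
                         config$sdlog[depth]^2 / 2,
                       sdlog = config$sdlog[depth]),
    constant = unname(config$conditional_mean[depth])
  )
  cells$living_density <- ifelse(occ, cond, 0)

  dead_bg <- (!occ) & (runif(nrow(cells)) < config$dead_only_occupancy[depth])
  bg_dens <- if (config$family == "lognormal") {
    rlnorm(nrow(cells), meanlog = log(config$dead_only_mean) -
             config$sdlog[depth]^2 / 2, sdlog = config$sdlog[depth])
  } else {
    rep(config$dead_only_mean, nrow(cells))
  }
  cells$dead_density <- cells$living_density * config$dead_per_living[depth] +
    ifelse(dead_bg, bg_dens, 0)

  cells <- as_tibble(cells[c("cell_id", "survey_id", "area_label", "depth_label",
                             "cell_index", "cell_area_m2",
                             "living_density", "dead_density")])
  truth <- cells |>
    group_by(.data$survey_id, .data$area_label, .data$depth_label) |>
    summarise(n_cells = dplyr::n(),
              true_mean_living = mean(.data$living_density),
              true_total_living = sum(.data$living_density * .data$cell_area_m2),
              true_total_dead = sum(.data$dead_density * .data$cell_area_m2),
              .groups = "drop")
  structure(
    list(cells = cells, frame = frame, config = config, truth = truth,
         true_total_living = sum(truth$true_total_living),
         true_total_dead = sum(truth$true_total_dead)),
    class = "synthetic_population"
  )
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population: ", nrow(x$cells), " cells over ",
      nrow(x$frame), " strata>\n", sep = "")
  cat(sprintf("  true living total %.2f million, dead total %.2f million\n",
              x$true_total_living / 1e6, x$true_total_dead / 1e6))
  invisible(x)
}

#' @export
glance.synthetic_population <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_strata = nrow(x$frame),
         true_total_living = x$true_total_living,
         true_total_dead = x$true_total_dead)
}

# Observation process over a set of cells (or bare densities).
# Latent abundance in the filmed strip is Poisson(density * filmed area);
# each individual is counted independently with probability
# detection_efficiency * (1 - undetectable_fraction).
observe_cells <- function(cells, config, expectation = FALSE,
                          transects = TRUE) {
  filmed <- site_filmed_area(config$transects_per_site,
                             config$transect_length_m, config$frame_width_m)
  p <- config$detection_efficiency * (1 - config$undetectable_fraction)
  nsite <- nrow(cells)

  draw <- function(dens) {
    lambda <- dens * filmed
    if (expectation) {
      lambda * p
    } else {
      latent <- rpois(nsite, lambda)
      rbinom(nsite, latent, p)
    }
  }
  living <- draw(cells$living_density)
  dead <- draw(cells$dead_density)

  mobile <- runif(nsite) < config$mobile_fraction
  sites <- tibble(
    site_id = cells$cell_id,
    area_label = cells$area_label,
    depth_label = cells$depth_label,
    n_transects = config$transects_per_site,
    filmed_area_m2 = filmed,
    living_count = living,
    dead_count = dead,
    rocky_absent = FALSE,
    sub_mud = ifelse(mobile, 0.50, 0.10),
    sub_sand = ifelse(mobile, 0.30, 0.15),
    sub_gravel = ifelse(mobile, 0.10, 0.05),
    sub_shell = ifelse(mobile, 0.05, 0.05),
    sub_rock = ifelse(mobile, 0.05, 0.65),
    veg_cover = round(runif(nsite, 0, 0.6), 2)
  )

  tr <- NULL
  if (transects) {
    k <- config$transects_per_site
    split_counts <- function(count) {
      # multinomial-uniform split via sequential binomials, vectorised
      out <- matrix(0, nrow = nsite, ncol = k)
      remaining <- count
      for (j in seq_len(k - 1)) {
        out[, j] <- if (expectation) remaining / (k - j + 1) else
          rbinom(nsite, remaining, 1 / (k - j + 1))
        remaining <- remaining - out[, j]
      }
      out[, k] <- remaining
      out
    }
    lm <- split_counts(living)
    dm <- split_counts(dead)
    tr <- tibble(
      site_id = rep(sites$site_id, each = k),
      transect_index = rep(seq_len(k), times = nsite),
      length_m = config$transect_length_m,
      frame_width_m = config$frame_width_m,
      living_count = as.vector(t(lm)),
      dead_count = as.vector(t(dm))
    )
  }
  list(sites = sites, transects = tr)
}

#' Simulate the towed-video observation of sites with known density
#'
#' For each true density, the number of individuals present in the filmed
#' strip is Poisson with mean `density * filmed_area`; each is counted
#' independently with probability
#' `detection_efficiency * (1 - undetectable_fraction)`, so the expected
#' observed count is `density * filmed_area * p`. Counts are split across
#' the site's transects multinomially with equal probabilities.
#'
#' @param true_density Vector of true living densities, per m^2.
#' @param config A [sim_config()].
#' @param true_dead_density Optional vector of dead densities (default 0).
#' @param seed Optional integer seed.
#' @param expectation If `TRUE`, counts are replaced by their (possibly
#'   non-integer) expectations — the deterministic "census" observation used
#'   in exactness checks.
#' @param transects Also return per-transect counts?
#' @return A list with `sites` and `transects` tibbles in the survey-table
#'   schema.
#' @export
observe_site <- function(true_density, config = sim_config(),
                         true_dead_density = 0, seed = NULL,
                         expectation = FALSE, transects = TRUE) {
  stopifnot(all(true_density >= 0))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(true_density)
  cells <- tibble(
    cell_id = sprintf("S%04d", seq_len(n)),
    area_label = "sim", depth_label = depth_bands()[1],
    living_density = true_density,
    dead_density = rep_len(true_dead_density, n)
  )
  observe_cells(cells, config, expectation = expectation, transects = transects)
}

#' Draw a stratified random survey from a synthetic population
#'
#' Samples sites uniformly without replacement from each stratum's cells and
#' passes them through the observation model, returning tables in the same
#' schema as real survey data.
#'
#' @param population A `synthetic_population`.
#' @param n_per_stratum Sites to sample per stratum: a single number (every
#'   (area, depth) cell gets the same n), a vector named by depth band, or a
#'   tibble `(area_label, depth_label, n)`.
#' @param seed Optional integer seed.
#' @inheritParams observe_site
#' @return A list with `sites`, `transects` (or `NULL`) and `cells` (the
#'   sampled cells with their true densities).
#' @export
generate_survey <- function(population, n_per_stratum = 15, seed = NULL,
                            expectation = FALSE, transects = TRUE) {
  stopifnot(inherits(population, "synthetic_population"))
  if (!is.null(seed)) withr::local_seed(seed)
  cfg <- population$config
  frame <- population$frame

  plan <- if (is.data.frame(n_per_stratum)) {
    as_tibble(n_per_stratum)
  } else if (!is.null(names(n_per_stratum))) {
    tibble(depth_label = names(n_per_stratum), n = as.integer(n_per_stratum)) |>
      left_join(x = frame[c("area_label", "depth_label")], by = "depth_label")
  } else {
    mutate(frame[c("area_label", "depth_label")], n = as.integer(n_per_stratum))
  }
  plan <- left_join(frame[c("area_label", "depth_label")], plan,
                    by = c("area_label", "depth_label"))
  plan$n[is.na(plan$n)] <- 0L

  chosen <- purrr::pmap_dfr(plan, function(area_label, depth_label, n, ...) {
    cells <- filter(population$cells, .data$area_label == .env$area_label,
                    .data$depth_label == .env$depth_label)
    if (n > nrow(cells)) {
      abort(paste0("requested ", n, " sites but only ", nrow(cells),
                   " cells in stratum ", area_label, " / ", depth_label),
            class = "seastrat_validation_error")
    }
    cells[sort(sample.int(nrow(cells), n)), ]
  })
  obs <- observe_cells(chosen, cfg, expectation = expectation,
                       transects = transects)
  list(sites = obs$sites, transects = obs$transects, cells = chosen)
}

#' Per-stratum site counts of the Skagerrak inventory
#'
#' The sampling intensities of the original field inventory (how many sites
#' were filmed per area and depth band). The two deep coastal cells that the
#' inventory left unsampled are assigned the typical deep-stratum intensity
#' (15 sites) so that a simulated survey covers the whole frame.
#'
#' @return A tibble `(area_label, depth_label, n)`.
#' @export
skagerrak_site_counts <- function() {
  tibble(
    area_label = rep(c("Area 1", "Area 2", "Area 3", "Area 4", "Koster"), each = 3),
    depth_label = rep(depth_bands(), times = 5),
    n = as.integer(c(22, 16, 15,
                     24, 33, 20,
                     32, 38, 15,
                     26, 34, 15,
                     59, 55, 61))
  )
}

#' Simulate a complete stratified towed-video survey
#'
#' Convenience wrapper: generates a ground-truth population over the frame
#' and draws one stratified survey from it with the Skagerrak sampling
#' intensities by default.
#'
#' @inheritParams generate_population
#' @inheritParams generate_survey
#' @return A list with `population`, `sites`, `transects`, `cells`.
#' @examples
#' sim <- simulate_survey(seed = 42)
#' estimate_population(sim$sites, skagerrak_frame())
#' @export
simulate_survey <- function(config = sim_config(), frame = skagerrak_frame(),
                            n_per_stratum = skagerrak_site_counts(),
                            seed = NULL, expectation = FALSE, transects = TRUE) {
  if (!is.null(seed)) withr::local_seed(seed)
  population <- generate_population(config, frame)
  survey <- generate_survey(population, n_per_stratum,
                            expectation = expectation, transects = transects)
  c(list(population = population), survey)
}
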