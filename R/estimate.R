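# Design-based stratified estimation: per-stratum means and variances,
# areal weighting within each survey domain, population totals +- SE,
# and combination of independently planned surveys.

#' Per-stratum sample estimates
#'
#' Computes, for every (area, depth-band) stratum of the frame, the number of
#' sampled sites, the arithmetic mean of site densities and their unbiased
#' (n-1 denominator) sample variance. These are the building blocks of the
#' stratified estimator: strata are combined within each survey domain with
#' areal weights by [stratified_mean()] and [stratified_variance()].
#'
#' @param sites A validated site tibble.
#' @param frame A frame tibble (see [as_frame()]).
#' @param which `"living"` or `"dead"`.
#' @param allow_missing_strata If `FALSE` (default), a frame cell with no
#'   sampled sites is an error: the estimator refuses to extrapolate
#'   silently. If `TRUE`, such cells are dropped from the frame (they then
#'   contribute neither weight nor area downstream).
#' @return A tibble with one row per stratum: `survey_id, area_label,
#'   depth_label, areal_extent_m2, n_sites, mean_density, var_density`.
#' @export
stratum_estimates <- function(sites, frame, which = c("living", "dead"),
                              allow_missing_strata = FALSE) {
  which <- rlang::arg_match(which)
  frame <- as_frame(frame)
  dens <- site_density(sites, which)

  unknown <- anti_join(dens, frame, by = c("area_label", "depth_label"))
  if (nrow(unknown) > 0) {
    abort(paste0(nrow(unknown), " site(s) reference strata absent from the frame; ",
                 "validate with a frame first"),
          class = "seastrat_validation_error")
  }

  per <- dens |>
    group_by(.data$area_label, .data$depth_label) |>
    summarise(n_sites = dplyr::n(),
              mean_density = mean(.data$density),
              var_density = var(.data$density),
              .groups = "drop")
  out <- left_join(frame, per, by = c("area_label", "depth_label"))

  empty <- is.na(out$n_sites)
  if (any(empty)) {
    labels <- paste(out$area_label[empty], out$depth_label[empty], sep = " / ")
    if (!allow_missing_strata) {
      abort(paste0("frame cell(s) with no sampled sites: ",
                   paste(labels, collapse = "; "),
                   " (set allow_missing_strata = TRUE to exclude them from ",
                   "weights and total area)"),
            class = "seastrat_missing_stratum_error")
    }
    out <- out[!empty, , drop = FALSE]
  }
  thin <- out$n_sites < 2
  if (any(thin)) {
    labels <- paste(out$area_label[thin], out$depth_label[thin], sep = " / ")
    abort(paste0("stratum variance undefined (fewer than 2 sites) in: ",
                 paste(labels, collapse = "; ")),
          class = "seastrat_validation_error")
  }
  out
}

add_stratum_weights <- function(estimates) {
  estimates |>
    group_by(.data$survey_id) |>
    mutate(weight = .data$areal_extent_m2 / sum(.data$areal_extent_m2)) |>
    ungroup()
}

#' Stratified mean density per survey domain
#'
#' The areally weighted mean `sum(W_st * ybar_st)` with
#' `W_st = A_st / sum(A_st)` taken within each survey domain (`survey_id`),
#' because the surveys were planned independently.
#'
#' @param estimates A stratum-estimate tibble from [stratum_estimates()].
#' @return A tibble with one row per `survey_id`: `N_m2` (total extent),
#'   `mean_density` (per m^2).
#' @export
stratified_mean <- function(estimates) {
  add_stratum_weights(estimates) |>
    group_by(.data$survey_id) |>
    summarise(N_m2 = sum(.data$areal_extent_m2),
              mean_density = sum(.data$weight * .data$mean_density),
              .groups = "drop")
}

#' Variance of the stratified mean per survey domain
#'
#' `sum(W_st^2 * s2_st / n_st)`, the classical stratified-sampling variance
#' of the mean. No finite-population correction is applied: sites are random
#' positions in continuous habitat, not draws from a finite list.
#'
#' @inheritParams stratified_mean
#' @return A tibble with one row per `survey_id`: `N_m2`, `var_mean`
#'   ((per m^2)^2).
#' @export
stratified_variance <- function(estimates) {
  add_stratum_weights(estimates) |>
    group_by(.data$survey_id) |>
    summarise(N_m2 = sum(.data$areal_extent_m2),
              var_mean = sum(.data$weight^2 * .data$var_density / .data$n_sites),
              .groups = "drop")
}

new_population_estimate <- function(label, N_m2, mean_density, var_mean,
                                    breakdown = NULL, surveys = NULL,
                                    which = NA_character_, notes = character()) {
  if (!is.finite(var_mean) || var_mean < 0) {
    abort("variance of the mean must be non-negative",
          class = "seastrat_validation_error")
  }
  structure(
    list(label = label,
         N_m2 = N_m2,
         mean_density = mean_density,
         var_mean = var_mean,
         total = mean_density * N_m2,
         se_total = sqrt(var_mean) * N_m2,
         breakdown = breakdown,
         surveys = surveys,
         which = which,
         notes = notes),
    class = "population_estimate"
  )
}

#' Population total from a mean density and an areal extent
#'
#' Scales a mean density and the variance of that mean to the full surveyed
#' extent: `total = mean * N`, `SE(total) = sqrt(V) * N`. The error term is
#' the standard error of the total, i.e. the square root of the variance of
#' the mean scaled by N.
#'
#' @param mean_density Mean density, individuals per m^2.
#' @param var_mean Variance of the mean, (per m^2)^2.
#' @param N_m2 Total areal extent of the estimated domain, m^2.
#' @param label Domain label.
#' @return A `population_estimate` object; see [tidy.population_estimate()].
#' @export
population_total <- function(mean_density, var_mean, N_m2, label = "population") {
  if (!is.finite(N_m2) || N_m2 <= 0) {
    abort("N_m2 must be positive", class = "seastrat_validation_error")
  }
  new_population_estimate(label, N_m2, mean_density, var_mean)
}

#' Combine independently planned surveys
#'
#' Totals add; the SE of the combined total is the root sum of squares of the
#' independent survey SEs; extents add. Order-invariant.
#'
#' @param estimates A list of `population_estimate` objects with distinct
#'   labels (duplicate labels are an error: each survey enters once).
#' @param label Label for the combined estimate.
#' @return A `population_estimate` whose `surveys` field tabulates the inputs.
#' @export
combine_surveys <- function(estimates, label = "combined") {
  if (inherits(estimates, "population_estimate")) estimates <- list(estimates)
  if (length(estimates) < 1) {
    abort("need at least one survey estimate", class = "seastrat_validation_error")
  }
  labels <- vapply(estimates, function(e) e$label, character(1))
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate survey label(s): ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
          class = "seastrat_validation_error")
  }
  surveys <- purrr::map_dfr(estimates, glance)
  N <- sum(surveys$N_m2)
  total <- sum(surveys$total)
  var_total <- sum(surveys$se_total^2)
  breakdown <- purrr::map_dfr(estimates, function(e) e$breakdown)
  if (nrow(breakdown) == 0) breakdown <- NULL
  new_population_estimate(
    label, N,
    mean_density = total / N,
    var_mean = var_total / N^2,
    breakdown = breakdown,
    surveys = surveys,
    which = unique(vapply(estimates, function(e) e$which, character(1)))[1],
    notes = unique(unlist(lapply(estimates, function(e) e$notes)))
  )
}

#' Full stratified estimation pipeline
#'
#' From a validated site table and a frame to a combined population estimate:
#' per-stratum means/variances, areal weighting and totals within each survey
#' domain, then combination of the independent surveys. The `breakdown` field
#' gives one row per stratum with its partial total `A_st * ybar_st` and
#' partial SE `A_st * sqrt(s2_st / n_st)`; partials sum to the domain totals.
#'
#' @inheritParams stratum_estimates
#' @param label Label for the combined estimate.
#' @return A `population_estimate`.
#' @examples
#' sim <- simulate_survey(seed = 1)
#' est <- estimate_population(sim$sites, skagerrak_frame())
#' glance(est)
#' @export
estimate_population <- function(sites, frame, which = c("living", "dead"),
                                allow_missing_strata = FALSE,
                                label = "combined") {
  which <- rlang::arg_match(which)
  est <- stratum_estimates(sites, frame, which = which,
                           allow_missing_strata = allow_missing_strata)
  est <- add_stratum_weights(est)
  per_survey <- lapply(split(est, est$survey_id), function(g) {
    N <- sum(g$areal_extent_m2)
    mean_d <- sum(g$weight * g$mean_density)
    var_m <- sum(g$weight^2 * g$var_density / g$n_sites)
    breakdown <- g |>
      mutate(partial_total = .data$areal_extent_m2 * .data$mean_density,
             partial_se = .data$areal_extent_m2 *
               sqrt(.data$var_density / .data$n_sites)) |>
      select(all_of(c("survey_id", "area_label", "depth_label", "n_sites",
                      "areal_extent_m2", "weight", "mean_density",
                      "var_density", "partial_total", "partial_se")))
    new_population_estimate(g$survey_id[1], N, mean_d, var_m,
                            breakdown = breakdown, which = which)
  })
  combine_surveys(unname(per_survey), label = label)
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate: ", x$label,
      if (!is.na(x$which)) paste0(" (", x$which, ")"), ">\n", sep = "")
  cat(sprintf("  total   %.2f million individuals (SE %.2f million)\n",
              x$total / 1e6, x$se_total / 1e6))
  cat(sprintf("  mean    %.4g per m2 over %.2f km2\n",
              x$mean_density, x$N_m2 / 1e6))
  if (!is.null(x$surveys) && nrow(x$surveys) > 1) {
    cat("  surveys:", paste(x$surveys$label, collapse = ", "), "\n")
  }
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Tidy a population estimate into its per-stratum breakdown
#'
#' @param x A `population_estimate`.
#' @param ... Unused.
#' @return The per-stratum breakdown tibble (one row per (survey, area,
#'   depth) cell with partial totals and SEs), or a one-row summary when the
#'   estimate carries no breakdown.
#' @export
tidy.population_estimate <- function(x, ...) {
  if (!is.null(x$breakdown)) x$breakdown else glance(x)
}

#' One-row summary of a population estimate
#'
#' @param x A `population_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `label, N_m2, mean_density, var_mean, total,
#'   se_total`.
#' @export
glance.population_estimate <- function(x, ...) {
  tibble(label = x$label, N_m2 = x$N_m2, mean_density = x$mean_density,
         var_mean = x$var_mean, total = x$total, se_total = x$se_total)
}

#' Domain-by-depth grid of partial totals
#'
#' Reshapes a combined estimate's breakdown into the conventional reporting
#' layout: one row per survey domain plus a combined row, one column per
#' depth band (partial totals in millions of individuals), and `total` /
#' `se_total` margin columns.
#'
#' @param est A `population_estimate` with a breakdown.
#' @param digits Decimal places for the millions scale (default 2).
#' @return A tibble.
#' @export
estimate_grid <- function(est, digits = 2) {
  if (is.null(est$breakdown)) {
    abort("estimate carries no per-stratum breakdown")
  }
  b <- est$breakdown
  by_depth <- b |>
    group_by(.data$survey_id, .data$depth_label) |>
    summarise(partial = sum(.data$partial_total) / 1e6, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "depth_label", values_from = "partial")
  margins <- b |>
    group_by(.data$survey_id) |>
    summarise(total = sum(.data$partial_total) / 1e6,
              se_total = sqrt(sum(.data$partial_se^2)) / 1e6,
              .groups = "drop")
  grid <- left_join(by_depth, margins, by = "survey_id")
  combined <- tibble(survey_id = est$label)
  for (dl in setdiff(names(by_depth), "survey_id")) {
    combined[[dl]] <- sum(by_depth[[dl]], na.rm = TRUE)
  }
  combined$total <- est$total / 1e6
  combined$se_total <- est$se_total / 1e6
  out <- bind_rows(grid, combined)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  out
}
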