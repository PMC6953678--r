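# Derived stock metrics: occurrence frequencies, living/dead ratios, the
# cumulative density concentration curve and bed share, detection-efficiency
# correction, biomass, exploitation rates, and the habitat-restricted
# re-estimate.

#' Frequency of occurrence
#'
#' Proportion of sampled sites holding at least one individual, per group
#' (by default per depth band), with the plain binomial standard error
#' `sqrt(p(1-p)/n)`.
#'
#' @param sites A validated site tibble.
#' @param which `"living"` or `"dead"`.
#' @param group_by Grouping column(s), e.g. `"depth_label"` or
#'   `c("area_label", "depth_label")`.
#' @return A tibble: grouping columns, `n_sites`, `n_present`, `proportion`,
#'   `se`.
#' @export
occurrence_frequency <- function(sites, which = c("living", "dead"),
                                 group_by = "depth_label") {
  which <- rlang::arg_match(which)
  if (nrow(sites) == 0) abort("no sites", class = "seastrat_validation_error")
  count <- sites[[paste0(which, "_count")]]
  sites <- as_tibble(sites)
  sites$.present <- count >= 1
  sites |>
    dplyr::group_by(across(all_of(group_by))) |>
    summarise(n_sites = dplyr::n(),
              n_present = sum(.data$.present),
              .groups = "drop") |>
    mutate(proportion = .data$n_present / .data$n_sites,
           se = sqrt(.data$proportion * (1 - .data$proportion) / .data$n_sites))
}

#' Living/(living + dead) ratio
#'
#' The per-site ratio of living to total (living + dead) counts — a crude
#' survival/condition proxy — averaged per group over the sites that contain
#' any oysters at all (living + dead >= 1). Groups with no qualifying site
#' are kept with `NA` (missing, not zero).
#'
#' @inheritParams occurrence_frequency
#' @return A tibble: grouping columns, `n_sites` (qualifying), `mean_ratio`,
#'   `se` (standard error of the mean over sites).
#' @export
living_ratio <- function(sites, group_by = "depth_label") {
  sites |>
    mutate(.tot = .data$living_count + .data$dead_count,
           .ratio = ifelse(.data$.tot >= 1, .data$living_count / .data$.tot, NA_real_)) |>
    dplyr::group_by(across(all_of(group_by))) |>
    summarise(n_sites = sum(!is.na(.data$.ratio)),
              mean_ratio = if (sum(!is.na(.data$.ratio)) > 0)
                mean(.data$.ratio, na.rm = TRUE) else NA_real_,
              se = if (sum(!is.na(.data$.ratio)) > 1)
                sd(.data$.ratio, na.rm = TRUE) / sqrt(sum(!is.na(.data$.ratio)))
              else NA_real_,
              .groups = "drop")
}

#' Cumulative density concentration curve
#'
#' Orders observation units (transects by default, sites if the table has a
#' `filmed_area_m2` column and `unit = "site"`) from low to high density and
#' accumulates the fraction of all counted individuals at or below each
#' density. A steeply rising tail means the population is concentrated in a
#' few high-density units — the signature of a patchy, bed-forming stock.
#'
#' @param x A transect tibble (columns `length_m`, `frame_width_m`) or a site
#'   tibble (column `filmed_area_m2`).
#' @param which `"living"` or `"dead"`.
#' @param unit `"transect"` or `"site"`; chooses the density denominator.
#' @return A `density_curve` tibble: `density` (non-decreasing), `count`,
#'   `cum_count`, `cum_fraction` (non-decreasing, ending at 1).
#' @export
cumulative_density_curve <- function(x, which = c("living", "dead"),
                                     unit = c("transect", "site")) {
  which <- rlang::arg_match(which)
  unit <- rlang::arg_match(unit)
  dens <- if (unit == "transect") transect_density(x, which) else
    site_density(x, which)
  count <- dens[[paste0(which, "_count")]]
  total <- sum(count)
  if (!isTRUE(total > 0)) {
    abort("curve undefined: total counted individuals is 0",
          class = "seastrat_validation_error")
  }
  ord <- order(dens$density)  # stable: ties keep original order
  out <- tibble(density = dens$density[ord], count = count[ord]) |>
    mutate(cum_count = cumsum(.data$count),
           cum_fraction = .data$cum_count / total)
  class(out) <- c("density_curve", class(out))
  attr(out, "unit") <- unit
  attr(out, "which") <- which
  out
}

#' Share of the population in bed densities
#'
#' From a [cumulative_density_curve()], the fraction of all counted
#' individuals found at units with density at or above the threshold
#' (default 5 per m^2, the OSPAR "five or more individuals per m^2" oyster-bed
#' definition), together with the fraction of units at or above it.
#'
#' @param curve A `density_curve`.
#' @param threshold Bed density threshold, per m^2.
#' @param denominator `"nonzero"` counts the unit share among units with at
#'   least one individual (the convention used when quoting "x out of n
#'   transects having living oysters"); `"all"` uses every unit.
#' @return A one-row tibble: `threshold`, `population_share`,
#'   `n_units_at_or_above`, `n_units`, `unit_share`, `denominator`.
#' @export
bed_share <- function(curve, threshold = 5,
                      denominator = c("nonzero", "all")) {
  denominator <- rlang::arg_match(denominator)
  at_or_above <- curve$density >= threshold
  pop_share <- sum(curve$count[at_or_above]) / sum(curve$count)
  units <- if (denominator == "nonzero") curve$count >= 1 else
    rep(TRUE, nrow(curve))
  tibble(threshold = threshold,
         population_share = pop_share,
         n_units_at_or_above = sum(at_or_above & units),
         n_units = sum(units),
         unit_share = sum(at_or_above & units) / sum(units),
         denominator = denominator)
}

#' Detection-efficiency correction
#'
#' Rescales a population estimate by a detection-efficiency factor (default
#' 1.25, i.e. 1/0.8 for the 20% average miss rate of video counting due to
#' burial and coverage). Total, SE and mean scale together; no extra
#' uncertainty term is attached to the factor itself.
#'
#' @param est A `population_estimate`.
#' @param factor Multiplicative correction, > 0.
#' @return A corrected `population_estimate` with a provenance note.
#' @export
detection_correction <- function(est, factor = 1.25) {
  stopifnot(inherits(est, "population_estimate"))
  if (!is.finite(factor) || factor <= 0) {
    abort("correction factor must be positive", class = "seastrat_validation_error")
  }
  breakdown <- est$breakdown
  if (!is.null(breakdown)) {
    breakdown <- mutate(breakdown,
                        mean_density = .data$mean_density * factor,
                        var_density = .data$var_density * factor^2,
                        partial_total = .data$partial_total * factor,
                        partial_se = .data$partial_se * factor)
  }
  surveys <- est$surveys
  if (!is.null(surveys)) {
    surveys <- mutate(surveys,
                      mean_density = .data$mean_density * factor,
                      var_mean = .data$var_mean * factor^2,
                      total = .data$total * factor,
                      se_total = .data$se_total * factor)
  }
  out <- new_population_estimate(
    est$label, est$N_m2,
    mean_density = est$mean_density * factor,
    var_mean = est$var_mean * factor^2,
    breakdown = breakdown, surveys = surveys, which = est$which,
    notes = c(est$notes,
              sprintf("detection-efficiency correction x%.4g applied", factor))
  )
  out
}

#' Biomass from a population estimate
#'
#' Converts individuals to tonnes with a mean individual weight (default
#' 63 g per adult oyster): `tonnes = total * weight_g * 1e-6`. The SE scales
#' identically.
#'
#' @param est A `population_estimate`.
#' @param mean_weight_g Mean individual weight, grams.
#' @return A one-row tibble: `mean_weight_g`, `total_tonnes`, `se_tonnes`.
#' @export
biomass <- function(est, mean_weight_g = 63) {
  stopifnot(inherits(est, "population_estimate"))
  if (!is.finite(mean_weight_g) || mean_weight_g <= 0) {
    abort("mean weight must be positive", class = "seastrat_validation_error")
  }
  tibble(mean_weight_g = mean_weight_g,
         total_tonnes = est$total * mean_weight_g * 1e-6,
         se_tonnes = est$se_total * mean_weight_g * 1e-6)
}

#' Annual exploitation rate
#'
#' Annual removals as a percentage of the standing stock:
#' `100 * landings * multiplier / total`. The multiplier accommodates
#' scenarios such as unreported catch of the same magnitude as the licensed
#' one (`multiplier = 2`). Works on a `population_estimate` or directly on a
#' numeric stock size (in which case landings must be in the same units).
#'
#' @param est A `population_estimate`, or a positive number (stock size).
#' @param landings Annual removals, same units as the stock.
#' @param multiplier Scenario multiplier on the landings.
#' @return A one-row tibble: `landings`, `multiplier`, `stock`,
#'   `rate_percent`.
#' @export
exploitation_rate <- function(est, landings = 88000, multiplier = 1) {
  stock <- if (inherits(est, "population_estimate")) est$total else est
  if (!is.finite(stock) || stock <= 0) {
    abort("stock size must be positive", class = "seastrat_validation_error")
  }
  if (landings < 0 || multiplier < 0) {
    abort("landings and multiplier must be non-negative",
          class = "seastrat_validation_error")
  }
  tibble(landings = landings, multiplier = multiplier, stock = stock,
         rate_percent = 100 * landings * multiplier / stock)
}

# built-in suitability predicates
suitability_predicates <- list(
  living_or_dead_present = function(sites) {
    sites$living_count + sites$dead_count >= 1
  },
  mobile_majority = function(sites) {
    needed <- c("sub_mud", "sub_sand", "sub_gravel", "sub_shell", "sub_rock")
    missing <- setdiff(needed, names(sites))
    if (length(missing) > 0) {
      abort(paste0("mobile_majority predicate needs cover column(s): ",
                   paste(missing, collapse = ", ")),
            class = "seastrat_schema_error")
    }
    (sites$sub_mud + sites$sub_sand + sites$sub_gravel + sites$sub_shell) >
      sites$sub_rock
  }
)

#' Habitat-restricted population estimate
#'
#' Re-estimates the population under an assumption about which sites are
#' suitable habitat. Per stratum, the suitable area is estimated as
#' `A_hat = (k/n) * A` (k of n sampled sites suitable) and the density over
#' suitable sites only; the partial total is `A_hat * mean(density | suitable)`
#' with SE `A_hat * sqrt(var(density | suitable) / k)`. Strata with no
#' suitable site contribute zero. When every site is suitable — or whenever
#' all sites with non-zero density are suitable — the total coincides with
#' the unrestricted estimator, since `(k/n) A (sum d / k) = A (sum d / n)`.
#'
#' @inheritParams stratum_estimates
#' @param suitable A built-in predicate name (`"living_or_dead_present"` or
#'   `"mobile_majority"`), a function mapping the site tibble to a logical
#'   vector, or a logical vector of length `nrow(sites)`.
#' @param on_single What to do with a stratum holding exactly one suitable
#'   site (its variance is undefined): `"error"` (default) or `"drop"`
#'   (exclude the stratum, i.e. treat it as contributing no suitable area).
#' @param label Label for the resulting estimate.
#' @return A `population_estimate` over the estimated suitable area.
#' @export
habitat_restricted_estimate <- function(sites, frame,
                                        suitable = "living_or_dead_present",
                                        which = c("living", "dead"),
                                        on_single = c("error", "drop"),
                                        allow_missing_strata = FALSE,
                                        label = "habitat-restricted") {
  which <- rlang::arg_match(which)
  on_single <- rlang::arg_match(on_single)
  frame <- as_frame(frame)
  flag <- if (is.character(suitable)) {
    pred <- suitability_predicates[[suitable]]
    if (is.null(pred)) {
      abort(paste0("unknown suitability predicate: ", suitable,
                   " (built-ins: ",
                   paste(names(suitability_predicates), collapse = ", "), ")"))
    }
    pred(sites)
  } else if (is.function(suitable)) {
    suitable(sites)
  } else {
    as.logical(suitable)
  }
  if (length(flag) != nrow(sites) || anyNA(flag)) {
    abort("suitability must evaluate to one non-missing logical per site",
          class = "seastrat_validation_error")
  }

  dens <- mutate(site_density(sites, which), .suitable = flag)
  per <- dens |>
    group_by(.data$area_label, .data$depth_label) |>
    summarise(n_sites = dplyr::n(),
              k_suitable = sum(.data$.suitable),
              mean_suit = if (sum(.data$.suitable) > 0)
                mean(.data$density[.data$.suitable]) else 0,
              var_suit = if (sum(.data$.suitable) > 1)
                var(.data$density[.data$.suitable]) else 0,
              .groups = "drop")
  out <- left_join(frame, per, by = c("area_label", "depth_label"))
  empty <- is.na(out$n_sites)
  if (any(empty)) {
    if (!allow_missing_strata) {
      abort(paste0("frame cell(s) with no sampled sites: ",
                   paste(paste(out$area_label[empty], out$depth_label[empty],
                               sep = " / "), collapse = "; ")),
            class = "seastrat_missing_stratum_error")
    }
    out <- out[!empty, , drop = FALSE]
  }
  single <- out$k_suitable == 1
  if (any(single)) {
    labels <- paste(out$area_label[single], out$depth_label[single], sep = " / ")
    if (on_single == "error") {
      abort(paste0("stratum with a single suitable site (variance undefined): ",
                   paste(labels, collapse = "; "),
                   " (use on_single = \"drop\" to exclude)"),
            class = "seastrat_validation_error")
    }
    out$k_suitable[single] <- 0L
    out$mean_suit[single] <- 0
    out$var_suit[single] <- 0
  }
  out <- out |>
    mutate(suitable_area_m2 = (.data$k_suitable / .data$n_sites) *
             .data$areal_extent_m2,
           partial_total = .data$suitable_area_m2 * .data$mean_suit,
           partial_se = ifelse(.data$k_suitable > 0,
                               .data$suitable_area_m2 *
                                 sqrt(.data$var_suit / pmax(.data$k_suitable, 1)),
                               0))
  N_hat <- sum(out$suitable_area_m2)
  total <- sum(out$partial_total)
  var_total <- sum(out$partial_se^2)
  if (N_hat <= 0) {
    abort("no suitable area under this predicate",
          class = "seastrat_validation_error")
  }
  breakdown <- out |>
    mutate(mean_density = .data$mean_suit, var_density = .data$var_suit,
           weight = .data$suitable_area_m2 / N_hat) |>
    select(all_of(c("survey_id", "area_label", "depth_label", "n_sites",
                    "k_suitable", "suitable_area_m2", "weight", "mean_density",
                    "var_density", "partial_total", "partial_se")))
  new_population_estimate(
    label, N_hat, mean_density = total / N_hat, var_mean = var_total / N_hat^2,
    breakdown = breakdown, which = which,
    notes = sprintf("habitat-restricted: suitable area estimated from %d of %d sites",
                    sum(out$k_suitable), sum(out$n_sites))
  )
}
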