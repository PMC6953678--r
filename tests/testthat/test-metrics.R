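# Derived stock metrics: occurrence, living ratio, concentration curve,
# bed share, correction, biomass, exploitation, habitat restriction.

make_transects <- function(counts, length_m = 20, frame_width_m = 0.8) {
  tibble::tibble(site_id = paste0("t", seq_along(counts)),
                 transect_index = 1L, length_m = length_m,
                 frame_width_m = frame_width_m,
                 living_count = counts, dead_count = 0)
}

test_that("occurrence frequency uses the binomial SE", {
  sites <- dplyr::bind_rows(
    valid_site_row("a", living = 3), valid_site_row("b", living = 0),
    valid_site_row("c", living = 0), valid_site_row("d", living = 1))
  p <- occurrence_frequency(sites)
  expect_equal(p$proportion, 0.5)
  expect_equal(p$se, 0.25)
  none <- occurrence_frequency(dplyr::mutate(sites, living_count = 0))
  expect_equal(none$proportion, 0)
  expect_equal(none$se, 0)
  all_p <- occurrence_frequency(dplyr::mutate(sites, living_count = 2))
  expect_equal(all_p$proportion, 1)
  expect_equal(all_p$se, 0)
})

test_that("duplicating every site keeps p and shrinks its SE by sqrt(2)", {
  sites <- dplyr::bind_rows(
    valid_site_row("a", living = 3), valid_site_row("b", living = 0),
    valid_site_row("c", living = 0), valid_site_row("d", living = 1))
  p1 <- occurrence_frequency(sites)
  p2 <- occurrence_frequency(dplyr::bind_rows(sites, sites))
  expect_equal(p2$proportion, p1$proportion)
  expect_equal(p2$se, p1$se / sqrt(2))
})

test_that("living ratio averages per-site ratios over occupied sites only", {
  sites <- dplyr::bind_rows(
    valid_site_row("a", living = 4, dead = 0),   # ratio 1
    valid_site_row("b", living = 2, dead = 2),   # ratio 0.5
    valid_site_row("c", living = 0, dead = 0))   # not qualifying
  lr <- living_ratio(sites)
  expect_equal(lr$mean_ratio, 0.75)
  expect_equal(lr$n_sites, 2)
  all_dead <- living_ratio(dplyr::mutate(sites, living_count = 0,
                                         dead_count = 3))
  expect_equal(all_dead$mean_ratio, 0)
  all_living <- living_ratio(dplyr::mutate(sites, living_count = 3,
                                           dead_count = 0))
  expect_equal(all_living$mean_ratio, 1)
  empty <- living_ratio(dplyr::mutate(sites, living_count = 0, dead_count = 0))
  expect_true(is.na(empty$mean_ratio))
})

test_that("the cumulative curve sorts by density and accumulates counts", {
  tr <- make_transects(c(0, 8, 16, 160))
  curve <- cumulative_density_curve(tr)
  expect_equal(curve$density, c(0, 0.5, 1, 10))
  expect_equal(curve$cum_fraction, c(0, 8, 24, 184) / 184)
  # permutation invariance and monotonicity
  curve2 <- cumulative_density_curve(tr[c(3, 1, 4, 2), ])
  expect_equal(curve2$density, curve$density)
  expect_equal(curve2$cum_fraction, curve$cum_fraction)
  expect_true(all(diff(curve$cum_fraction) >= 0))
  expect_equal(curve$cum_fraction[nrow(curve)], 1)
  single <- cumulative_density_curve(make_transects(5))
  expect_equal(single$cum_fraction, 1)
  expect_error(cumulative_density_curve(make_transects(c(0, 0))),
               "undefined", class = "seastrat_validation_error")
})

test_that("bed share splits the population at the density threshold", {
  curve <- cumulative_density_curve(make_transects(c(0, 8, 16, 160)))
  b <- bed_share(curve, 5)
  expect_equal(b$population_share, 160 / 184)
  expect_equal(bed_share(curve, 0)$population_share, 1)
  expect_equal(bed_share(curve, 100)$population_share, 0)
  # non-increasing in the threshold
  shares <- vapply(c(0, 0.5, 1, 5, 11),
                   function(t) bed_share(curve, t)$population_share, 1)
  expect_true(all(diff(shares) <= 0))
  # unit share denominators: 3 of 4 transects hold oysters
  expect_equal(bed_share(curve, 5, "nonzero")$unit_share, 1 / 3)
  expect_equal(bed_share(curve, 5, "all")$unit_share, 1 / 4)
})

test_that("detection correction rescales the whole estimate linearly", {
  est <- population_total(3.2, 0.34, 1e6)
  up <- detection_correction(est, 1.25)
  expect_equal(up$total, est$total * 1.25)
  expect_equal(up$se_total, est$se_total * 1.25)
  expect_equal(up$mean_density, est$mean_density * 1.25)
  expect_equal(detection_correction(est, 1)$total, est$total)
  round_trip <- detection_correction(detection_correction(est, 1 / 0.8), 0.8)
  expect_equal(round_trip$total, est$total)
  expect_error(detection_correction(est, 0),
               class = "seastrat_validation_error")
})

test_that("biomass conversion is exactly linear in weight and abundance", {
  est <- population_total(36.56e6 / 151.96e6, (16.29e6 / 151.96e6)^2, 151.96e6)
  b <- biomass(est, 63)
  expect_equal(b$total_tonnes, 36.56e6 * 63 * 1e-6)
  expect_equal(b$se_tonnes, 16.29e6 * 63 * 1e-6)
  expect_equal(biomass(population_total(0, 0, 1), 63)$total_tonnes, 0)
  double_weight <- biomass(est, 126)
  expect_equal(double_weight$total_tonnes, 2 * b$total_tonnes)
})

test_that("exploitation rate is landings over stock in percent", {
  est <- population_total(36.56e6 / 151.96e6, 0, 151.96e6)
  expect_equal(exploitation_rate(est, 88000)$rate_percent,
               100 * 88000 / 36.56e6)
  expect_equal(exploitation_rate(est, 88000, multiplier = 2)$rate_percent,
               2 * 100 * 88000 / 36.56e6)
  expect_equal(exploitation_rate(est, 0)$rate_percent, 0)
  expect_equal(exploitation_rate(2648, 450)$rate_percent, 100 * 450 / 2648)
  expect_error(exploitation_rate(0, 10), class = "seastrat_validation_error")
})

test_that("habitat restriction estimates suitable area and density jointly", {
  frame <- as_frame(tibble::tibble(area_label = "A 1", depth_label = "0.5-3",
                                   areal_extent_km2 = 100 / 1e6,
                                   survey_id = "s"))
  sites <- sites_from_densities(c(0, 0, 4, 2), area = "A 1")
  est <- habitat_restricted_estimate(sites, frame,
                                     suitable = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(est$N_m2, 50)
  expect_equal(est$mean_density, 3)
  expect_equal(est$total, 150)
})

test_that("habitat restriction reduces to the unrestricted estimator", {
  sim <- simulate_survey(seed = 21, n_per_stratum = 10, transects = FALSE)
  unrestricted <- estimate_population(sim$sites, skagerrak_frame())
  all_suitable <- habitat_restricted_estimate(
    sim$sites, skagerrak_frame(), suitable = rep(TRUE, nrow(sim$sites)))
  expect_equal(all_suitable$total, unrestricted$total)
  expect_equal(all_suitable$se_total, unrestricted$se_total)
  expect_equal(all_suitable$N_m2, unrestricted$N_m2)

  # totals also agree whenever every non-zero-density site is suitable
  flags <- sim$sites$living_count > 0 | seq_len(nrow(sim$sites)) %% 2 == 0
  some <- habitat_restricted_estimate(sim$sites, skagerrak_frame(),
                                      suitable = flags, on_single = "drop")
  expect_equal(some$total, unrestricted$total)
})

test_that("built-in predicates flag habitat by occurrence and substrate", {
  sim <- simulate_survey(seed = 31, n_per_stratum = 30, transects = FALSE)
  occ <- habitat_restricted_estimate(sim$sites, skagerrak_frame(),
                                     "living_or_dead_present",
                                     on_single = "drop")
  unrestricted <- estimate_population(sim$sites, skagerrak_frame())
  # occurrence-based restriction preserves the total by construction
  expect_equal(occ$total, unrestricted$total, tolerance = 1e-9)
  expect_lt(occ$N_m2, unrestricted$N_m2)
  mob <- habitat_restricted_estimate(sim$sites, skagerrak_frame(),
                                     "mobile_majority", on_single = "drop")
  expect_true(mob$total > 0)
  expect_error(habitat_restricted_estimate(sim$sites, skagerrak_frame(),
                                           "unknown_predicate"),
               "unknown suitability")
})

test_that("a single suitable site in a stratum is an error unless dropped", {
  frame <- toy_frame(extents_km2 = 1, areas = "A 1")
  sites <- sites_from_densities(c(0, 1, 2), area = "A 1")
  expect_error(habitat_restricted_estimate(sites, frame,
                                           suitable = c(FALSE, FALSE, TRUE)),
               "single suitable", class = "seastrat_validation_error")
  dropped <- habitat_restricted_estimate(sites, frame,
                                         suitable = c(TRUE, TRUE, FALSE),
                                         on_single = "drop")
  expect_equal(dropped$mean_density, 0.5)
})
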