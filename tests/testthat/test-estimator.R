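# Stratified estimation core: per-stratum moments, areal weighting,
# totals +- SE, survey combination, and the brute-force oracle check.

test_that("per-stratum mean and unbiased variance match hand arithmetic", {
  frame <- toy_frame(extents_km2 = 1, areas = "A 1")
  est <- stratum_estimates(sites_from_densities(c(0, 0, 3, 1)), frame)
  expect_equal(est$mean_density, 1)
  expect_equal(est$var_density, 2)
  expect_equal(est$var_density / est$n_sites, 0.5)

  const <- stratum_estimates(sites_from_densities(c(4, 4, 4)), frame)
  expect_equal(const$mean_density, 4)
  expect_equal(const$var_density, 0)
  zero <- stratum_estimates(sites_from_densities(c(0, 0)), frame)
  expect_equal(zero$mean_density, 0)
  expect_equal(zero$var_density, 0)
})

test_that("a stratum with fewer than two sites is refused", {
  frame <- toy_frame(extents_km2 = 1, areas = "A 1")
  expect_error(stratum_estimates(sites_from_densities(3), frame),
               "variance undefined", class = "seastrat_validation_error")
})

test_that("stratified mean and variance apply areal weights", {
  est <- tibble::tibble(
    survey_id = "s1", area_label = c("A 1", "A 2"), depth_label = "0.5-3",
    areal_extent_m2 = c(0.6e6, 0.4e6), n_sites = c(1, 1),
    mean_density = c(2, 5), var_density = c(0.5, 1.0)
  )
  expect_equal(stratified_mean(est)$mean_density, 0.6 * 2 + 0.4 * 5)
  expect_equal(stratified_variance(est)$var_mean,
               0.36 * 0.5 + 0.16 * 1.0)
  # permutation invariance and the single-stratum identity
  expect_equal(stratified_mean(est[2:1, ])$mean_density, 3.2)
  one <- est[1, ]
  expect_equal(stratified_mean(one)$mean_density, 2)
  expect_equal(stratified_variance(one)$var_mean, 0.5 / 1)
})

test_that("population totals scale mean and SE by the areal extent", {
  est <- population_total(3.2, 0.34, 1e6)
  expect_equal(est$total, 3.2e6)
  expect_equal(est$se_total, sqrt(0.34) * 1e6)
  # linearity in N
  est2 <- population_total(3.2, 0.34, 2e6)
  expect_equal(est2$total, 2 * est$total)
  expect_equal(est2$se_total, 2 * est$se_total)
  expect_equal(population_total(0, 0, 1e6)$total, 0)
  expect_error(population_total(1, -0.1, 1e6),
               class = "seastrat_validation_error")
})

test_that("independent surveys combine by sums and root-sum-of-squares", {
  koster <- population_total(2.89e6 / 21.26e6, (1.00e6 / 21.26e6)^2,
                             21.26e6, label = "koster")
  coastal <- population_total(33.67e6 / 130.70e6, (16.26e6 / 130.70e6)^2,
                              130.70e6, label = "coastal")
  comb <- combine_surveys(list(koster, coastal))
  expect_equal(comb$total, 36.56e6)
  expect_equal(comb$se_total, sqrt(1.00^2 + 16.26^2) * 1e6)
  expect_equal(comb$N_m2, 151.96e6)
  # order invariance, identity, zero-survey neutrality
  comb2 <- combine_surveys(list(coastal, koster))
  expect_equal(comb2$total, comb$total)
  expect_equal(comb2$se_total, comb$se_total)
  single <- combine_surveys(list(koster))
  expect_equal(single$total, koster$total)
  zero <- population_total(0, 0, 1, label = "empty")
  comb3 <- combine_surveys(list(koster, coastal, zero))
  expect_equal(comb3$total, comb$total)
  expect_equal(comb3$se_total, comb$se_total)
  expect_error(combine_surveys(list(koster, koster)), "duplicate",
               class = "seastrat_validation_error")
})

test_that("weights sum to one per domain and the mean is a convex combination", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instance()
    est <- stratum_estimates(inst$sites, inst$frame)
    w <- est |>
      dplyr::group_by(survey_id) |>
      dplyr::mutate(w = areal_extent_m2 / sum(areal_extent_m2)) |>
      dplyr::summarise(sw = sum(w))
    expect_equal(w$sw, rep(1, nrow(w)), tolerance = 1e-12)
    sm <- stratified_mean(est)
    rng <- est |>
      dplyr::group_by(survey_id) |>
      dplyr::summarise(lo = min(mean_density), hi = max(mean_density))
    expect_true(all(sm$mean_density >= rng$lo - 1e-12 &
                    sm$mean_density <= rng$hi + 1e-12))
  }
})

test_that("the pipeline matches an independent brute-force computation", {
  set.seed(91)
  for (i in 1:100) {
    inst <- random_instance()
    est <- estimate_population(inst$sites, inst$frame)
    oracle <- oracle_estimate(inst$strata)
    expect_equal(est$total, oracle$total, tolerance = 1e-12)
    expect_equal(est$se_total, oracle$se_total, tolerance = 1e-12)
    expect_equal(est$N_m2, oracle$N, tolerance = 1e-12)
    # breakdown partials add up to the combined total
    expect_equal(sum(est$breakdown$partial_total), est$total,
                 tolerance = 1e-9)
  }
})

test_that("doubling every stratum's n halves the variance of the mean", {
  est <- tibble::tibble(
    survey_id = "s1", area_label = c("A 1", "A 2"), depth_label = "0.5-3",
    areal_extent_m2 = c(0.6e6, 0.4e6), n_sites = c(4, 8),
    mean_density = c(2, 5), var_density = c(0.5, 1.0)
  )
  v1 <- stratified_variance(est)$var_mean
  est2 <- dplyr::mutate(est, n_sites = n_sites * 2)
  expect_equal(stratified_variance(est2)$var_mean, v1 / 2)
  expect_true(v1 >= 0)
})

test_that("an unsampled frame cell is an error unless explicitly excluded", {
  frame <- toy_frame(extents_km2 = c(1, 2), areas = c("A 1", "A 2"))
  sites <- sites_from_densities(c(1, 2, 3), area = "A 1")
  expect_error(estimate_population(sites, frame), "no sampled sites",
               class = "seastrat_missing_stratum_error")
  est <- estimate_population(sites, frame, allow_missing_strata = TRUE)
  expect_equal(est$N_m2, 1e6)  # the empty cell leaves weights and N
  expect_equal(est$total, 2 * 1e6)
})

test_that("shuffling input rows leaves the estimate unchanged", {
  sim <- simulate_survey(seed = 5, n_per_stratum = 6, transects = FALSE)
  est <- estimate_population(sim$sites, skagerrak_frame())
  shuffled <- sim$sites[sample.int(nrow(sim$sites)), ]
  est2 <- estimate_population(shuffled, skagerrak_frame())
  expect_equal(est2$total, est$total)
  expect_equal(est2$se_total, est$se_total)
})

test_that("census with perfect detection recovers the true total exactly", {
  cfg <- sim_config(detection_efficiency = 1, undetectable_fraction = 0,
                    cells_per_stratum = 40)
  pop <- generate_population(cfg, seed = 8)
  survey <- generate_survey(pop, n_per_stratum = 40, expectation = TRUE,
                            transects = FALSE)
  est <- estimate_population(survey$sites, skagerrak_frame())
  expect_equal(est$total, pop$true_total_living, tolerance = 1e-9)
  dead <- estimate_population(survey$sites, skagerrak_frame(), which = "dead")
  expect_equal(dead$total, pop$true_total_dead, tolerance = 1e-9)
})

test_that("an all-zero survey yields a zero total with zero SE", {
  cfg <- sim_config(occupancy = 0, dead_only_occupancy = 0,
                    cells_per_stratum = 10)
  pop <- generate_population(cfg, seed = 2)
  survey <- generate_survey(pop, n_per_stratum = 5, transects = FALSE)
  est <- estimate_population(survey$sites, skagerrak_frame())
  expect_equal(est$total, 0)
  expect_equal(est$se_total, 0)
})

test_that("tidy and glance expose the breakdown and the headline numbers", {
  sim <- simulate_survey(seed = 3, n_per_stratum = 5, transects = FALSE)
  est <- estimate_population(sim$sites, skagerrak_frame())
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 15)
  gl <- glance(est)
  expect_equal(gl$total, est$total)
  expect_equal(gl$se_total, est$se_total)
  grid <- estimate_grid(est)
  expect_equal(grid$total[grid$survey_id == "combined"],
               round(est$total / 1e6, 2))
})
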