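# Builders for small in-memory fixtures and an independent brute-force
# oracle for the stratified estimator.

toy_frame <- function(extents_km2 = c(0.6, 0.4),
                      areas = paste("A", seq_along(extents_km2)),
                      depths = rep("0.5-3", length(extents_km2)),
                      survey = "s1") {
  as_frame(tibble::tibble(
    area_label = areas, depth_label = depths,
    areal_extent_km2 = extents_km2, survey_id = survey
  ))
}

# one stratum's sites from target densities (filmed area 1 m2 so density
# equals the stored count; counts need not be integers here because the
# estimator consumes densities)
sites_from_densities <- function(densities, area = "A 1", depth = "0.5-3",
                                 filmed = 1) {
  tibble::tibble(
    site_id = paste0(area, "-", seq_along(densities)),
    area_label = area, depth_label = depth,
    n_transects = 2L, filmed_area_m2 = filmed,
    living_count = densities * filmed, dead_count = 0,
    rocky_absent = FALSE
  )
}

valid_site_row <- function(site_id = "s1", area = "Area 1", depth = "0.5-3",
                           living = 0, dead = 0, filmed = 32,
                           rocky = FALSE, n_transects = 2L) {
  tibble::tibble(
    site_id = site_id, area_label = area, depth_label = depth,
    n_transects = n_transects, filmed_area_m2 = filmed,
    living_count = living, dead_count = dead, rocky_absent = rocky
  )
}

# Brute-force stratified estimator: explicit loops, no shared code with the
# package. `strata` is a list of lists with fields survey, A (m2), dens
# (site densities).
oracle_estimate <- function(strata) {
  surveys <- unique(vapply(strata, function(s) s$survey, character(1)))
  total <- 0
  var_total <- 0
  N_all <- 0
  for (sv in surveys) {
    in_sv <- Filter(function(s) s$survey == sv, strata)
    A_sum <- 0
    for (s in in_sv) A_sum <- A_sum + s$A
    mean_sv <- 0
    v_sv <- 0
    for (s in in_sv) {
      W <- s$A / A_sum
      n <- length(s$dens)
      m <- sum(s$dens) / n
      s2 <- sum((s$dens - m)^2) / (n - 1)
      mean_sv <- mean_sv + W * m
      v_sv <- v_sv + W^2 * s2 / n
    }
    total <- total + mean_sv * A_sum
    var_total <- var_total + v_sv * A_sum^2
    N_all <- N_all + A_sum
  }
  list(total = total, se_total = sqrt(var_total), N = N_all)
}

# random small stratified instance + the site/frame tables it maps to
random_instance <- function() {
  n_surveys <- sample(1:2, 1)
  strata <- list()
  frame_rows <- list()
  site_rows <- list()
  idx <- 0
  for (sv in seq_len(n_surveys)) {
    n_strata <- sample(1:4, 1)
    for (st in seq_len(n_strata)) {
      idx <- idx + 1
      dens <- round(stats::rexp(sample(2:10, 1), rate = 1 / 2), 3)
      area <- paste0("A", idx)
      depth <- sample(depth_bands(), 1)
      A_km2 <- round(stats::runif(1, 0.1, 20), 3)
      strata[[idx]] <- list(survey = paste0("s", sv), A = A_km2 * 1e6,
                            dens = dens)
      frame_rows[[idx]] <- tibble::tibble(
        area_label = area, depth_label = depth,
        areal_extent_km2 = A_km2, survey_id = paste0("s", sv))
      site_rows[[idx]] <- sites_from_densities(dens, area = area, depth = depth)
    }
  }
  list(strata = strata,
       frame = as_frame(dplyr::bind_rows(frame_rows)),
       sites = dplyr::bind_rows(site_rows))
}
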