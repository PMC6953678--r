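# Site and transect tables: reading, validation, densities.

SITE_COLS <- c("site_id", "area_label", "depth_label", "n_transects",
               "filmed_area_m2", "living_count", "dead_count", "rocky_absent")
COVER_COLS <- c("sub_mud", "sub_sand", "sub_gravel", "sub_shell", "sub_rock",
                "veg_cover")
TRANSECT_COLS <- c("site_id", "transect_index", "length_m", "frame_width_m",
                   "living_count", "dead_count")

#' Validate a site table
#'
#' Checks each row of a site table against the survey-data contract: counts
#' are non-negative integers; a non-rocky site has a positive filmed area;
#' a rocky site recorded absent by visual inspection carries no transects and
#' its counts are forced to zero (it remains a density-zero member of the
#' population of sites); optional substrate/vegetation cover fractions lie in
#' \[0, 1\]; and, when a frame is supplied, every row maps onto a known
#' (area, depth) stratum.
#'
#' @param sites A data frame with at least the columns
#'   `site_id, area_label, depth_label, n_transects, filmed_area_m2,
#'   living_count, dead_count, rocky_absent`. Optional cover columns:
#'   `sub_mud, sub_sand, sub_gravel, sub_shell, sub_rock, veg_cover`.
#' @param frame Optional frame tibble; rows referencing unknown strata are
#'   rejected.
#' @return The accepted rows as a tibble, with a `validation` attribute: a
#'   list with `n_accepted`, `n_rejected` and a `rejects` tibble
#'   (`row`, `site_id`, `reason`). Retrieve it with [site_validation()].
#' @export
validate_sites <- function(sites, frame = NULL) {
  missing <- setdiff(SITE_COLS, names(sites))
  if (length(missing) > 0) {
    abort(paste0("site table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seastrat_schema_error")
  }
  sites <- as_tibble(sites)
  # normalise storage types so a written-and-reread table compares identical
  sites$site_id <- as.character(sites$site_id)
  sites$area_label <- as.character(sites$area_label)
  sites$depth_label <- as.character(sites$depth_label)
  sites$n_transects <- as.integer(sites$n_transects)
  sites$filmed_area_m2 <- as.numeric(sites$filmed_area_m2)
  sites$living_count <- as.numeric(sites$living_count)
  sites$dead_count <- as.numeric(sites$dead_count)
  sites$rocky_absent <- as.logical(sites$rocky_absent)
  sites$rocky_absent[is.na(sites$rocky_absent)] <- FALSE

  # rocky convention before row checks: counts are forced to 0, no filmed area
  rocky <- sites$rocky_absent
  sites$living_count[rocky] <- 0
  sites$dead_count[rocky] <- 0

  reasons <- vector("list", nrow(sites))
  add_reason <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  bad_count <- function(x) {
    !is.finite(x) | x < 0 | (x != floor(x))
  }
  add_reason(bad_count(sites$living_count), "living_count not a non-negative integer")
  add_reason(bad_count(sites$dead_count), "dead_count not a non-negative integer")
  add_reason(!rocky & (!is.finite(sites$filmed_area_m2) | sites$filmed_area_m2 <= 0),
             "filmed_area_m2 not positive on a filmed site")
  add_reason(is.na(sites$site_id), "missing site_id")
  for (col in intersect(COVER_COLS, names(sites))) {
    x <- sites[[col]]
    add_reason(!is.na(x) & (x < 0 | x > 1), paste0(col, " outside [0, 1]"))
  }
  if (!is.null(frame)) {
    known <- paste(frame$area_label, frame$depth_label, sep = "\r")
    here <- paste(sites$area_label, sites$depth_label, sep = "\r")
    add_reason(!(here %in% known), "unknown stratum (area_label, depth_label)")
  }

  bad <- !vapply(reasons, is.null, logical(1))
  rejects <- tibble(
    row = which(bad),
    site_id = as.character(sites$site_id[bad]),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; ")
  )
  accepted <- sites[!bad, , drop = FALSE]
  attr(accepted, "validation") <- list(
    n_accepted = nrow(accepted), n_rejected = nrow(rejects), rejects = rejects
  )
  accepted
}

#' Retrieve the validation report attached to a site table
#'
#' @param sites A tibble returned by [validate_sites()] or [read_sites()].
#' @return A list with `n_accepted`, `n_rejected` and a `rejects` tibble.
#' @export
site_validation <- function(sites) {
  attr(sites, "validation") %||%
    list(n_accepted = nrow(sites), n_rejected = 0L,
         rejects = tibble(row = integer(), site_id = character(),
                          reason = character()))
}

#' Read a site table from CSV
#'
#' Comma-separated, UTF-8, header required. See [validate_sites()] for the
#' column contract and the validation report.
#'
#' @inheritParams validate_sites
#' @param path Path to a CSV file.
#' @return A validated site tibble with a `validation` attribute.
#' @export
read_sites <- function(path, frame = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sites(raw, frame = frame)
}

#' Write a site table to CSV
#'
#' @param sites A site tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  readr::write_csv(sites, path, progress = FALSE)
  invisible(path)
}

#' Read a transect table from CSV
#'
#' @param path Path to a CSV with columns
#'   `site_id, transect_index, length_m, frame_width_m, living_count,
#'   dead_count`.
#' @return A tibble.
#' @export
read_transects <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TRANSECT_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("transect table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seastrat_schema_error")
  }
  if (any(raw$length_m <= 0) || any(raw$frame_width_m <= 0)) {
    abort("transect with non-positive swept dimensions",
          class = "seastrat_validation_error")
  }
  raw
}

#' Site-level density
#'
#' Adds a `density` column (individuals per m^2) to a site table:
#' `count / filmed_area_m2`, with rocky visually-inspected sites contributing
#' an exact zero. The site is the sampling unit: counts from a site's
#' transects are pooled over its total filmed area (nominally two 20 m x
#' 0.8 m transects, 32 m^2).
#'
#' @param sites A validated site tibble.
#' @param which `"living"` or `"dead"`.
#' @return `sites` with a `density` column.
#' @export
site_density <- function(sites, which = c("living", "dead")) {
  which <- rlang::arg_match(which)
  count <- sites[[paste0(which, "_count")]]
  rocky <- sites$rocky_absent %in% TRUE
  if (any(!rocky & (!is.finite(sites$filmed_area_m2) | sites$filmed_area_m2 <= 0))) {
    abort("filmed_area_m2 must be positive on filmed sites",
          class = "seastrat_validation_error")
  }
  d <- ifelse(rocky, 0, count / sites$filmed_area_m2)
  mutate(as_tibble(sites), density = as.numeric(d))
}

#' Transect-level density
#'
#' Adds a `density` column: `count / (length_m * frame_width_m)`. Transect
#' densities are the unit of the cumulative concentration curve
#' ([cumulative_density_curve()]); estimation itself pools to the site.
#'
#' @param transects A transect tibble.
#' @param which `"living"` or `"dead"`.
#' @return `transects` with a `density` column.
#' @export
transect_density <- function(transects, which = c("living", "dead")) {
  which <- rlang::arg_match(which)
  swept <- transects$length_m * transects$frame_width_m
  if (any(!is.finite(swept) | swept <= 0)) {
    abort("transect with zero or negative swept area",
          class = "seastrat_validation_error")
  }
  count <- transects[[paste0(which, "_count")]]
  mutate(as_tibble(transects), density = count / swept)
}

#' Filmed area of a site
#'
#' The nominal observation geometry: `n_transects` strips of `length_m` swept
#' at the camera frame width. Defaults give the standard 2 x 20 m x 0.8 m =
#' 32 m^2 per site.
#'
#' @param n_transects Number of transects per site.
#' @param length_m Transect length, m.
#' @param frame_width_m Across-track frame width, m.
#' @return Filmed area in m^2.
#' @export
site_filmed_area <- function(n_transects = 2, length_m = 20, frame_width_m = 0.8) {
  stopifnot(n_transects > 0, length_m > 0, frame_width_m > 0)
  n_transects * length_m * frame_width_m
}
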