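# Sampling frame: (area x depth-band) strata with known areal extents.

#' Depth bands used by the survey design
#'
#' The three depth bands of the sampling design. The shallowest band starts at
#' 0.5 m because the towed sled cannot operate shallower; its areal extent is
#' derived from the 0--3 m chart interval (see [load_strata()]).
#'
#' @return Character vector of the three depth-band labels.
#' @export
depth_bands <- function() c("0.5-3", "3-6", "6-10")

# fraction of the 0-3 m chart interval that lies above 0.5 m and is
# therefore excluded from the sampled frame
SHALLOW_CORRECTION <- 1 / 6

#' Validate and normalise a stratum frame
#'
#' A frame is a tibble with one row per (area, depth-band) stratum and columns
#' `area_label`, `depth_label`, `areal_extent_km2` and `survey_id` (the
#' independently planned survey that covers the cell). Validation enforces
#' positive extents, known depth bands and uniqueness of (area, depth) cells,
#' and adds `areal_extent_m2` (the only place km^2 are converted to m^2).
#'
#' @param frame A data frame with the columns above.
#' @return A validated tibble with an added `areal_extent_m2` column.
#' @export
as_frame <- function(frame) {
  required <- c("area_label", "depth_label", "areal_extent_km2", "survey_id")
  missing <- setdiff(required, names(frame))
  if (length(missing) > 0) {
    abort(paste0("frame is missing column(s): ", paste(missing, collapse = ", ")),
          class = "seastrat_schema_error")
  }
  frame <- as_tibble(frame)
  frame$area_label <- as.character(frame$area_label)
  frame$depth_label <- as.character(frame$depth_label)
  frame$survey_id <- as.character(frame$survey_id)

  bad_depth <- setdiff(unique(frame$depth_label), depth_bands())
  if (length(bad_depth) > 0) {
    abort(paste0("unknown depth band(s): ", paste(bad_depth, collapse = ", "),
                 " (expected ", paste(depth_bands(), collapse = ", "), ")"),
          class = "seastrat_validation_error")
  }
  if (any(!is.finite(frame$areal_extent_km2) | frame$areal_extent_km2 <= 0)) {
    bad <- frame[!is.finite(frame$areal_extent_km2) | frame$areal_extent_km2 <= 0, ]
    abort(paste0("non-positive areal extent for: ",
                 paste(paste(bad$area_label, bad$depth_label), collapse = "; ")),
          class = "seastrat_validation_error")
  }
  dup <- frame |>
    dplyr::count(.data$area_label, .data$depth_label) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate stratum cell(s): ",
                 paste(paste(dup$area_label, dup$depth_label), collapse = "; ")),
          class = "seastrat_validation_error")
  }
  frame$areal_extent_m2 <- frame$areal_extent_km2 * 1e6
  frame[c("survey_id", "area_label", "depth_label", "areal_extent_km2", "areal_extent_m2")]
}

#' Load a stratum frame from a YAML configuration
#'
#' The configuration holds a `strata` list of
#' `{area_label, depth_label, areal_extent_km2, survey_id}` entries, and an
#' optional top-level flag `shallow_area_correction`. When the flag is set,
#' entries for the shallowest band may instead give `raw_extent_0_3_km2`, the
#' 0--3 m chart-interval extent; the sampled 0.5--3 m extent is then computed
#' as `raw * (1 - 1/6)`, the convention used to exclude the un-navigable
#' 0--0.5 m sliver.
#'
#' @param path Path to a YAML file, or an already-parsed list of the same shape.
#' @return A validated frame tibble (see [as_frame()]).
#' @examples
#' frame <- load_strata(seastrat_example("skagerrak_strata.yaml"))
#' @export
load_strata <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$strata)) {
    abort("strata config has no 'strata' entry", class = "seastrat_schema_error")
  }
  correct <- isTRUE(cfg$shallow_area_correction)
  rows <- purrr::map(cfg$strata, function(s) {
    ext <- s$areal_extent_km2
    if (is.null(ext)) {
      if (correct && !is.null(s$raw_extent_0_3_km2) && identical(s$depth_label, "0.5-3")) {
        ext <- s$raw_extent_0_3_km2 * (1 - SHALLOW_CORRECTION)
      } else {
        abort(paste0("stratum ", s$area_label, " / ", s$depth_label,
                     " has no areal extent"), class = "seastrat_schema_error")
      }
    }
    tibble(area_label = s$area_label, depth_label = s$depth_label,
           areal_extent_km2 = ext,
           survey_id = s$survey_id %||% "survey")
  })
  as_frame(bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The Skagerrak flat-oyster sampling frame
#'
#' The stratified frame of the Swedish Skagerrak *Ostrea edulis* inventory:
#' five geographic areas (four coastal areas surveyed together, plus the
#' separately planned Koster archipelago survey) times three depth bands,
#' with the areal extent of each cell in km^2. Shallow-band extents already
#' include the 0.5 m lower-bound correction.
#'
#' @return A frame tibble (see [as_frame()]).
#' @export
skagerrak_frame <- function() {
  as_frame(tibble(
    area_label = rep(c("Area 1", "Area 2", "Area 3", "Area 4", "Koster"), each = 3),
    depth_label = rep(depth_bands(), times = 5),
    areal_extent_km2 = c(15.93, 6.37, 8.68,
                         13.35, 6.42, 10.42,
                         12.35, 6.78, 8.93,
                         20.65, 7.91, 12.91,
                         7.47, 5.86, 7.93),
    survey_id = rep(c("coastal", "coastal", "coastal", "coastal", "koster"), each = 3)
  ))
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; `NULL` lists
#'   the available files.
#' @return A file path (or a character vector of file names).
#' @export
seastrat_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "seastrat"))
  } else {
    path <- system.file("extdata", file, package = "seastrat")
    if (path == "") abort(paste0("no packaged example file '", file, "'"))
    path
  }
}
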