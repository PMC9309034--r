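#' Read a camera image table
#'
#' Reads the raw image-level CSV with columns
#' `site_id,species,datetime,n_adult_female,n_adult_male,n_fawn`
#' (ISO-8601 datetimes, UTF-8).
#'
#' @param path Path to a CSV file.
#' @return A tibble of image records.
#' @export
read_image_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      species = readr::col_character(),
      datetime = readr::col_character(),
      n_adult_female = readr::col_integer(),
      n_adult_male = readr::col_integer(),
      n_fawn = readr::col_integer()
    )
  )
}

parse_image_timestamps <- function(x) {
  if (inherits(x, "POSIXt")) return(lubridate::with_tz(x, "UTC"))
  parsed <- suppressWarnings(
    lubridate::ymd_hms(as.character(x), tz = "UTC", truncated = 1)
  )
  bad <- which(is.na(parsed) & !is.na(x))
  if (length(bad) > 0) {
    abort(
      sprintf("Unparseable datetime in image record(s): row %s (e.g. \"%s\").",
              paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]),
      class = "dielrisk_parse_error"
    )
  }
  parsed
}

validate_images <- function(images) {
  required <- c("site_id", "species", "datetime")
  missing <- setdiff(required, names(images))
  if (length(missing) > 0) {
    abort(paste0("Image table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dielrisk_parse_error")
  }
  for (col in c("n_adult_female", "n_adult_male", "n_fawn")) {
    if (!col %in% names(images)) images[[col]] <- 0L
    v <- images[[col]]
    if (any(is.na(v)) || any(v < 0)) {
      abort(sprintf("`%s` must be non-negative and non-missing.", col),
            class = "dielrisk_parse_error")
    }
  }
  bad_sp <- setdiff(unique(images$species), camera_species())
  if (length(bad_sp) > 0) {
    abort(paste0("Unknown species label(s): ", paste(bad_sp, collapse = ", "),
                 ". Allowed: ", paste(camera_species(), collapse = ", ")),
          class = "dielrisk_parse_error")
  }
  images$datetime <- parse_image_timestamps(images$datetime)
  images
}

#' Classify the deer demographic group of a detection
#'
#' At least one fawn present makes the detection a nursery group; otherwise an
#' adult female present makes it an adult-female detection; otherwise an adult
#' male present makes it an adult-male detection. Deer detections with no
#' classified individuals get `NA` (excluded from demographic analyses).
#'
#' @param n_adult_female,n_adult_male,n_fawn Non-negative integer counts
#'   (vectorized).
#' @return Character vector with values `"nursery_group"`, `"adult_female"`,
#'   `"adult_male"`, or `NA`.
#' @export
classify_deer_group <- function(n_adult_female, n_adult_male, n_fawn) {
  dplyr::case_when(
    n_fawn >= 1 ~ "nursery_group",
    n_adult_female >= 1 ~ "adult_female",
    n_adult_male >= 1 ~ "adult_male",
    TRUE ~ NA_character_
  )
}

#' Collapse camera images into independent detections
#'
#' Camera traps fire bursts of images; all images of one species at one site
#' separated by at most `gap_minutes` from the previous image belong to a
#' single detection (the gap rule chains, so a detection can span more than
#' `gap_minutes` in total). The detection keeps the first image's timestamp;
#' deer class counts within a detection are the per-image maxima, so a fawn on
#' any image makes the detection a nursery group.
#'
#' @param images Data frame of image records with columns `site_id`,
#'   `species`, `datetime` (`POSIXct` or ISO-8601 text) and, for deer, the
#'   count columns `n_adult_female`, `n_adult_male`, `n_fawn`.
#' @param gap_minutes Maximum inter-image gap (minutes) kept within one
#'   detection; a strictly larger gap starts a new detection. Default 15.
#' @return A tibble of detections with columns `site_id`, `species`, `group`
#'   (`NA` for unclassifiable deer), `timestamp`, `date`, `time_of_day_rad`,
#'   the event-level count maxima, and `n_images`.
#' @export
#' @examples
#' imgs <- tibble::tibble(
#'   site_id = "A", species = "deer",
#'   datetime = as.POSIXct("2019-07-20 06:00:00", tz = "UTC") + c(0, 300, 600),
#'   n_adult_female = c(1L, 1L, 0L), n_adult_male = 0L, n_fawn = c(0L, 2L, 1L)
#' )
#' collapse_detections(imgs)
collapse_detections <- function(images, gap_minutes = 15) {
  assert_scalar_number(gap_minutes, "gap_minutes", min = 0)
  if (nrow(images) == 0) {
    return(tibble(
      site_id = character(), species = character(), group = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      date = as.Date(character()), time_of_day_rad = numeric(),
      n_adult_female = integer(), n_adult_male = integer(),
      n_fawn = integer(), n_images = integer()
    ))
  }
  images <- validate_images(images)
  events <- images |>
    dplyr::arrange(.data$site_id, .data$species, .data$datetime) |>
    dplyr::group_by(.data$site_id, .data$species) |>
    dplyr::mutate(
      gap_min = as.numeric(difftime(.data$datetime,
                                    dplyr::lag(.data$datetime),
                                    units = "mins")),
      event_id = cumsum(is.na(.data$gap_min) | .data$gap_min > gap_minutes)
    ) |>
    dplyr::group_by(.data$site_id, .data$species, .data$event_id) |>
    dplyr::summarise(
      timestamp = dplyr::first(.data$datetime),
      n_adult_female = max(.data$n_adult_female),
      n_adult_male = max(.data$n_adult_male),
      n_fawn = max(.data$n_fawn),
      n_images = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      group = dplyr::if_else(
        .data$species == "deer",
        classify_deer_group(.data$n_adult_female, .data$n_adult_male,
                            .data$n_fawn),
        "not_deer"
      ),
      date = lubridate::as_date(.data$timestamp),
      time_of_day_rad = time_to_radians(.data$timestamp)
    ) |>
    dplyr::select(
      "site_id", "species", "group", "timestamp", "date", "time_of_day_rad",
      "n_adult_female", "n_adult_male", "n_fawn", "n_images"
    ) |>
    dplyr::arrange(.data$site_id, .data$species, .data$timestamp)
  events
}

#' Extract circular detection times for a species or demographic group
#'
#' Filters detections to one species and/or deer group (or a set of species,
#' e.g. the four carnivores pooled) and returns the time-of-day angles.
#'
#' @param events Detection tibble from [collapse_detections()].
#' @param species Optional character vector of species to keep.
#' @param group Optional character vector of deer groups to keep.
#' @return Numeric vector of radians in `[0, 2*pi)`, in the input order of the
#'   retained rows.
#' @export
to_circular_times <- function(events, species = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(species)) keep <- keep & events$species %in% species
  if (!is.null(group)) {
    keep <- keep & !is.na(events$group) & events$group %in% group
  }
  if (!any(keep)) {
    stop_empty_selection(paste(
      c(if (!is.null(species)) paste0("species=", paste(species, collapse = "/")),
        if (!is.null(group)) paste0("group=", paste(group, collapse = "/"))),
      collapse = ", "
    ))
  }
  wrap_circular(events$time_of_day_rad[keep])
}

#' Write a detection table to CSV
#'
#' @param events Detection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}
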