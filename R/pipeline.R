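# ---- end-to-end analysis orchestration ---------------------------------

#' Build an analysis configuration
#'
#' Bundles every tunable the pipeline uses, with the defaults of the summer
#' deer / multi-predator analysis: 15-minute detection gap, automatic von
#' Mises bandwidth on a 512-point grid, 1000-replicate percentile bootstrap,
#' and an 11-day moving window.
#'
#' @param images Image-record data frame or path to its CSV.
#' @param mortality Subject-history data frame or path to its CSV.
#' @param gap_minutes Detection-independence gap (minutes). Default 15.
#' @param kappa,adjust,grid_size Circular-KDE settings
#'   (see [fit_circular_kde()]).
#' @param estimator Overlap estimator policy (see [bootstrap_overlap()]).
#' @param n_boot Bootstrap replicates for overlap CIs; 0 skips the bootstrap
#'   (point estimates only). Default 1000.
#' @param conf Confidence level. Default 0.95.
#' @param window_start,window_end Moving-window centre range (`Date` or ISO
#'   text, `NULL` = derived from the data).
#' @param half_window_days Moving-window half width. Default 5.
#' @param min_window_n Minimum per-sample window size. Default 20.
#' @param seed Integer seed driving all resampling.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(images, mortality, gap_minutes = 15,
                            kappa = "auto", adjust = 1, grid_size = 512,
                            estimator = "auto", n_boot = 1000, conf = 0.95,
                            window_start = NULL, window_end = NULL,
                            half_window_days = 5, min_window_n = 20,
                            seed = 42) {
  if (is.character(images)) {
    if (!file.exists(images)) {
      abort(paste0("Image file not found: ", images),
            class = "dielrisk_config_error")
    }
    images <- read_image_csv(images)
  }
  if (is.character(mortality)) {
    if (!file.exists(mortality)) {
      abort(paste0("Mortality file not found: ", mortality),
            class = "dielrisk_config_error")
    }
    mortality <- read_mortality_csv(mortality)
  }
  assert_scalar_number(gap_minutes, "gap_minutes", min = 0)
  assert_scalar_number(n_boot, "n_boot", min = 0)
  structure(
    list(images = images, mortality = mortality, gap_minutes = gap_minutes,
         kappa = kappa, adjust = adjust, grid_size = grid_size,
         estimator = estimator, n_boot = n_boot, conf = conf,
         window_start = window_start, window_end = window_end,
         half_window_days = half_window_days, min_window_n = min_window_n,
         seed = seed),
    class = "analysis_config"
  )
}

overlap_row <- function(times_a, times_b, cfg, seed_offset) {
  if (cfg$n_boot >= 100) {
    est <- bootstrap_overlap(times_a, times_b, estimator = cfg$estimator,
                             n_boot = cfg$n_boot, conf = cfg$conf,
                             seed = cfg$seed + seed_offset,
                             kappa = cfg$kappa, adjust = cfg$adjust)
    tibble(delta = est$delta, ci_low = est$ci_low, ci_high = est$ci_high,
           method = est$method, n1 = est$n1, n2 = est$n2)
  } else {
    n1 <- length(times_a)
    n2 <- length(times_b)
    method <- resolve_estimator(cfg$estimator, n1, n2, quiet = TRUE)
    d <- delta_fun(method)(times_a, times_b, kappa = cfg$kappa,
                           adjust = cfg$adjust)
    tibble(delta = d, ci_low = NA_real_, ci_high = NA_real_,
           method = method, n1 = n1, n2 = n2)
  }
}

#' Run the full diel-risk analysis
#'
#' The complete chain: collapse images to independent detections and classify
#' deer groups; fit circular activity densities; estimate Delta-4 overlap
#' (with bootstrap CIs) between each risk source (four carnivores + humans)
#' and both deer demographic groupings (nursery groups vs fawn-free adult
#' deer); estimate cause-specific cumulative incidence for the fawn and adult
#' cohorts; convert incidences to proportional risk weights and build the
#' mortality-weighted diel risk index per stratum; compute the seasonal
#' moving-window deer-carnivore overlap; and derive the summary percentage
#' contrasts (per-species overlap reduction/increase of nursery groups
#' relative to adult deer, group-average overlaps, and the fawn:adult
#' mortality ratio).
#'
#' @param config An [analysis_config()].
#' @return A `dielrisk_report` list: `detections`, `densities`,
#'   `overlap_table`, `derived`, `cif` (list of `cif_set`), `cif_table`,
#'   `weights`, `risk_index`, `window`, `settings`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config

  detections <- collapse_detections(cfg$images, gap_minutes = cfg$gap_minutes)
  if (nrow(detections) == 0) {
    abort("[detections] no detections after collapsing.",
          class = "dielrisk_data_error")
  }

  groups <- list(
    nursery = list(species = "deer", group = "nursery_group"),
    adult = list(species = "deer", group = c("adult_female", "adult_male"))
  )
  sources <- risk_sources()
  source_species <- c(bear = "black_bear", bobcat = "bobcat",
                      coyote = "coyote", wolf = "wolf", human = "human")

  times <- list()
  for (g in names(groups)) {
    times[[g]] <- to_circular_times(detections, species = groups[[g]]$species,
                                    group = groups[[g]]$group)
  }
  for (s in sources) {
    times[[s]] <- to_circular_times(detections,
                                    species = source_species[[s]])
  }
  times$carnivores <- to_circular_times(detections,
                                        species = carnivore_species())

  densities <- purrr::imap(times, function(tt, nm) {
    suppressWarnings(fit_circular_kde(tt, kappa = cfg$kappa,
                                      grid_size = cfg$grid_size,
                                      adjust = cfg$adjust))
  })

  # Table-1-shaped overlap table: source x deer grouping
  combos <- tidyr::expand_grid(source = sources,
                               deer_group = names(groups))
  overlap_table <- combos |>
    dplyr::mutate(purrr::map2_dfr(
      .data$source, .data$deer_group,
      function(s, g) overlap_row(times[[g]], times[[s]], cfg,
                                 seed_offset = match(s, sources) * 10 +
                                   match(g, names(groups)))
    ))

  # competing-risks incidence and risk weights per stratum
  strata <- list(fawn = "fawn",
                 adult = c("adult", "adult_female", "adult_male"))
  cif <- list()
  weights <- list()
  risk_index <- list()
  for (st in names(strata)) {
    present <- intersect(strata[[st]], unique(cfg$mortality$stratum))
    if (length(present) == 0) next
    cif[[st]] <- aalen_johansen(cfg$mortality, stratum = present)
    ms <- mortality_summary(cif[[st]])
    attr(ms, "stratum") <- st
    weights[[st]] <- compute_risk_weights(ms)
    risk_index[[st]] <- compute_risk_index(densities[sources], weights[[st]])
  }
  cif_table <- dplyr::bind_rows(purrr::map(cif, tidy))

  window <- moving_window_overlap(
    dplyr::filter(detections, .data$species == "deer", !is.na(.data$group),
                  .data$group %in% deer_groups()),
    dplyr::filter(detections, .data$species %in% carnivore_species()),
    start_date = cfg$window_start, end_date = cfg$window_end,
    half_window_days = cfg$half_window_days, estimator = cfg$estimator,
    min_n = cfg$min_window_n, kappa = cfg$kappa, adjust = cfg$adjust
  )

  derived <- derive_contrasts(overlap_table, cif)

  structure(
    list(detections = detections, densities = densities,
         overlap_table = overlap_table, derived = derived, cif = cif,
         cif_table = cif_table, weights = weights, risk_index = risk_index,
         window = window,
         settings = cfg[setdiff(names(cfg), c("images", "mortality"))]),
    class = "dielrisk_report"
  )
}

# summary percentage contrasts from the overlap table and cohort CIFs
derive_contrasts <- function(overlap_table, cif = list()) {
  wide <- overlap_table |>
    dplyr::select("source", "deer_group", "delta") |>
    tidyr::pivot_wider(names_from = "deer_group", values_from = "delta")
  carn <- dplyr::filter(wide, .data$source != "human")
  hum <- dplyr::filter(wide, .data$source == "human")
  out <- dplyr::bind_rows(
    tibble(
      quantity = paste0("overlap_reduction_", carn$source, "_pct"),
      value = round_percent(relative_overlap_change(carn$nursery,
                                                    carn$adult,
                                                    "reduction"))
    ),
    tibble(
      quantity = "overlap_increase_human_pct",
      value = round_percent(relative_overlap_change(hum$nursery, hum$adult,
                                                    "increase"))
    ),
    tibble(
      quantity = c("mean_overlap_nursery_pct", "mean_overlap_adult_pct"),
      value = round_percent(100 * c(mean(wide$nursery), mean(wide$adult)))
    ),
    tibble(
      quantity = c("mean_overlap_nursery", "mean_overlap_adult"),
      value = c(mean(wide$nursery), mean(wide$adult))
    )
  )
  if (all(c("fawn", "adult") %in% names(cif))) {
    fawn_tot <- attr(mortality_summary(cif$fawn), "total")
    adult_tot <- attr(mortality_summary(cif$adult), "total")
    out <- dplyr::bind_rows(out, tibble(
      quantity = c("fawn_total_mortality", "adult_total_mortality",
                   "mortality_ratio_fawn_adult"),
      value = c(fawn_tot, adult_tot, round_half_up(fawn_tot / adult_tot, 1))
    ))
  }
  out
}

#' @export
print.dielrisk_report <- function(x, ...) {
  cat("Diel risk analysis report\n")
  cat(sprintf("  detections: %d (deer %d, carnivores %d, humans %d)\n",
              nrow(x$detections),
              sum(x$detections$species == "deer"),
              sum(x$detections$species %in% carnivore_species()),
              sum(x$detections$species == "human")))
  cat("  overlap (Delta-4, nursery vs adult deer):\n")
  wide <- x$overlap_table |>
    dplyr::select("source", "deer_group", "delta") |>
    tidyr::pivot_wider(names_from = "deer_group", values_from = "delta")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("    %-7s nursery %.2f  adult %.2f\n", wide$source[i],
                wide$nursery[i], wide$adult[i]))
  }
  for (i in seq_len(nrow(x$derived))) {
    cat(sprintf("  %-32s %g\n", x$derived$quantity[i], x$derived$value[i]))
  }
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Plain-text outputs: `detections.csv`, `overlap_table.csv`, `cif.csv`,
#' `weights.csv`, `risk_index_<stratum>.csv`, `window.csv`, `derived.csv`,
#' and `settings.json`.
#'
#' @param report A `dielrisk_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$detections, file.path(dir, "detections.csv"))
  readr::write_csv(report$overlap_table, file.path(dir, "overlap_table.csv"))
  readr::write_csv(report$cif_table, file.path(dir, "cif.csv"))
  w <- purrr::imap(report$weights, function(x, nm) {
    dplyr::mutate(as_tibble(x), stratum = nm,
                  excluded_mass = attr(x, "excluded_mass"))
  })
  readr::write_csv(dplyr::bind_rows(w), file.path(dir, "weights.csv"))
  for (nm in names(report$risk_index)) {
    readr::write_csv(as_tibble(report$risk_index[[nm]]),
                     file.path(dir, paste0("risk_index_", nm, ".csv")))
  }
  readr::write_csv(report$window, file.path(dir, "window.csv"))
  readr::write_csv(report$derived, file.path(dir, "derived.csv"))
  settings <- report$settings
  settings$window_start <- as.character(settings$window_start)
  settings$window_end <- as.character(settings$window_end)
  jsonlite::write_json(settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
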