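# ---- von Mises mixture activity generators -----------------------------

#' Convert clock hours to diel radians
#'
#' @param h Hours since midnight (0-24).
#' @return Radians in `[0, 2*pi)`.
#' @export
hours_to_radians <- function(h) {
  wrap_circular(2 * pi * h / 24)
}

#' Specify a von Mises mixture diel activity archetype
#'
#' A mixture of von Mises components on the diel circle, the generative model
#' behind the synthetic detection times: nocturnal carnivores, diurnal
#' humans and crepuscular deer are all expressible as 1-3 components.
#'
#' @param mean_rad Component mean directions (radians).
#' @param kappa Component concentrations (> 0).
#' @param prop Component mixing proportions (non-negative, sum to 1).
#' @param label Optional label for the archetype.
#' @return An `activity_mixture` object.
#' @export
activity_mixture <- function(mean_rad, kappa, prop = NULL, label = NULL) {
  prop <- prop %||% rep(1 / length(mean_rad), length(mean_rad))
  if (length(mean_rad) != length(kappa) || length(kappa) != length(prop)) {
    abort("`mean_rad`, `kappa` and `prop` must have equal lengths.",
          class = "dielrisk_invalid_spec")
  }
  if (any(kappa <= 0)) {
    abort("Invalid mixture spec: all `kappa` must be > 0.",
          class = "dielrisk_invalid_spec")
  }
  if (any(prop < 0) || abs(sum(prop) - 1) > 1e-9) {
    abort("Invalid mixture spec: `prop` must be >= 0 and sum to 1.",
          class = "dielrisk_invalid_spec")
  }
  structure(
    list(mean_rad = wrap_circular(mean_rad), kappa = kappa, prop = prop,
         label = label),
    class = "activity_mixture"
  )
}

#' @export
print.activity_mixture <- function(x, ...) {
  cat(sprintf("Von Mises mixture%s: %d component(s)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$prop)))
  for (i in seq_along(x$prop)) {
    cat(sprintf("  mean %5.1f h, kappa %.2f, prop %.2f\n",
                x$mean_rad[i] * 24 / (2 * pi), x$kappa[i], x$prop[i]))
  }
  invisible(x)
}

#' Density of a von Mises mixture
#'
#' @param theta Angles (radians).
#' @param spec An `activity_mixture`.
#' @return Density values.
#' @export
dmixture <- function(theta, spec) {
  stopifnot(inherits(spec, "activity_mixture"))
  Reduce(`+`, purrr::pmap(
    list(spec$mean_rad, spec$kappa, spec$prop),
    function(mu, k, p) p * dvonmises(theta, mu, k)
  ))
}

#' Pool several mixtures into one mixture
#'
#' Weighted union of component lists, e.g. the four carnivore archetypes
#' pooled in proportion to their detection counts.
#'
#' @param specs List of `activity_mixture` objects.
#' @param weights Pooling weights (normalized internally).
#' @param label Optional label.
#' @return An `activity_mixture`.
#' @export
pool_mixtures <- function(specs, weights, label = NULL) {
  weights <- weights / sum(weights)
  activity_mixture(
    mean_rad = unlist(lapply(specs, `[[`, "mean_rad")),
    kappa = unlist(lapply(specs, `[[`, "kappa")),
    prop = unlist(purrr::map2(specs, weights, function(s, w) w * s$prop)),
    label = label
  )
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0; 0 gives the circular uniform).
#' @return Radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) abort("`kappa` must be >= 0.", class = "dielrisk_invalid_parameter")
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    k <- length(th)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrap_circular(out + mu)
}

#' Draw from a von Mises mixture
#'
#' @param n Number of draws.
#' @param spec An `activity_mixture`.
#' @return Radians in `[0, 2*pi)`.
#' @export
rmixture <- function(n, spec) {
  stopifnot(inherits(spec, "activity_mixture"))
  comp <- sample.int(length(spec$prop), n, replace = TRUE, prob = spec$prop)
  out <- numeric(n)
  for (i in seq_along(spec$prop)) {
    idx <- comp == i
    if (any(idx)) out[idx] <- rvonmises(sum(idx), spec$mean_rad[i],
                                        spec$kappa[i])
  }
  out
}

#' True overlap between two mixture densities
#'
#' Quadrature of `min(f1, f2)` on a fine circular grid; the analytic target
#' the Delta estimators are checked against.
#'
#' @param spec1,spec2 `activity_mixture` objects.
#' @param grid_size Quadrature grid size. Default 4096.
#' @return Overlap in `[0, 1]`.
#' @export
true_overlap <- function(spec1, spec2, grid_size = 4096) {
  grid <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  circ_trapz(grid, pmin(dmixture(grid, spec1), dmixture(grid, spec2)))
}

# ---- detection-time generator ------------------------------------------

#' Generate synthetic detection events
#'
#' Detection times are drawn from the mixture archetype, detection dates
#' uniformly over `date_range`, and sites uniformly over a site pool.
#' Deterministic given `seed`.
#'
#' @param spec An `activity_mixture`.
#' @param n Number of detections (>= 1).
#' @param date_range Length-2 `Date` (or ISO text) vector, inclusive.
#' @param seed Integer seed (optional; caller's RNG preserved).
#' @param species Species label for the detections.
#' @param group Deer group label (`NA` for non-deer; implies the class
#'   counts).
#' @param n_sites Size of the site pool. Default 300.
#' @return A detection tibble matching [collapse_detections()] output.
#' @export
gen_detection_times <- function(spec, n, date_range, seed = NULL,
                                species = "deer", group = NA_character_,
                                n_sites = 300) {
  stopifnot(inherits(spec, "activity_mixture"))
  if (n < 1) abort("`n` must be >= 1.", class = "dielrisk_invalid_parameter")
  if (!species %in% camera_species()) {
    abort("Unknown `species`.", class = "dielrisk_invalid_parameter")
  }
  date_range <- lubridate::as_date(date_range)
  with_local_seed(seed, {
    theta <- rmixture(n, spec)
    dates <- sample(seq(date_range[1], date_range[2], by = "day"), n,
                    replace = TRUE)
    sites <- sprintf("S%03d", sample.int(n_sites, n, replace = TRUE))
    secs <- round(theta * 86400 / (2 * pi))
    timestamp <- lubridate::as_datetime(dates) + secs
    counts <- switch(
      as.character(group),
      nursery_group = list(f = 1L, m = 0L, y = 1L + rbinom(n, 1, 0.5)),
      adult_female = list(f = 1L, m = 0L, y = 0L),
      adult_male = list(f = 0L, m = 1L, y = 0L),
      list(f = 0L, m = 0L, y = 0L)
    )
    group_label <- if (species == "deer") group else "not_deer"
    tibble(
      site_id = sites, species = species,
      group = group_label,
      timestamp = timestamp, date = lubridate::as_date(timestamp),
      time_of_day_rad = time_to_radians(timestamp),
      n_adult_female = rep_len(as.integer(counts$f), n),
      n_adult_male = rep_len(as.integer(counts$m), n),
      n_fawn = rep_len(as.integer(counts$y), n),
      n_images = 1L
    ) |>
      dplyr::arrange(.data$site_id, .data$species, .data$timestamp)
  })
}

#' Expand detections into image bursts
#'
#' Emulates a camera firing a short burst per detection: each detection
#' becomes `images_per_detection` image records spaced `spacing_seconds`
#' apart, carrying the detection's class counts.
#'
#' @param events Detection tibble.
#' @param images_per_detection Images per burst. Default 3.
#' @param spacing_seconds Seconds between images. Default 20.
#' @return An image-record tibble suitable for [collapse_detections()].
#' @export
detections_to_images <- function(events, images_per_detection = 3,
                                 spacing_seconds = 20) {
  events |>
    dplyr::mutate(.det = dplyr::row_number()) |>
    tidyr::uncount(images_per_detection, .id = ".img") |>
    dplyr::mutate(
      datetime = .data$timestamp + (.data$.img - 1) * spacing_seconds
    ) |>
    dplyr::select("site_id", "species", "datetime",
                  "n_adult_female", "n_adult_male", "n_fawn")
}

# ---- mortality-cohort generator ----------------------------------------

#' Specify a synthetic monitored cohort
#'
#' Constant daily cause-specific hazards with daily random right-censoring
#' over a fixed monitoring horizon (discrete-day, geometric-type survival,
#' matching the daily-step incidence estimator).
#'
#' @param n Cohort size.
#' @param daily_hazards Named numeric vector over [mortality_causes()]
#'   subsets: per-day death probability by cause.
#' @param daily_censor_prob Per-day censoring probability. Default 0.
#' @param horizon_days Number of daily steps monitored. Default 78 (a
#'   July 15 - September 30 window).
#' @param stratum Stratum label (`"fawn"`, `"adult_female"`, ...).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n, daily_hazards, daily_censor_prob = 0,
                        horizon_days = 78, stratum = "fawn") {
  if (is.null(names(daily_hazards)) ||
      !all(names(daily_hazards) %in% mortality_causes())) {
    abort("`daily_hazards` must be named by mortality causes.",
          class = "dielrisk_invalid_spec")
  }
  if (any(daily_hazards < 0) || daily_censor_prob < 0 ||
      sum(daily_hazards) + daily_censor_prob >= 1) {
    abort("Need hazards >= 0, censor prob >= 0, and their sum < 1.",
          class = "dielrisk_invalid_spec")
  }
  structure(
    list(n = as.integer(n), daily_hazards = daily_hazards,
         daily_censor_prob = daily_censor_prob,
         horizon_days = as.integer(horizon_days), stratum = stratum),
    class = "cohort_spec"
  )
}

#' Generate a synthetic monitored cohort
#'
#' Each animal is simulated day by day from day 1 to the horizon: censoring
#' with `daily_censor_prob`, else death from cause `k` with
#' `daily_hazards[k]`, else survival to the next day. Animals reaching the
#' horizon are recorded as `survived`. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (optional).
#' @return A subject-history tibble for [aalen_johansen()].
#' @export
gen_mortality_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  h <- spec$daily_hazards
  pc <- spec$daily_censor_prob
  # per-day categorical: censor pc, death (1 - pc) * h_k, else survive
  p_stop <- pc + (1 - pc) * sum(h)
  with_local_seed(seed, {
    stop_day <- if (p_stop > 0) {
      stats::rgeom(spec$n, p_stop) + 1L
    } else {
      rep(Inf, spec$n)
    }
    survived <- stop_day > spec$horizon_days
    outcome <- rep("survived", spec$n)
    n_stop <- sum(!survived)
    if (n_stop > 0) {
      probs <- c(censored = pc, (1 - pc) * h) / p_stop
      outcome[!survived] <- sample(names(probs), n_stop, replace = TRUE,
                                   prob = probs)
    }
    tibble(
      animal_id = sprintf("%s_%04d", spec$stratum, seq_len(spec$n)),
      stratum = spec$stratum,
      start_day = 0L,
      end_day = as.integer(ifelse(survived, spec$horizon_days, stop_day)),
      outcome = outcome
    )
  })
}

#' Analytic cumulative incidence under constant daily hazards
#'
#' For constant cause-specific daily hazards the discrete-time CIF is
#' `CIF_k(t) = (h_k / h_tot) * (1 - (1 - h_tot)^t)`; the generator's ground
#' truth for recovery tests.
#'
#' @param daily_hazards Named per-day hazards.
#' @param t Day(s).
#' @return Tibble `cause`, `day`, `cif`.
#' @export
analytic_cif <- function(daily_hazards, t) {
  h_tot <- sum(daily_hazards)
  tidyr::expand_grid(cause = names(daily_hazards), day = t) |>
    dplyr::mutate(
      cif = unname(daily_hazards[.data$cause] / h_tot) *
        (1 - (1 - h_tot)^.data$day)
    )
}

#' Constant daily hazards matching target terminal incidences
#'
#' Inverts the analytic CIF: given target terminal cumulative incidences by
#' cause, returns the constant daily hazards that reproduce them at the
#' horizon (after discounting the slight risk-set erosion from daily
#' censoring).
#'
#' @param terminal_cif Named target incidences.
#' @param horizon_days Number of daily steps.
#' @param daily_censor_prob Daily censor probability used by the generator.
#' @return Named daily hazards.
#' @export
hazards_from_terminal_cif <- function(terminal_cif, horizon_days = 78,
                                      daily_censor_prob = 0) {
  total <- sum(terminal_cif)
  h_tot <- (1 - (1 - total)^(1 / horizon_days)) / (1 - daily_censor_prob)
  h_tot * terminal_cif / total
}

# ---- full study-scale scenario -----------------------------------------

#' Diel activity archetypes of the study community
#'
#' The built-in mixture specs: nocturnal carnivores, diurnal humans,
#' crepuscular adult deer and a diurnally shifted nursery-group archetype.
#'
#' @return Named list of `activity_mixture` objects.
#' @export
activity_archetypes <- function() {
  list(
    black_bear = activity_mixture(hours_to_radians(c(22, 4)), c(1.6, 2.2),
                                  c(0.65, 0.35), label = "black_bear"),
    bobcat = activity_mixture(hours_to_radians(c(0.5, 21)), c(1.3, 2.5),
                              c(0.7, 0.3), label = "bobcat"),
    coyote = activity_mixture(hours_to_radians(c(23, 3.5)), c(1.8, 1.8),
                              c(0.6, 0.4), label = "coyote"),
    wolf = activity_mixture(hours_to_radians(c(1, 21)), c(1.4, 2.2),
                            c(0.75, 0.25), label = "wolf"),
    human = activity_mixture(hours_to_radians(c(10.5, 15.5)), c(3.5, 3.0),
                             c(0.5, 0.5), label = "human"),
    adult_deer = activity_mixture(hours_to_radians(c(6, 20.5, 13)),
                                  c(3.5, 3.5, 0.8), c(0.38, 0.38, 0.24),
                                  label = "adult_deer"),
    nursery = activity_mixture(hours_to_radians(c(8.5, 18, 13)),
                               c(2.8, 2.8, 1.2), c(0.38, 0.34, 0.28),
                               label = "nursery")
  )
}

#' Simulate a full field-study-scale dataset bundle
#'
#' One self-contained synthetic dataset with the structure the analysis
#' assumes: camera image bursts for deer demographic groups, four carnivores
#' and humans (detection counts of the same order as a large summer camera
#' array: thousands of deer and carnivore detections, tens of thousands of
#' human detections), plus radio-collared fawn and adult cohorts with
#' constant daily cause-specific hazards calibrated to realistic summer
#' incidences (fawn total 0.16, adult total 0.03). Ground-truth parameters
#' (mixture specs, hazards, analytic incidences, true overlaps) travel with
#' the bundle so recovery tests never re-derive them.
#'
#' @param seed Integer seed.
#' @param scale Multiplier on detection counts (cohort sizes are fixed).
#'   Default 1.
#' @param date_range Camera deployment window. Default July 15 -
#'   September 15, 2019.
#' @return A list with `images`, `detections`, `mortality`, and `truth`.
#' @export
sim_field_scenario <- function(seed = 42, scale = 1,
                               date_range = as.Date(c("2019-07-15",
                                                      "2019-09-15"))) {
  arch <- activity_archetypes()
  counts <- c(nursery_group = 3596, adult_female = 7379, adult_male = 2438,
              black_bear = 1387, bobcat = 356, coyote = 2781, wolf = 1400,
              human = 27228)
  counts <- setNames(pmax(2L, as.integer(round(counts * scale))),
                     names(counts))

  spec_for <- function(nm) {
    switch(nm,
           nursery_group = arch$nursery,
           adult_female = arch$adult_deer,
           adult_male = arch$adult_deer,
           arch[[nm]])
  }
  dets <- purrr::imap(counts, function(n, nm) {
    is_deer <- nm %in% deer_groups()
    gen_detection_times(
      spec_for(nm), n, date_range,
      seed = seed + match(nm, names(counts)),
      species = if (is_deer) "deer" else nm,
      group = if (is_deer) nm else NA_character_
    )
  })
  detections <- dplyr::bind_rows(dets)
  images <- detections_to_images(detections)

  fawn_cif <- c(coyote = 0.04, bobcat = 0.02, vehicle = 0.03, bear = 0.01,
                wolf = 0.01, unidentified_predation = 0.03, disease = 0.02)
  adult_cif <- c(wolf = 0.013, vehicle = 0.011, coyote = 0.004,
                 disease = 0.002)
  fawn_censor <- 1 - (1 - 15 / 232)^(1 / 78)
  adult_censor <- 2e-4
  fawn_spec <- cohort_spec(232, hazards_from_terminal_cif(fawn_cif, 78,
                                                          fawn_censor),
                           fawn_censor, 78, "fawn")
  adult_spec <- cohort_spec(545, hazards_from_terminal_cif(adult_cif, 78,
                                                           adult_censor),
                            adult_censor, 78, "adult")
  mortality <- dplyr::bind_rows(
    gen_mortality_cohort(fawn_spec, seed = seed + 101),
    gen_mortality_cohort(adult_spec, seed = seed + 102)
  )

  carn <- c("black_bear", "bobcat", "coyote", "wolf")
  pooled_carnivore <- pool_mixtures(arch[carn], counts[carn],
                                    label = "carnivores_pooled")
  truth <- list(
    seed = seed, scale = scale, counts = counts,
    archetypes = arch, pooled_carnivore = pooled_carnivore,
    fawn_spec = fawn_spec, adult_spec = adult_spec,
    fawn_terminal_cif = fawn_cif, adult_terminal_cif = adult_cif,
    fawn_total_mortality = sum(fawn_cif),
    adult_total_mortality = sum(adult_cif),
    overlap_nursery_carnivores = true_overlap(arch$nursery, pooled_carnivore),
    overlap_adult_carnivores = true_overlap(arch$adult_deer, pooled_carnivore),
    overlap_nursery_human = true_overlap(arch$nursery, arch$human),
    overlap_adult_human = true_overlap(arch$adult_deer, arch$human)
  )
  list(images = images, detections = detections, mortality = mortality,
       truth = truth)
}

#' Write a scenario bundle to plain-text files
#'
#' Writes `images.csv`, `mortality.csv` and a `truth.json` sidecar carrying
#' the generator's ground-truth parameters.
#'
#' @param bundle Output of [sim_field_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$images, file.path(dir, "images.csv"))
  readr::write_csv(bundle$mortality, file.path(dir, "mortality.csv"))
  truth <- bundle$truth
  truth$archetypes <- lapply(truth$archetypes, unclass)
  truth$pooled_carnivore <- unclass(truth$pooled_carnivore)
  truth$fawn_spec <- unclass(truth$fawn_spec)
  truth$adult_spec <- unclass(truth$adult_spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
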