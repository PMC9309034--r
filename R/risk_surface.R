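# ---- mortality-weighted diel risk index --------------------------------

#' Proportional risk weights from cause-specific mortality
#'
#' Converts terminal cumulative incidences into the weights that combine
#' activity densities in the diel risk index: each identified source (the
#' four carnivores and humans, with vehicle-collision mortality attributed to
#' humans) is weighted by its share of the identified-cause mortality, so a
#' source accounting for 40% of known-cause mortality gets weight 0.4.
#' Unidentified predation, disease and unknown causes are excluded and
#' reported as `excluded_mass`; `redistribute_unidentified = TRUE` instead
#' spreads unidentified predation pro-rata across the four carnivores before
#' normalizing.
#'
#' @param incidence Terminal incidence by cause: the tibble from
#'   [mortality_summary()], or a named numeric vector over
#'   [mortality_causes()].
#' @param identified_sources Risk sources entering the weights. Default
#'   [risk_sources()].
#' @param redistribute_unidentified Spread unidentified predation across the
#'   carnivore sources in proportion to their incidences. Default `FALSE`.
#' @return A `risk_weights` object: tibble with columns `source`, `weight`
#'   and attributes `excluded_mass`, `stratum`.
#' @export
compute_risk_weights <- function(incidence,
                                 identified_sources = risk_sources(),
                                 redistribute_unidentified = FALSE) {
  stratum <- NA_character_
  if (is.data.frame(incidence)) {
    stratum <- attr(incidence, "stratum") %||% NA_character_
    incidence <- incidence |>
      dplyr::filter(.data$cause != "total")
    incidence <- setNames(incidence$incidence, incidence$cause)
  }
  if (is.null(names(incidence))) {
    abort("`incidence` must be named by mortality cause.",
          class = "dielrisk_invalid_parameter")
  }
  if (any(incidence < 0)) {
    abort("Incidences must be non-negative.",
          class = "dielrisk_invalid_parameter")
  }
  src <- cause_to_source(names(incidence))
  by_source <- tapply(incidence[!is.na(src)], src[!is.na(src)], sum)
  w <- setNames(numeric(length(identified_sources)), identified_sources)
  w[names(by_source)[names(by_source) %in% identified_sources]] <-
    by_source[names(by_source) %in% identified_sources]

  excluded <- sum(incidence[is.na(src)])
  if (redistribute_unidentified && "unidentified_predation" %in% names(incidence)) {
    up <- incidence[["unidentified_predation"]]
    carn <- intersect(c("bear", "bobcat", "coyote", "wolf"), names(w))
    if (sum(w[carn]) > 0 && up > 0) {
      w[carn] <- w[carn] + up * w[carn] / sum(w[carn])
      excluded <- excluded - up
    }
  }
  if (sum(w) <= 0) {
    abort("All identified-source incidences are zero; weights are undefined.",
          class = "dielrisk_undefined_weights")
  }
  out <- tibble(source = names(w), weight = unname(w) / sum(w))
  attr(out, "excluded_mass") <- excluded
  attr(out, "stratum") <- stratum
  class(out) <- c("risk_weights", class(out))
  out
}

#' Combine activity densities into the diel risk index
#'
#' The diel risk index is the weighted sum of the risk sources' activity
#' densities, `index(theta) = sum_k w_k * f_k(theta)`, on the common density
#' grid. Since the weights sum to 1 and each density integrates to 1, the
#' index is itself a probability density over the diel cycle.
#'
#' @param densities Named list of `circular_kde` fits, one per risk source
#'   with positive weight, all on the same grid.
#' @param weights A `risk_weights` object (or tibble with `source`,
#'   `weight`).
#' @return A `risk_index` object: tibble with `theta_rad`, one weighted
#'   component column per source, and `index`; attribute `stratum`.
#' @export
compute_risk_index <- function(densities, weights) {
  active <- weights$source[weights$weight > 0]
  missing <- setdiff(active, names(densities))
  if (length(missing) > 0) {
    abort(paste0("No fitted density for weighted source(s): ",
                 paste(missing, collapse = ", ")),
          class = "dielrisk_config_error")
  }
  grids <- lapply(densities[active], function(d) d$grid)
  if (length(active) > 1) {
    same <- vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                   logical(1))
    if (!all(same)) {
      abort("All densities must share the same grid.",
            class = "dielrisk_config_error")
    }
  }
  grid <- grids[[1]]
  comp <- purrr::map2(
    densities[active],
    weights$weight[match(active, weights$source)],
    function(d, w) w * d$density
  )
  out <- tibble(theta_rad = grid) |>
    dplyr::bind_cols(as_tibble(comp)) |>
    dplyr::mutate(index = Reduce(`+`, comp))
  attr(out, "stratum") <- attr(weights, "stratum")
  class(out) <- c("risk_index", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_index <- function(object, ...) {
  object |>
    as_tibble() |>
    tidyr::pivot_longer(cols = -c("theta_rad", "index"),
                        names_to = "source", values_to = "component") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$theta_rad * 24 / (2 * pi),
                                 y = .data$component, fill = .data$source)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), expand = c(0, 0)) +
    ggplot2::labs(x = "Time of day (h)", y = "Weighted activity density",
                  fill = "Risk source") +
    ggplot2::theme_minimal()
}

# ---- moving-window overlap series --------------------------------------

#' Moving-window overlap between deer and pooled carnivores
#'
#' For each calendar day `d` in `[start_date, end_date]`, estimates the diel
#' overlap between the deer sample and the pooled carnivore sample restricted
#' to detections dated within `d` plus/minus `half_window_days` (an 11-day
#' window by default, boundary days included). Windows where either sample
#' falls below `min_n` yield a missing overlap with the counts still
#' reported.
#'
#' @param deer_events,carnivore_events Detection tibbles with columns `date`
#'   and `time_of_day_rad` (carnivore events are typically the four species
#'   pooled as one sample).
#' @param start_date,end_date First and last window centres (`Date` or
#'   ISO text). Defaults: the detection date range shrunk inward by
#'   `half_window_days`.
#' @param half_window_days Half-width of the window in days. Default 5.
#' @param estimator Overlap estimator, as in [bootstrap_overlap()]; the
#'   default `"auto"` uses Delta-4 when both window samples reach 75 and
#'   Delta-1 below.
#' @param min_n Minimum per-sample window size for estimation. Default 20.
#' @inheritParams estimate_delta4
#' @return A `moving_window` tibble: `date`, `delta`, `n_deer`,
#'   `n_carnivore`, `estimator`.
#' @export
moving_window_overlap <- function(deer_events, carnivore_events,
                                  start_date = NULL, end_date = NULL,
                                  half_window_days = 5,
                                  estimator = c("auto", "delta4", "delta1"),
                                  min_n = 20, kappa = "auto", adjust = 1) {
  estimator <- match.arg(estimator)
  assert_scalar_number(half_window_days, "half_window_days", min = 0)
  if (nrow(deer_events) == 0 || nrow(carnivore_events) == 0) {
    abort("Both detection sets must be non-empty.",
          class = "dielrisk_empty_selection")
  }
  all_dates <- c(deer_events$date, carnivore_events$date)
  start_date <- lubridate::as_date(start_date %||%
                                     (min(all_dates) + half_window_days))
  end_date <- lubridate::as_date(end_date %||%
                                   (max(all_dates) - half_window_days))
  if (end_date < start_date) {
    abort("`end_date` is before `start_date`.",
          class = "dielrisk_invalid_parameter")
  }
  centres <- seq(start_date, end_date, by = "day")
  rows <- purrr::map(centres, function(d) {
    in_win <- function(ev) abs(as.numeric(ev$date - d)) <= half_window_days
    td <- deer_events$time_of_day_rad[in_win(deer_events)]
    tc <- carnivore_events$time_of_day_rad[in_win(carnivore_events)]
    n_deer <- length(td)
    n_carn <- length(tc)
    if (min(n_deer, n_carn) < min_n) {
      return(tibble(date = d, delta = NA_real_, n_deer = n_deer,
                    n_carnivore = n_carn, estimator = NA_character_))
    }
    method <- resolve_estimator(estimator, n_deer, n_carn, quiet = TRUE)
    delta <- delta_fun(method)(td, tc, kappa = kappa, adjust = adjust)
    tibble(date = d, delta = delta, n_deer = n_deer, n_carnivore = n_carn,
           estimator = method)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("moving_window", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.moving_window <- function(object, ...) {
  object |>
    as_tibble() |>
    ggplot2::ggplot(ggplot2::aes(x = .data$date, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Window centre date", y = "Overlap (Delta)") +
    ggplot2::theme_minimal()
}

# ---- derived percentage contrasts --------------------------------------

#' Relative change between two overlap estimates
#'
#' Expresses how much smaller (`type = "reduction"`,
#' `100 * (b - a) / b`) or larger (`type = "increase"`, `100 * (a - b) / b`)
#' group A's overlap is relative to baseline group B's.
#'
#' @param delta_a Overlap of the focal group (e.g. nursery groups).
#' @param delta_b Baseline overlap (e.g. adult deer); must be positive.
#' @param type `"reduction"` or `"increase"`.
#' @return Signed percent (not rounded; see [round_percent()]).
#' @export
relative_overlap_change <- function(delta_a, delta_b,
                                    type = c("reduction", "increase")) {
  type <- match.arg(type)
  if (any(delta_b <= 0)) {
    abort("Baseline overlap must be positive.",
          class = "dielrisk_invalid_parameter")
  }
  switch(type,
         reduction = 100 * (delta_b - delta_a) / delta_b,
         increase = 100 * (delta_a - delta_b) / delta_b)
}

#' Round a percentage the way results tables print it
#'
#' Round-half-away-from-zero to integer percent.
#'
#' @param x Percent values.
#' @return Rounded values.
#' @export
round_percent <- function(x) {
  round_half_up(x, 0)
}
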