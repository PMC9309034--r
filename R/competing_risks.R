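# ---- Aalen-Johansen cumulative incidence on a daily grid ---------------

#' Read a telemetry mortality table
#'
#' CSV with columns `animal_id,stratum,start_day,end_day,outcome`. Study days
#' are integers with day 0 = first monitoring day (July 15 for the summer
#' fawn-survival window); `outcome` is `survived`, `censored`, or one of
#' [mortality_causes()].
#'
#' @param path Path to a CSV file.
#' @return A tibble of subject histories.
#' @export
read_mortality_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      stratum = readr::col_character(),
      start_day = readr::col_integer(),
      end_day = readr::col_integer(),
      outcome = readr::col_character()
    )
  )
}

validate_histories <- function(histories) {
  required <- c("animal_id", "stratum", "start_day", "end_day", "outcome")
  missing <- setdiff(required, names(histories))
  if (length(missing) > 0) {
    abort(paste0("Mortality table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dielrisk_parse_error")
  }
  bad <- setdiff(unique(histories$outcome), terminal_outcomes())
  if (length(bad) > 0) {
    abort(paste0("Unknown outcome label(s): ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(terminal_outcomes(), collapse = ", ")),
          class = "dielrisk_parse_error")
  }
  if (any(histories$start_day < 0) ||
      any(histories$end_day < histories$start_day)) {
    abort("Need 0 <= start_day <= end_day for every subject.",
          class = "dielrisk_parse_error")
  }
  histories
}

#' Aalen-Johansen cause-specific cumulative incidence
#'
#' Nonparametric estimator of the cumulative incidence function (CIF) of each
#' mortality cause under competing risks with right-censoring, on a daily
#' step grid. For each day `t` with `n(t)` subjects at risk and `d_k(t)`
#' deaths from cause `k`:
#' `CIF_k(t) = CIF_k(t-1) + S(t-1) * d_k(t) / n(t)` and
#' `S(t) = S(t-1) * (1 - sum_k d_k(t) / n(t))`.
#' Subjects censored on day `t` (including `survived`, treated as censored at
#' their `end_day`) stay in the risk set for day-`t` deaths and leave
#' afterwards (events-before-censorings tie convention). Staggered entry is
#' supported through `start_day` (a subject enters the risk set the day after
#' `start_day`); cohorts with all `start_day = 0` reproduce the common
#' no-staggered-entry design.
#'
#' @param histories Data frame of subject histories (see
#'   [read_mortality_csv()]).
#' @param stratum Optional stratum label(s) to keep (e.g. `"fawn"`).
#' @param horizon Last day of the grid; defaults to the maximum `end_day`.
#' @return A `cif_set` object: `days` (0..horizon), `surv`, `n_at_risk`,
#'   `cif` (matrix day x cause), `stratum`, `n_subjects`.
#' @export
#' @examples
#' coh <- tibble::tibble(
#'   animal_id = as.character(1:3), stratum = "fawn", start_day = 0L,
#'   end_day = c(1L, 2L, 77L), outcome = c("censored", "coyote", "survived")
#' )
#' fit <- aalen_johansen(coh)
#' mortality_summary(fit)
aalen_johansen <- function(histories, stratum = NULL, horizon = NULL) {
  histories <- validate_histories(histories)
  if (!is.null(stratum)) {
    histories <- dplyr::filter(histories, .data$stratum %in% !!stratum)
    if (nrow(histories) == 0) {
      stop_empty_selection(paste0("stratum=", paste(stratum, collapse = "/")))
    }
  }
  if (nrow(histories) == 0) {
    abort("Empty cohort.", class = "dielrisk_empty_selection")
  }
  horizon <- horizon %||% max(histories$end_day)
  assert_scalar_number(horizon, "horizon", min = 0)
  causes <- mortality_causes()
  days <- 0:horizon
  nt <- length(days)

  surv <- rep(1, nt)
  n_at_risk <- integer(nt)
  cif <- matrix(0, nrow = nt, ncol = length(causes),
                dimnames = list(NULL, causes))
  is_death <- histories$outcome %in% causes

  for (i in seq_along(days)) {
    t <- days[i]
    # at risk on day t: entered before t, not yet terminated before t
    at_risk <- histories$start_day < t & histories$end_day >= t
    n_at_risk[i] <- sum(at_risk)
    if (i == 1) next # day 0: everyone alive, no transitions
    surv[i] <- surv[i - 1]
    cif[i, ] <- cif[i - 1, ]
    if (n_at_risk[i] == 0) next
    died_today <- at_risk & is_death & histories$end_day == t
    if (any(died_today)) {
      d_k <- table(factor(histories$outcome[died_today], levels = causes))
      inc <- surv[i - 1] * as.numeric(d_k) / n_at_risk[i]
      cif[i, ] <- cif[i - 1, ] + inc
      surv[i] <- surv[i - 1] * (1 - sum(d_k) / n_at_risk[i])
    }
  }
  n_at_risk[1] <- sum(histories$start_day <= 0)

  structure(
    list(days = days, surv = surv, n_at_risk = n_at_risk, cif = cif,
         stratum = stratum %||% paste(unique(histories$stratum),
                                      collapse = "+"),
         n_subjects = nrow(histories)),
    class = "cif_set"
  )
}

#' Terminal cumulative incidence by cause
#'
#' Cause-specific cumulative incidence at the horizon day, plus the total
#' mortality across causes.
#'
#' @param cifset A `cif_set` object.
#' @param horizon Day at which to read the CIFs; defaults to the last grid
#'   day.
#' @return A tibble with columns `cause` and `incidence`; the attribute
#'   `total` (also included as the `"total"` row) is the summed incidence.
#' @export
mortality_summary <- function(cifset, horizon = NULL) {
  stopifnot(inherits(cifset, "cif_set"))
  horizon <- horizon %||% max(cifset$days)
  i <- match(horizon, cifset$days)
  if (is.na(i)) {
    abort("`horizon` is outside the estimated day grid.",
          class = "dielrisk_invalid_parameter")
  }
  inc <- cifset$cif[i, ]
  out <- tibble(cause = c(names(inc), "total"),
                incidence = c(unname(inc), sum(inc)))
  attr(out, "total") <- sum(inc)
  attr(out, "stratum") <- cifset$stratum
  out
}

#' @export
print.cif_set <- function(x, ...) {
  ms <- mortality_summary(x)
  cat(sprintf(
    "Aalen-Johansen CIFs: stratum %s, n = %d, days 0..%d, total mortality %.3f\n",
    x$stratum, x$n_subjects, max(x$days), attr(ms, "total")
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cif_set <- function(x, ...) {
  surv_tbl <- tibble(stratum = x$stratum, day = x$days, measure = "surv",
                     cause = NA_character_, value = x$surv)
  risk_tbl <- tibble(stratum = x$stratum, day = x$days, measure = "n_at_risk",
                     cause = NA_character_, value = as.numeric(x$n_at_risk))
  cif_tbl <- as_tibble(x$cif) |>
    dplyr::mutate(day = x$days) |>
    tidyr::pivot_longer(-"day", names_to = "cause", values_to = "value") |>
    dplyr::mutate(stratum = x$stratum, measure = "cif") |>
    dplyr::select("stratum", "day", "measure", "cause", "value")
  dplyr::bind_rows(surv_tbl, cif_tbl, risk_tbl)
}

#' @exportS3Method generics::glance
glance.cif_set <- function(x, ...) {
  ms <- mortality_summary(x)
  wide <- setNames(as.list(ms$incidence), paste0("cif_", ms$cause))
  dplyr::bind_cols(
    tibble(stratum = x$stratum, n = x$n_subjects, horizon = max(x$days),
           surv_terminal = x$surv[length(x$surv)]),
    as_tibble(wide)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cif_set <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$measure == "cif") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$day, y = .data$value,
                                 colour = .data$cause)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Study day", y = "Cumulative incidence",
                  colour = "Cause") +
    ggplot2::theme_minimal()
}

#' Write a CIF set to long-format CSV
#'
#' @param cifset A `cif_set` object.
#' @param path Output path; columns `stratum,day,measure,cause,value`.
#' @return `path`, invisibly.
#' @export
write_cif_csv <- function(cifset, path) {
  readr::write_csv(tidy(cifset), path)
  invisible(path)
}
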