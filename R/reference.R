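#' Published summary values from the motivating field study
#'
#' Point estimates printed by the Upper Peninsula (Michigan) white-tailed
#' deer / multi-predator field study that motivates this package: per-source
#' cause-specific mortality of collared fawns and adults, risk weights,
#' Delta-4 diel overlap of nursery groups and fawn-free adult deer with each
#' carnivore and with humans (95% confidence limits), and total cohort
#' mortality per stratum. Shipped as plain-text reference inputs so the
#' package's derived-contrast arithmetic can be checked against the study's
#' printed percentages without any field data.
#'
#' @return A list of two tibbles, `overlap` (per risk source) and `totals`
#'   (per stratum).
#' @export
study_reference <- function() {
  list(
    overlap = readr::read_csv(
      system.file("extdata", "field_study_reference.csv",
                  package = "dielrisk"),
      col_types = readr::cols(source = readr::col_character(),
                              .default = readr::col_double())
    ),
    totals = readr::read_csv(
      system.file("extdata", "field_study_totals.csv", package = "dielrisk"),
      col_types = readr::cols(stratum = readr::col_character(),
                              total_mortality = readr::col_double(),
                              n_collared = readr::col_integer())
    )
  )
}

#' Derived percentage contrasts from reference overlap and mortality values
#'
#' Applies the package's derived-contrast operations
#' ([relative_overlap_change()], group means, mortality ratio, and the
#' integer-percent rounding rule) to a per-source table of overlap point
#' estimates, e.g. the published values from [study_reference()].
#'
#' @param reference A list like [study_reference()]: `overlap` with columns
#'   `source`, `delta4_nursery`, `delta4_adult`; `totals` with `stratum`,
#'   `total_mortality`.
#' @return A tibble `quantity`, `value` of derived contrasts.
#' @export
reference_contrasts <- function(reference = study_reference()) {
  overlap_table <- reference$overlap |>
    dplyr::select("source", nursery = "delta4_nursery",
                  adult = "delta4_adult") |>
    tidyr::pivot_longer(c("nursery", "adult"), names_to = "deer_group",
                        values_to = "delta")
  derived <- derive_contrasts(overlap_table)
  tot <- setNames(reference$totals$total_mortality,
                  reference$totals$stratum)
  dplyr::bind_rows(derived, tibble(
    quantity = c("fawn_total_mortality", "adult_total_mortality",
                 "mortality_ratio_fawn_adult"),
    value = c(unname(tot["fawn"]), unname(tot["adult"]),
              round_half_up(tot[["fawn"]] / tot[["adult"]], 1))
  ))
}
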