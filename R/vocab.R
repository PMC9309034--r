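#' Controlled vocabularies
#'
#' The closed sets of labels used across the pipeline: camera species, the
#' four carnivores, deer demographic groups, mortality causes recorded for
#' collared deer, and the identified risk sources that enter the diel risk
#' index. Vehicle-collision mortality maps to the `human` risk source.
#'
#' @return A character vector of labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
camera_species <- function() {
  c("deer", "black_bear", "bobcat", "coyote", "wolf", "human", "other")
}

#' @rdname vocabularies
#' @export
carnivore_species <- function() {
  c("black_bear", "bobcat", "coyote", "wolf")
}

#' @rdname vocabularies
#' @export
deer_groups <- function() {
  c("nursery_group", "adult_female", "adult_male")
}

#' @rdname vocabularies
#' @export
mortality_causes <- function() {
  c("vehicle", "coyote", "bear", "wolf", "bobcat",
    "unidentified_predation", "disease", "unknown")
}

#' @rdname vocabularies
#' @export
terminal_outcomes <- function() {
  c("survived", "censored", mortality_causes())
}

#' @rdname vocabularies
#' @export
risk_sources <- function() {
  c("bear", "bobcat", "coyote", "wolf", "human")
}

# mortality cause -> risk source (NA = not an identified source)
cause_to_source <- function(cause) {
  map <- c(
    vehicle = "human", coyote = "coyote", bear = "bear", wolf = "wolf",
    bobcat = "bobcat", unidentified_predation = NA, disease = NA, unknown = NA
  )
  unname(map[cause])
}

# camera species -> risk source
species_to_source <- function(species) {
  map <- c(
    black_bear = "bear", bobcat = "bobcat", coyote = "coyote",
    wolf = "wolf", human = "human"
  )
  unname(map[species])
}
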