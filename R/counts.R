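#' Grouped counting primitives
#'
#' The three integer ingredients every index is built from, for one species
#' within one informant group:
#'
#' * `citation_frequency()` -- FC, the number of distinct informants with at
#'   least one use report for the species;
#' * `use_report_count()` -- UR, the number of (informant, ailment) pairs
#'   citing the species, i.e. its total use reports;
#' * `distinct_use_count()` -- NU, the number of distinct normalized ailments
#'   the species is reported against.
#'
#' For every species and group, FC <= UR and NU <= UR.
#'
#' @param ds An `eb_dataset`.
#' @param species A `species_id` present in the dataset.
#' @param group Ethnic group label, or `"all"` (default) for the pooled survey.
#' @return A nonnegative integer.
#' @examples
#' ds <- simulate_study(sim_config(seed = 1))
#' sp <- ds$species$species_id[1]
#' citation_frequency(ds, sp) <= use_report_count(ds, sp) # always TRUE
#' @name counting
NULL

#' @rdname counting
#' @export
citation_frequency <- function(ds, species, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  rep <- group_reports(ds, group)
  length(unique(rep$informant_id[rep$species_id == species]))
}

#' @rdname counting
#' @export
use_report_count <- function(ds, species, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  rep <- group_reports(ds, group)
  sum(rep$species_id == species)
}

#' @rdname counting
#' @export
distinct_use_count <- function(ds, species, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  rep <- group_reports(ds, group)
  length(unique(rep$ailment[rep$species_id == species]))
}

#' Per-species count table for a group
#'
#' Vectorised version of the counting primitives: one row per species cited in
#' the group, with its FC, UR and NU.
#'
#' @inheritParams counting
#' @return A tibble with columns `species_id`, `fc`, `ur`, `nu`.
#' @export
count_table <- function(ds, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  rep <- group_reports(ds, group)
  if (nrow(rep) == 0) {
    return(tibble::tibble(
      species_id = character(), fc = integer(),
      ur = integer(), nu = integer()
    ))
  }
  rep |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      fc = dplyr::n_distinct(.data$informant_id),
      ur = dplyr::n(),
      nu = dplyr::n_distinct(.data$ailment),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species_id)
}
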