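#' Packaged survey fixtures
#'
#' Machine-readable transcriptions of the printed summary tables of a
#' three-ethnic-group medicinal plant survey (Gedeo, Oromo and Sidama ethnic
#' groups, 63 informants each), shipped so worked examples can be replayed
#' from their printed integer ingredients:
#'
#' * `"demographics"` -- informant counts and percentages per demographic
#'   level (ethnicity, age class, gender, education, religion).
#' * `"knowledge"` -- per-level knowledge-score means, standard deviations and
#'   group-test p-values for each demographic variable.
#' * `"species"` -- the documented species list (`species_id`,
#'   `scientific_name` with author, `family`, `voucher`); free-text columns of
#'   the source (local names, habit, uses) are not transcribed.
#' * `"use_value"` -- per species and group: FC (citing informants), UR (use
#'   reports), NU (distinct ailments) and the printed UV. `uv_consistent`
#'   flags whether the printed UV equals UR/63 at printed precision; a few
#'   source rows do not, and exact replays skip them.
#' * `"consensus"` -- per ailment and group: use reports, distinct species and
#'   the printed ICF, with the cited species list; `icf_consistent` flags
#'   agreement with (nur-nt)/(nur-1) at 2 dp (all transcribed rows agree).
#' * `"priority"` -- per species, ailment and group: printed FL, RPL and ROP.
#'   The `note` column flags source defects (a missing FL, a missing decimal
#'   point, rows violating ROP = RPL*FL at printed precision) that replay
#'   tests exclude.
#'
#' @param name One of `"demographics"`, `"knowledge"`, `"species"`,
#'   `"use_value"`, `"consensus"`, `"priority"`.
#' @return A tibble.
#' @examples
#' nrow(eb_fixture("species")) # 189 documented species
#' @export
eb_fixture <- function(name = c(
                         "demographics", "knowledge", "species",
                         "use_value", "consensus", "priority"
                       )) {
  name <- match.arg(name)
  file <- c(
    demographics = "demographics_table.csv",
    knowledge = "knowledge_by_demographic.csv",
    species = "species_table.csv",
    use_value = "use_value_table.csv",
    consensus = "consensus_table.csv",
    priority = "priority_table.csv"
  )[[name]]
  path <- system.file("extdata", file, package = "ethnoindices", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path,
    stringsAsFactors = FALSE,
    check.names = FALSE, fileEncoding = "UTF-8"
  ))
}

# smallest report layout realising given FC / UR / NU for one species:
# every one of the fc informants gets >= 1 report, every one of the nu
# ailments appears, and exactly ur distinct (informant, ailment) pairs exist
report_layout <- function(fc, ur, nu) {
  stopifnot(fc >= 1, nu >= 1, ur >= fc, ur >= nu, ur <= fc * nu)
  inf <- integer(0)
  ail <- integer(0)
  seen <- matrix(FALSE, nrow = fc, ncol = nu)
  add <- function(i, j) {
    inf <<- c(inf, i)
    ail <<- c(ail, j)
    seen[i, j] <<- TRUE
  }
  for (i in seq_len(fc)) add(i, (i - 1L) %% nu + 1L)
  for (j in seq_len(nu)) {
    if (!any(seen[, j])) {
      i <- which(!seen[, j])[1]
      add(i, j)
    }
  }
  for (i in seq_len(fc)) {
    for (j in seq_len(nu)) {
      if (length(inf) >= ur) break
      if (!seen[i, j]) add(i, j)
    }
  }
  stopifnot(length(inf) == ur)
  list(informant = inf, ailment = ail)
}

#' Reconstruct a minimal dataset from printed index ingredients
#'
#' Published survey tables print only the integer ingredients of each index
#' (citing informants, use reports, distinct ailments, species per category),
#' not the raw informant-level data. These constructors build the smallest
#' report table realising those ingredients so the index arithmetic can be
#' recomputed -- not assumed -- from print.
#'
#' `reconstruct_uv_dataset()` realises one species with the given FC / UR / NU
#' inside a group of `n_informants`; `reconstruct_icf_dataset()` realises one
#' ailment category with `nur` use reports spread over `nt` species;
#' `reconstruct_fl_dataset()` realises a species cited by `fcs` informants of
#' whom `ns` cite it for the focal ailment.
#'
#' @param fc,ur,nu Citing informants, use reports and distinct ailments of the
#'   species (requires `fc <= ur`, `nu <= ur`, `ur <= fc * nu`).
#' @param nur,nt Use reports and distinct species in the ailment category.
#' @param ns,fcs Informants citing the species for the focal ailment, and for
#'   any purpose (`ns <= fcs`).
#' @param n_informants Informants in the group (the UV denominator).
#' @param group Group label for the reconstructed informants.
#' @return An `eb_dataset`.
#' @examples
#' ds <- reconstruct_uv_dataset(fc = 16, ur = 38, nu = 14, n_informants = 63)
#' use_value(ds, "sp1", "Oromo")$uv # 38/63 = 0.603 (3 dp)
#' @name reconstruct
NULL

reconstruct_informants <- function(n_informants, group) {
  tibble::tibble(
    informant_id = sprintf("inf%03d", seq_len(n_informants)),
    ethnic_group = group,
    age = 50L,
    gender = "Male",
    education = "Primary",
    religion = "Protestant"
  )
}

#' @rdname reconstruct
#' @export
reconstruct_uv_dataset <- function(fc, ur, nu, n_informants = 63, group = "Oromo") {
  stopifnot(fc <= n_informants)
  lay <- report_layout(fc, ur, nu)
  reports <- tibble::tibble(
    informant_id = sprintf("inf%03d", lay$informant),
    species_id = "sp1",
    ailment = sprintf("ailment %02d", lay$ailment)
  )
  eb_dataset(reports, reconstruct_informants(n_informants, group))
}

#' @rdname reconstruct
#' @export
reconstruct_icf_dataset <- function(nur, nt, n_informants = 63, group = "Sidama") {
  stopifnot(nt >= 1, nt <= nur, nur <= n_informants)
  reports <- tibble::tibble(
    informant_id = sprintf("inf%03d", seq_len(nur)),
    species_id = sprintf("sp%02d", (seq_len(nur) - 1L) %% nt + 1L),
    ailment = "focal ailment"
  )
  eb_dataset(reports, reconstruct_informants(n_informants, group),
    category_map = tibble::tibble(
      ailment = "focal ailment",
      category = "focal category"
    )
  )
}

#' @rdname reconstruct
#' @export
reconstruct_fl_dataset <- function(ns, fcs, n_informants = 63, group = "Gedeo") {
  stopifnot(ns >= 1, ns <= fcs, fcs <= n_informants)
  reports <- tibble::tibble(
    informant_id = sprintf("inf%03d", seq_len(fcs)),
    species_id = "sp1",
    ailment = ifelse(seq_len(fcs) <= ns, "focal ailment", "other ailment")
  )
  eb_dataset(reports, reconstruct_informants(n_informants, group))
}
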