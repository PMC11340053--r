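#' Use value of a species
#'
#' The use value index UV = UR / N_g: the species' total use reports in the
#' group divided by the number of informants interviewed in that group. It
#' measures the relative importance of a species to a community; a species
#' every informant cites for several ailments scores high. The integer
#' ingredients (FC, UR, NU) are returned alongside the index so the arithmetic
#' stays auditable; UV is kept at full precision, display rounding happens only
#' in the reporting layer.
#'
#' @param ds An `eb_dataset`.
#' @param species A `species_id` present in the dataset.
#' @param group Ethnic group label, or `"all"`.
#' @return A one-row tibble with columns `species_id`, `group`, `fc`, `ur`,
#'   `nu`, `uv`.
#' @examples
#' # 38 use reports among 63 informants give UV = 38/63 = 0.603 (3 dp)
#' @export
use_value <- function(ds, species, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  n_g <- informant_count(ds, group)
  if (n_g == 0) {
    stop_domain(sprintf("group '%s' has no informants; UV undefined", group))
  }
  ur <- use_report_count(ds, species, group)
  tibble::tibble(
    species_id = species,
    group = group,
    fc = citation_frequency(ds, species, group),
    ur = ur,
    nu = distinct_use_count(ds, species, group),
    uv = ur / n_g
  )
}

#' Use value table for a group
#'
#' One row per species retained by the minimum-citation filter, with the
#' integer ingredients and the use value.
#'
#' @inheritParams use_value
#' @param min_citations Minimum frequency of citation for a species to be
#'   evaluated (default 3, the customary reporting threshold; use 1 to keep
#'   every cited species).
#' @return A tibble with columns `species_id`, `group`, `fc`, `ur`, `nu`, `uv`,
#'   sorted by species.
#' @export
uv_table <- function(ds, group = "all", min_citations = 3) {
  stopifnot(inherits(ds, "eb_dataset"))
  n_g <- informant_count(ds, group)
  if (n_g == 0) {
    stop_domain(sprintf("group '%s' has no informants; UV undefined", group))
  }
  tab <- count_table(ds, group)
  tab <- tab[tab$fc >= min_citations, , drop = FALSE]
  tibble::tibble(
    species_id = tab$species_id,
    group = group,
    fc = tab$fc,
    ur = tab$ur,
    nu = tab$nu,
    uv = tab$ur / n_g
  )
}

#' Informant consensus factor for an ailment category
#'
#' ICF = (nur - nt) / (nur - 1), where nur is the number of use reports whose
#' ailment falls in the category (within the group) and nt the number of
#' distinct species cited in that category. ICF is 1 when all informants agree
#' on a single species and 0 when every report names a different species; it is
#' undefined (returned as `NA` with a warning) when nur < 2, because the
#' denominator vanishes.
#'
#' @param ds An `eb_dataset` with a category map.
#' @param category A category label present in the map.
#' @param group Ethnic group label, or `"all"`.
#' @return A one-row tibble with columns `category`, `group`, `nur`, `nt`,
#'   `icf`.
#' @examples
#' # 16 reports over 3 species: ICF = (16 - 3) / 15 = 0.87 (2 dp)
#' @export
icf <- function(ds, category, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  known <- unique(ds$category_map$category)
  if (!category %in% known) {
    stop_domain(sprintf("unknown ailment category '%s'", category))
  }
  rep <- group_reports(ds, group)
  rep <- rep[!is.na(rep$category) & rep$category == category, , drop = FALSE]
  nur <- nrow(rep)
  nt <- length(unique(rep$species_id))
  value <- if (nur >= 2) {
    (nur - nt) / (nur - 1)
  } else {
    rlang::warn(sprintf(
      "ICF undefined for category '%s' in group '%s' (%d use report%s)",
      category, group, nur, if (nur == 1) "" else "s"
    ))
    NA_real_
  }
  tibble::tibble(category = category, group = group, nur = nur, nt = nt, icf = value)
}

#' Informant consensus factor table
#'
#' One row per (category, group) combination with at least one use report.
#'
#' @inheritParams icf
#' @return A tibble with columns `category`, `group`, `nur`, `nt`, `icf`.
#' @export
icf_table <- function(ds, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  rep <- group_reports(ds, group)
  rep <- rep[!is.na(rep$category), , drop = FALSE]
  if (nrow(rep) == 0) {
    return(tibble::tibble(
      category = character(), group = character(),
      nur = integer(), nt = integer(), icf = double()
    ))
  }
  out <- rep |>
    dplyr::group_by(category = .data$category) |>
    dplyr::summarise(
      nur = dplyr::n(),
      nt = dplyr::n_distinct(.data$species_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category)
  out$group <- group
  out$icf <- ifelse(out$nur >= 2, (out$nur - out$nt) / (out$nur - 1), NA_real_)
  out[c("category", "group", "nur", "nt", "icf")]
}

#' Fidelity level of a species for one ailment
#'
#' FL = 100 * Ns / FCs: the percentage of the species' citing informants who
#' cite it specifically for this ailment (Ns informants out of the FCs distinct
#' informants citing the species for any purpose in the group). FL is defined
#' only when the species is actually cited for the ailment (Ns >= 1); a species
#' never cited for an ailment has no fidelity there, not a fidelity of zero.
#'
#' @param ds An `eb_dataset`.
#' @param species A `species_id`.
#' @param ailment An ailment label (normalized before matching).
#' @param group Ethnic group label, or `"all"`.
#' @return A one-row tibble with columns `species_id`, `ailment`, `group`,
#'   `ns`, `fcs`, `fl`.
#' @examples
#' # 3 of 4 citing informants name the species for one ailment: FL = 75
#' @export
fidelity_level <- function(ds, species, ailment, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  ailment <- normalize_ailment(ailment)
  rep <- group_reports(ds, group)
  rep_sp <- rep[rep$species_id == species, , drop = FALSE]
  ns <- length(unique(rep_sp$informant_id[rep_sp$ailment == ailment]))
  if (ns == 0) {
    stop_domain(sprintf(
      "species '%s' has no use report for ailment '%s' in group '%s'; FL undefined",
      species, ailment, group
    ))
  }
  fcs <- length(unique(rep_sp$informant_id))
  tibble::tibble(
    species_id = species, ailment = ailment, group = group,
    ns = ns, fcs = fcs, fl = 100 * ns / fcs
  )
}

#' Relative popularity level of a species
#'
#' A 0-1 popularity weight for a species within a group, used to correct the
#' fidelity level into the rank-order priority. Two modes:
#'
#' * `"friedman"` (default): species whose frequency of citation reaches half
#'   the maximum FC in the group are "popular" and get RPL = 1; below the
#'   threshold RPL = FC / (max FC / 2). The threshold is exactly max/2, with no
#'   integer truncation, so ties are handled consistently.
#' * `"supplied"`: a pass-through of an externally given RPL in \[0, 1\], used
#'   to replay published tables whose RPL derivation is not reproducible from
#'   the printed counts.
#'
#' @param ds An `eb_dataset`.
#' @param species A `species_id`.
#' @param group Ethnic group label, or `"all"`.
#' @param mode `"friedman"` or `"supplied"`.
#' @param supplied_value RPL value in \[0, 1\], required in supplied mode.
#' @return RPL as a single number in \[0, 1\].
#' @export
relative_popularity <- function(ds, species, group = "all",
                                mode = c("friedman", "supplied"),
                                supplied_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "supplied") {
    if (is.null(supplied_value)) {
      rlang::abort("supplied mode requires `supplied_value`", class = "eb_usage_error")
    }
    if (supplied_value < 0 || supplied_value > 1) {
      stop_domain("supplied RPL must lie in [0, 1]")
    }
    return(supplied_value)
  }
  stopifnot(inherits(ds, "eb_dataset"))
  check_species(ds, species)
  tab <- count_table(ds, group)
  if (nrow(tab) == 0) {
    stop_domain(sprintf("no use reports in group '%s'; RPL undefined", group))
  }
  fc <- tab$fc[match(species, tab$species_id)]
  if (is.na(fc)) fc <- 0L
  threshold <- max(tab$fc) / 2
  if (fc >= threshold) 1 else fc / threshold
}

#' Rank-order priority
#'
#' ROP = RPL * FL: the fidelity level corrected by the species' relative
#' popularity, used to rank species for pharmacological follow-up. The identity
#' holds to machine precision here; rounding to the customary integer display
#' happens only in the reporting layer.
#'
#' @param fl Fidelity level(s) in \[0, 100\].
#' @param rpl Relative popularity level(s) in \[0, 1\].
#' @return `rpl * fl`, vectorised.
#' @examples
#' rank_order_priority(85.71, 0.86) # 73.71, displayed as 74
#' @export
rank_order_priority <- function(fl, rpl) {
  if (any(is.na(fl)) || any(fl < 0 | fl > 100)) {
    stop_domain("fl must lie in [0, 100]")
  }
  if (any(is.na(rpl)) || any(rpl < 0 | rpl > 1)) {
    stop_domain("rpl must lie in [0, 1]")
  }
  rpl * fl
}

#' Species passing the minimum-citation filter
#'
#' Species cited by at least `threshold` distinct informants in the group.
#' With `group = "all"` a species is retained when it reaches the threshold in
#' any single ethnic group, matching the convention of evaluating indices only
#' for species claimed by three or more informants.
#'
#' @param ds An `eb_dataset`.
#' @param group Ethnic group label, or `"all"`.
#' @param threshold Minimum frequency of citation (default 3).
#' @return Character vector of `species_id`, sorted.
#' @export
min_citation_filter <- function(ds, group = "all", threshold = 3) {
  stopifnot(inherits(ds, "eb_dataset"), threshold >= 1)
  if (identical(group, "all")) {
    groups <- unique(ds$informants$ethnic_group)
    keep <- unique(unlist(lapply(groups, function(g) {
      tab <- count_table(ds, g)
      tab$species_id[tab$fc >= threshold]
    })))
    return(sort(keep))
  }
  tab <- count_table(ds, group)
  sort(tab$species_id[tab$fc >= threshold])
}

#' Fidelity / popularity / priority table
#'
#' One row per (species, ailment) pair in the group whose informant support
#' reaches `min_citations`, with Ns, FCs, FL, RPL (Friedman threshold mode) and
#' ROP = RPL * FL.
#'
#' @inheritParams fidelity_level
#' @param min_citations Minimum number of informants citing the species for
#'   the specific ailment (default 3).
#' @return A tibble with columns `species_id`, `ailment`, `group`, `ns`,
#'   `fcs`, `fl`, `rpl`, `rop`.
#' @export
priority_table <- function(ds, group = "all", min_citations = 3) {
  stopifnot(inherits(ds, "eb_dataset"))
  rep <- group_reports(ds, group)
  if (nrow(rep) == 0) {
    return(tibble::tibble(
      species_id = character(), ailment = character(), group = character(),
      ns = integer(), fcs = integer(), fl = double(), rpl = double(),
      rop = double()
    ))
  }
  counts <- count_table(ds, group)
  max_fc <- max(counts$fc)
  pairs <- rep |>
    dplyr::group_by(.data$species_id, .data$ailment) |>
    dplyr::summarise(ns = dplyr::n_distinct(.data$informant_id), .groups = "drop")
  pairs <- pairs[pairs$ns >= min_citations, , drop = FALSE]
  pairs$fcs <- counts$fc[match(pairs$species_id, counts$species_id)]
  pairs$group <- group
  pairs$fl <- 100 * pairs$ns / pairs$fcs
  pairs$rpl <- pmin(1, pairs$fcs / (max_fc / 2))
  pairs$rop <- pairs$rpl * pairs$fl
  dplyr::arrange(
    pairs[c("species_id", "ailment", "group", "ns", "fcs", "fl", "rpl", "rop")],
    .data$species_id, .data$ailment
  )
}
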