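#' Normalize ailment labels
#'
#' Case-folds, trims and collapses internal whitespace so that spelling
#' variants of the same ailment are counted once. Ethnobotanical surveys mix
#' free-text spellings; counting indices are only reproducible after a fixed,
#' documented normalization. Deliberate merges of genuinely different labels
#' (e.g. regional synonyms) are supplied through `synonyms`, never hard-coded.
#'
#' @param x Character vector of ailment labels.
#' @param synonyms Optional two-column data frame (`from`, `to`) applied after
#'   basic normalization; `from` is matched on the normalized form.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_ailment(c("  Common   Cold", "common cold")) # both "common cold"
#' @export
normalize_ailment <- function(x, synonyms = NULL) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("\\s+", " ", out)
  if (!is.null(synonyms)) {
    check_columns(synonyms, c("from", "to"), "synonyms")
    from <- normalize_ailment(synonyms$from)
    to <- normalize_ailment(synonyms$to)
    idx <- match(out, from)
    hit <- !is.na(idx)
    out[hit] <- to[idx[hit]]
  }
  out
}

#' Assemble a validated ethnobotanical survey dataset
#'
#' Bundles the three survey tables -- use reports (one row = one informant
#' citing one species for one ailment), informant demographics, and an
#' ailment-to-category map -- into a single validated object that all index
#' functions consume. Duplicate reports (the same informant repeating the same
#' species-ailment pair, e.g. for a different plant part or preparation) are
#' collapsed to a single use report with a warning: parts and preparations are
#' metadata, not part of the report key.
#'
#' @param reports Data frame with columns `informant_id`, `species_id`,
#'   `ailment`.
#' @param informants Data frame with columns `informant_id`, `ethnic_group`,
#'   `age`, `gender`, `education`, `religion` and optionally `occupation`.
#' @param species Optional data frame with columns `species_id`,
#'   `scientific_name` (plus any metadata). When omitted, a minimal species
#'   table is derived from the reports.
#' @param category_map Optional data frame with columns `ailment`, `category`.
#'   Reports whose normalized ailment has no entry keep `category = NA` and are
#'   reported in a warning.
#' @param synonyms Optional ailment synonym table passed to
#'   [normalize_ailment()].
#' @return An object of class `eb_dataset`: a list with tibbles `informants`,
#'   `species`, `reports` (with normalized `ailment` and resolved `category`)
#'   and `category_map`, plus attribute `n_duplicates_dropped`.
#' @seealso [read_eb_dataset()] to load the tables from delimited files.
#' @export
eb_dataset <- function(reports, informants, species = NULL, category_map = NULL,
                       synonyms = NULL) {
  reports <- tibble::as_tibble(reports)
  informants <- tibble::as_tibble(informants)
  check_columns(reports, c("informant_id", "species_id", "ailment"), "reports")
  check_columns(
    informants,
    c("informant_id", "ethnic_group", "age", "gender", "education", "religion"),
    "informants"
  )

  informants$informant_id <- as.character(informants$informant_id)
  if (anyDuplicated(informants$informant_id)) {
    dup <- unique(informants$informant_id[duplicated(informants$informant_id)])
    stop_integrity(sprintf(
      "duplicated informant_id in informants table: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (any(is.na(informants$age)) || any(informants$age < 0)) {
    stop_integrity("informant ages must be nonnegative and non-missing")
  }

  if (is.null(species)) {
    species <- tibble::tibble(
      species_id = sort(unique(as.character(reports$species_id)))
    )
    species$scientific_name <- species$species_id
  }
  species <- tibble::as_tibble(species)
  check_columns(species, "species_id", "species")
  species$species_id <- as.character(species$species_id)
  if (!"scientific_name" %in% names(species)) {
    species$scientific_name <- species$species_id
  }
  if (anyDuplicated(species$species_id)) {
    stop_integrity("duplicated species_id in species table")
  }
  if (any(!nzchar(species$scientific_name))) {
    stop_integrity("species scientific_name must be nonempty")
  }

  reports$informant_id <- as.character(reports$informant_id)
  reports$species_id <- as.character(reports$species_id)
  reports$ailment <- normalize_ailment(reports$ailment, synonyms)

  bad_inf <- setdiff(unique(reports$informant_id), informants$informant_id)
  if (length(bad_inf) > 0) {
    stop_integrity(sprintf(
      "reports reference unknown informant_id: %s",
      paste(utils::head(bad_inf, 5), collapse = ", ")
    ))
  }
  bad_sp <- setdiff(unique(reports$species_id), species$species_id)
  if (length(bad_sp) > 0) {
    stop_integrity(sprintf(
      "reports reference unknown species_id: %s",
      paste(utils::head(bad_sp, 5), collapse = ", ")
    ))
  }

  n_before <- nrow(reports)
  reports <- dplyr::distinct(reports, .data$informant_id, .data$species_id,
    .data$ailment,
    .keep_all = FALSE
  )
  n_dropped <- n_before - nrow(reports)
  if (n_dropped > 0) {
    rlang::warn(sprintf(
      "collapsed %d duplicate use report%s (same informant, species and ailment)",
      n_dropped, if (n_dropped > 1) "s" else ""
    ))
  }

  if (!is.null(category_map)) {
    category_map <- tibble::as_tibble(category_map)
    check_columns(category_map, c("ailment", "category"), "category map")
    category_map$ailment <- normalize_ailment(category_map$ailment, synonyms)
    category_map <- dplyr::distinct(category_map, .data$ailment, .data$category)
    if (anyDuplicated(category_map$ailment)) {
      stop_integrity("category map assigns some ailment to more than one category")
    }
  } else {
    category_map <- tibble::tibble(ailment = character(), category = character())
  }
  reports$category <- category_map$category[match(reports$ailment, category_map$ailment)]
  unmapped <- sort(unique(reports$ailment[is.na(reports$category)]))
  if (length(unmapped) > 0 && nrow(category_map) > 0) {
    rlang::warn(sprintf(
      "%d ailment label%s without a category mapping: %s",
      length(unmapped), if (length(unmapped) > 1) "s" else "",
      paste(utils::head(unmapped, 5), collapse = ", ")
    ))
  }

  out <- list(
    informants = informants,
    species = species,
    reports = reports,
    category_map = category_map
  )
  attr(out, "n_duplicates_dropped") <- n_dropped
  class(out) <- "eb_dataset"
  out
}

#' @export
print.eb_dataset <- function(x, ...) {
  cat("<eb_dataset>\n")
  cat(sprintf(
    "  %d informants in %d group(s): %s\n",
    nrow(x$informants), length(unique(x$informants$ethnic_group)),
    paste(sort(unique(x$informants$ethnic_group)), collapse = ", ")
  ))
  cat(sprintf(
    "  %d species, %d use reports, %d distinct ailments\n",
    nrow(x$species), nrow(x$reports), length(unique(x$reports$ailment))
  ))
  if (nrow(x$category_map) > 0) {
    cat(sprintf(
      "  %d ailment categories\n",
      length(unique(x$category_map$category))
    ))
  }
  invisible(x)
}

read_delim_auto <- function(path, what) {
  if (!file.exists(path)) {
    stop_schema(sprintf("%s file not found: %s", what, path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.delim(path,
    sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE, fileEncoding = "UTF-8"
  )
}

#' Load a survey dataset from delimited files
#'
#' Reads the reports, informants and (optionally) ailment-category tables from
#' CSV or TSV files (delimiter auto-detected from the header line; UTF-8) and
#' validates them through [eb_dataset()]. The category map may alternatively be
#' a JSON object mapping ailment labels to category labels.
#'
#' @param reports_path Path to the use-report table.
#' @param informants_path Path to the informant demographics table.
#' @param category_map_path Optional path to a two-column CSV/TSV
#'   (`ailment`, `category`) or a JSON object.
#' @param species_path Optional path to a species metadata table.
#' @param synonyms Optional ailment synonym table (see [normalize_ailment()]).
#' @return An `eb_dataset`.
#' @export
read_eb_dataset <- function(reports_path, informants_path,
                            category_map_path = NULL, species_path = NULL,
                            synonyms = NULL) {
  reports <- read_delim_auto(reports_path, "reports")
  informants <- read_delim_auto(informants_path, "informants")
  species <- if (!is.null(species_path)) read_delim_auto(species_path, "species")
  category_map <- NULL
  if (!is.null(category_map_path)) {
    if (grepl("\\.json$", category_map_path, ignore.case = TRUE)) {
      obj <- jsonlite::read_json(category_map_path, simplifyVector = TRUE)
      category_map <- tibble::tibble(
        ailment = names(obj),
        category = unname(unlist(obj))
      )
    } else {
      category_map <- read_delim_auto(category_map_path, "category map")
    }
  }
  eb_dataset(reports, informants,
    species = species, category_map = category_map,
    synonyms = synonyms
  )
}

#' Write a survey dataset back to CSV files
#'
#' Inverse of [read_eb_dataset()]: writes `reports.csv`, `informants.csv`,
#' `species.csv` and (if present) `category_map.csv` into `dir`. Reloading the
#' written files yields identical counts for every index.
#'
#' @param ds An `eb_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eb_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "eb_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reports = file.path(dir, "reports.csv"),
    informants = file.path(dir, "informants.csv"),
    species = file.path(dir, "species.csv")
  )
  utils::write.csv(ds$reports[c("informant_id", "species_id", "ailment")],
    paths["reports"],
    row.names = FALSE
  )
  utils::write.csv(ds$informants, paths["informants"], row.names = FALSE)
  utils::write.csv(ds$species, paths["species"], row.names = FALSE)
  if (nrow(ds$category_map) > 0) {
    paths <- c(paths, category_map = file.path(dir, "category_map.csv"))
    utils::write.csv(ds$category_map, paths["category_map"], row.names = FALSE)
  }
  invisible(paths)
}

#' Informant group labels and sizes
#'
#' @param ds An `eb_dataset`.
#' @return Named integer vector of informant counts per ethnic group.
#' @export
group_sizes <- function(ds) {
  stopifnot(inherits(ds, "eb_dataset"))
  tab <- table(ds$informants$ethnic_group)
  stats::setNames(as.integer(tab), names(tab))
}

#' Number of informants in a group
#'
#' The denominator N_g of the use value index: the number of informants
#' interviewed in the group (`"all"` pools every group).
#'
#' @param ds An `eb_dataset`.
#' @param group Ethnic group label, or `"all"`.
#' @return Integer count.
#' @export
informant_count <- function(ds, group = "all") {
  stopifnot(inherits(ds, "eb_dataset"))
  if (identical(group, "all")) {
    return(nrow(ds$informants))
  }
  check_group(ds, group)
  sum(ds$informants$ethnic_group == group)
}

check_group <- function(ds, group) {
  if (identical(group, "all")) {
    return(invisible(group))
  }
  known <- unique(ds$informants$ethnic_group)
  if (!group %in% known) {
    stop_domain(sprintf(
      "unknown group label '%s' (known: %s)",
      group, paste(sort(known), collapse = ", ")
    ))
  }
  invisible(group)
}

check_species <- function(ds, species) {
  if (!species %in% ds$species$species_id) {
    stop_domain(sprintf("unknown species_id '%s'", species))
  }
  invisible(species)
}

# reports restricted to a group ("all" = no restriction)
group_reports <- function(ds, group) {
  check_group(ds, group)
  if (identical(group, "all")) {
    return(ds$reports)
  }
  ids <- ds$informants$informant_id[ds$informants$ethnic_group == group]
  ds$reports[ds$reports$informant_id %in% ids, , drop = FALSE]
}
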