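# Independent brute-force recomputation of every count and index by plain
# row-wise loops over the report table. Deliberately naive: no grouping
# verbs, no shared code with the implementation.

naive_group_rows <- function(ds, group) {
  if (identical(group, "all")) {
    seq_len(nrow(ds$reports))
  } else {
    ids <- ds$informants$informant_id[ds$informants$ethnic_group == group]
    which(ds$reports$informant_id %in% ids)
  }
}

naive_fc <- function(ds, species, group = "all") {
  seen <- character()
  for (i in naive_group_rows(ds, group)) {
    if (ds$reports$species_id[i] == species) {
      seen <- union(seen, ds$reports$informant_id[i])
    }
  }
  length(seen)
}

naive_ur <- function(ds, species, group = "all") {
  k <- 0L
  for (i in naive_group_rows(ds, group)) {
    if (ds$reports$species_id[i] == species) k <- k + 1L
  }
  k
}

naive_nu <- function(ds, species, group = "all") {
  seen <- character()
  for (i in naive_group_rows(ds, group)) {
    if (ds$reports$species_id[i] == species) {
      seen <- union(seen, ds$reports$ailment[i])
    }
  }
  length(seen)
}

naive_icf_parts <- function(ds, category, group = "all") {
  nur <- 0L
  taxa <- character()
  for (i in naive_group_rows(ds, group)) {
    cat_i <- ds$reports$category[i]
    if (!is.na(cat_i) && cat_i == category) {
      nur <- nur + 1L
      taxa <- union(taxa, ds$reports$species_id[i])
    }
  }
  list(nur = nur, nt = length(taxa))
}

naive_ns <- function(ds, species, ailment, group = "all") {
  seen <- character()
  for (i in naive_group_rows(ds, group)) {
    if (ds$reports$species_id[i] == species && ds$reports$ailment[i] == ailment) {
      seen <- union(seen, ds$reports$informant_id[i])
    }
  }
  length(seen)
}

naive_rpl <- function(ds, species, group = "all") {
  cited <- unique(ds$reports$species_id[naive_group_rows(ds, group)])
  fcs <- vapply(cited, function(s) naive_fc(ds, s, group), integer(1))
  half <- max(fcs) / 2
  fc <- naive_fc(ds, species, group)
  if (fc >= half) 1 else fc / half
}

# random micro-survey: <= 10 informants in 1-2 groups, <= 8 species,
# ailments spread over up to 3 categories
random_micro_dataset <- function(seed) {
  set.seed(seed)
  n_inf <- sample(3:10, 1)
  n_grp <- sample(1:2, 1)
  n_sp <- sample(2:8, 1)
  n_ail <- sample(2:6, 1)
  informants <- tibble::tibble(
    informant_id = paste0("i", seq_len(n_inf)),
    ethnic_group = sample(paste0("grp", seq_len(n_grp)), n_inf, replace = TRUE),
    age = sample(35:77, n_inf, replace = TRUE),
    gender = sample(c("Male", "Female"), n_inf, replace = TRUE),
    education = "Primary",
    religion = "Protestant"
  )
  species <- tibble::tibble(species_id = paste0("s", seq_len(n_sp)))
  ailments <- paste0("ail", seq_len(n_ail))
  n_rep <- sample(5:30, 1)
  reports <- tibble::tibble(
    informant_id = sample(informants$informant_id, n_rep, replace = TRUE),
    species_id = sample(species$species_id, n_rep, replace = TRUE),
    ailment = sample(ailments, n_rep, replace = TRUE)
  )
  cmap <- tibble::tibble(
    ailment = ailments,
    category = paste0("cat", (seq_len(n_ail) - 1) %% min(3, n_ail) + 1)
  )
  suppressWarnings(
    eb_dataset(reports, informants, species = species, category_map = cmap)
  )
}
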