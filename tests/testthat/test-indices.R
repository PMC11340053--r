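test_that("use value equals use reports over group size, with audit columns", {
  # 38 reports from 16 informants over 14 ailments among 63 informants
  ds <- reconstruct_uv_dataset(fc = 16, ur = 38, nu = 14, n_informants = 63, group = "Oromo")
  row <- use_value(ds, "sp1", "Oromo")
  expect_equal(row$fc, 16)
  expect_equal(row$ur, 38)
  expect_equal(row$nu, 14)
  expect_equal(round_half_up(row$uv, 3), 0.603)

  ds2 <- reconstruct_uv_dataset(fc = 14, ur = 21, nu = 8, n_informants = 63, group = "Sidama")
  expect_equal(round_half_up(use_value(ds2, "sp1", "Sidama")$uv, 3), 0.333)

  # a listed species nobody cites has UV exactly 0
  ds3 <- eb_dataset(
    tibble::tibble(informant_id = "inf001", species_id = "sp1", ailment = "x"),
    ds$informants,
    species = tibble::tibble(species_id = c("sp1", "sp2"))
  )
  expect_equal(use_value(ds3, "sp2", "Oromo")$uv, 0)
  expect_error(use_value(ds, "sp1", "nope"), class = "eb_domain_error")
})

test_that("UV is invariant under duplicating every informant with their reports", {
  for (seed in 1:10) {
    ds <- random_micro_dataset(seed)
    inf2 <- ds$informants
    inf2$informant_id <- paste0(inf2$informant_id, "_dup")
    rep2 <- ds$reports[1:3]
    rep2$informant_id <- paste0(rep2$informant_id, "_dup")
    dbl <- eb_dataset(
      rbind(ds$reports[1:3], rep2),
      rbind(ds$informants, inf2),
      species = ds$species, category_map = ds$category_map
    )
    tab1 <- uv_table(ds, "all", min_citations = 1)
    tab2 <- uv_table(dbl, "all", min_citations = 1)
    expect_equal(tab2$uv[match(tab1$species_id, tab2$species_id)], tab1$uv)
  }
})

test_that("ICF reproduces printed worked examples from their integer ingredients", {
  # 16 reports over 3 species
  r1 <- icf(reconstruct_icf_dataset(nur = 16, nt = 3), "focal category", "Sidama")
  expect_equal(round_half_up(r1$icf, 2), 0.87)
  # 4 reports all naming one species: complete consensus
  r2 <- icf(reconstruct_icf_dataset(nur = 4, nt = 1), "focal category", "Sidama")
  expect_equal(r2$icf, 1)
  # every report names a different species: no consensus
  r3 <- icf(reconstruct_icf_dataset(nur = 3, nt = 3), "focal category", "Sidama")
  expect_equal(r3$icf, 0)
  expect_error(icf(reconstruct_icf_dataset(4, 2), "no such category"),
    class = "eb_domain_error"
  )
})

test_that("ICF with fewer than two reports is undefined, not a division by zero", {
  ds <- reconstruct_icf_dataset(nur = 1, nt = 1)
  expect_warning(row <- icf(ds, "focal category", "Sidama"), "undefined")
  expect_true(is.na(row$icf))
  expect_equal(row$nur, 1)
})

test_that("ICF bounds and boundary characterisations hold on random micro-surveys", {
  for (seed in 1:25) {
    ds <- random_micro_dataset(seed)
    tab <- icf_table(ds, "all")
    tab <- tab[tab$nur >= 2, ]
    if (nrow(tab) == 0) next
    expect_true(all(tab$icf >= 0 & tab$icf <= 1))
    expect_equal(tab$icf == 1, tab$nt == 1)
    expect_equal(tab$icf == 0, tab$nt == tab$nur)
  }
})

test_that("ICF is invariant to species relabelings that preserve the taxon count", {
  ds <- random_micro_dataset(11)
  before <- icf_table(ds, "all")
  perm <- sample(ds$species$species_id)
  relab <- stats::setNames(perm, ds$species$species_id)
  rep2 <- ds$reports[1:3]
  rep2$species_id <- unname(relab[rep2$species_id])
  ds2 <- eb_dataset(rep2, ds$informants,
    species = ds$species,
    category_map = ds$category_map
  )
  after <- icf_table(ds2, "all")
  expect_equal(after[c("category", "nur", "nt", "icf")], before[c("category", "nur", "nt", "icf")])
})

test_that("fidelity level is the share of citing informants naming the ailment", {
  r <- fidelity_level(
    reconstruct_fl_dataset(ns = 3, fcs = 4), "sp1", "focal ailment", "Gedeo"
  )
  expect_equal(r$fl, 75)
  r2 <- fidelity_level(
    reconstruct_fl_dataset(ns = 5, fcs = 5), "sp1", "focal ailment", "Gedeo"
  )
  expect_equal(r2$fl, 100)
  r3 <- fidelity_level(
    reconstruct_fl_dataset(ns = 6, fcs = 7), "sp1", "focal ailment", "Gedeo"
  )
  expect_equal(round_half_up(r3$fl, 2), 85.71)
  # FL undefined (not zero) when the species is never cited for the ailment
  expect_error(
    fidelity_level(reconstruct_fl_dataset(2, 3), "sp1", "unseen ailment", "Gedeo"),
    class = "eb_domain_error"
  )
})

test_that("FL never exceeds 100 and reaches it only under unanimous citation", {
  for (seed in 1:25) {
    ds <- random_micro_dataset(seed)
    tab <- priority_table(ds, "all", min_citations = 1)
    expect_true(all(tab$fl <= 100 + 1e-12))
    unanimous <- tab$ns == tab$fcs
    expect_equal(tab$fl == 100, unanimous)
  }
})

test_that("relative popularity follows the half-of-maximum threshold rule", {
  # two species with FC 10 and 2: threshold 5, minor species scores 2/5
  reports <- tibble::tibble(
    informant_id = c(sprintf("i%02d", 1:10), "i01", "i02"),
    species_id = c(rep("big", 10), "small", "small"),
    ailment = "x"
  )
  informants <- tibble::tibble(
    informant_id = sprintf("i%02d", 1:10), ethnic_group = "g",
    age = 50L, gender = "Male", education = "Primary", religion = "Protestant"
  )
  ds <- eb_dataset(reports, informants)
  expect_equal(relative_popularity(ds, "big", "g"), 1)
  expect_equal(relative_popularity(ds, "small", "g"), 0.4)
  # supplied mode is a validated pass-through
  expect_equal(relative_popularity(ds, "small", "g",
    mode = "supplied",
    supplied_value = 0.86
  ), 0.86)
  expect_error(relative_popularity(ds, "small", "g", mode = "supplied"),
    class = "eb_usage_error"
  )
  expect_error(
    relative_popularity(ds, "small", "g", mode = "supplied", supplied_value = 1.2),
    class = "eb_domain_error"
  )
})

test_that("rank-order priority is the exact product and rounds half-up for display", {
  expect_equal(rank_order_priority(85.71, 0.86), 85.71 * 0.86)
  expect_equal(round_half_up(rank_order_priority(85.71, 0.86)), 74)
  expect_equal(round_half_up(rank_order_priority(77.78, 0.78)), 61)
  expect_equal(rank_order_priority(100, 1), 100)
  expect_error(rank_order_priority(120, 0.5), class = "eb_domain_error")
  expect_error(rank_order_priority(50, 1.5), class = "eb_domain_error")
})

test_that("the minimum-citation filter keeps species at or above the threshold", {
  reports <- tibble::tibble(
    informant_id = c("i1", "i2", "i3", "i1", "i2"),
    species_id = c("A", "A", "A", "B", "B"),
    ailment = "x"
  )
  informants <- tibble::tibble(
    informant_id = paste0("i", 1:3), ethnic_group = "g",
    age = 50L, gender = "Male", education = "Primary", religion = "Protestant"
  )
  ds <- eb_dataset(reports, informants)
  expect_equal(min_citation_filter(ds, "g", threshold = 3), "A")
  expect_equal(min_citation_filter(ds, "g", threshold = 1), c("A", "B"))
  # group = "all" keeps a species that clears the bar in any single group
  ds2 <- random_micro_dataset(5)
  all_kept <- min_citation_filter(ds2, "all", threshold = 2)
  per_group <- unique(unlist(lapply(
    unique(ds2$informants$ethnic_group),
    function(g) min_citation_filter(ds2, g, threshold = 2)
  )))
  expect_setequal(all_kept, per_group)
})

test_that("the priority table satisfies the ROP identity and matches single calls", {
  ds <- random_micro_dataset(13)
  tab <- priority_table(ds, "all", min_citations = 1)
  expect_equal(tab$rop, tab$rpl * tab$fl)
  for (k in seq_len(min(nrow(tab), 5))) {
    single <- fidelity_level(ds, tab$species_id[k], tab$ailment[k], "all")
    expect_equal(single$fl, tab$fl[k])
    expect_equal(
      relative_popularity(ds, tab$species_id[k], "all"),
      tab$rpl[k]
    )
  }
})
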