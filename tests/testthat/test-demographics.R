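toy_scores_dataset <- function() {
  informants <- tibble::tibble(
    informant_id = c("A", "B", "C"),
    ethnic_group = "g", age = c(40L, 50L, 60L),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  reports <- tibble::tibble(
    informant_id = c("A", "A", "A"),
    species_id = c("S1", "S1", "S2"),
    ailment = c("x", "y", "x")
  )
  eb_dataset(reports, informants)
}

test_that("knowledge scores count distinct species, zero for silent informants", {
  ds <- toy_scores_dataset()
  sc <- knowledge_scores(ds)
  expect_equal(sc$n_species_cited[sc$informant_id == "A"], 2L)
  expect_equal(sc$n_species_cited[sc$informant_id == "B"], 0L)
  expect_equal(nrow(sc), 3)
})

test_that("level means use the sample standard deviation", {
  scores <- tibble::tibble(
    informant_id = c("A", "B", "C"),
    n_species_cited = c(2L, 4L, 6L)
  )
  informants <- tibble::tibble(
    informant_id = c("A", "B", "C"), ethnic_group = "g",
    age = c(40L, 41L, 42L), gender = c("Male", "Male", "Female"),
    education = "Primary", religion = "Protestant"
  )
  cmp <- compare_groups(scores, informants, "gender")
  lev <- cmp$levels
  expect_equal(lev$mean[lev$label == "Male"], 3)
  expect_equal(lev$sd[lev$label == "Male"], stats::sd(c(2, 4))) # n - 1 denominator
  expect_equal(sum(lev$n), 3)
})

test_that("four age classes give a Kruskal-Wallis test with three degrees of freedom", {
  set.seed(1)
  n <- 40
  informants <- tibble::tibble(
    informant_id = sprintf("i%02d", 1:n), ethnic_group = "g",
    age = rep(c(38L, 50L, 60L, 70L), each = 10),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  scores <- tibble::tibble(
    informant_id = informants$informant_id,
    n_species_cited = rpois(n, 6)
  )
  cmp <- compare_groups(scores, informants, "age")
  expect_equal(cmp$test_name, "Kruskal-Wallis")
  expect_equal(cmp$df, 3)
  expect_equal(nrow(cmp$levels), 4)
})

test_that("identical scores in every level give statistic 0 and p 1", {
  informants <- tibble::tibble(
    informant_id = paste0("i", 1:6), ethnic_group = "g",
    age = rep(c(40L, 50L, 60L), each = 2),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  scores <- tibble::tibble(
    informant_id = informants$informant_id, n_species_cited = 5L
  )
  expect_warning(cmp <- compare_groups(scores, informants, "age"), "empty level")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the two-level rank-sum statistic matches exhaustive ranking", {
  informants <- tibble::tibble(
    informant_id = paste0("i", 1:6), ethnic_group = "g", age = 50L,
    gender = rep(c("Female", "Male"), each = 3),
    education = "Primary", religion = "Protestant"
  )
  scores <- tibble::tibble(
    informant_id = informants$informant_id,
    n_species_cited = c(1L, 2L, 3L, 4L, 5L, 6L)
  )
  cmp <- compare_groups(scores, informants, "gender")
  expect_equal(cmp$test_name, "Wilcoxon rank-sum")
  # brute force: W = (rank sum of first factor level) - n1 (n1 + 1) / 2;
  # Female holds ranks 1, 2, 3 so W = 6 - 6 = 0
  ranks <- rank(scores$n_species_cited)
  w_oracle <- sum(ranks[informants$gender == "Female"]) - 3 * 4 / 2
  expect_equal(cmp$statistic, w_oracle)
  expect_true(is.na(cmp$df))
})

test_that("rank tests are invariant under strictly monotone score transforms", {
  set.seed(21)
  informants <- tibble::tibble(
    informant_id = sprintf("i%02d", 1:30), ethnic_group = "g",
    age = sample(c(38L, 50L, 60L, 70L), 30, replace = TRUE),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  base <- sample(1:12, 30, replace = TRUE)
  s1 <- tibble::tibble(informant_id = informants$informant_id, n_species_cited = base)
  cmp1 <- compare_groups(s1, informants, "age")
  s2 <- s1
  s2$n_species_cited <- as.integer(base^2 + 3L) # strictly monotone on nonnegatives
  cmp2 <- compare_groups(s2, informants, "age")
  expect_equal(cmp2$statistic, cmp1$statistic)
  expect_equal(cmp2$p_value, cmp1$p_value)
})

test_that("shifting every score leaves the test statistic and R-squared unchanged", {
  set.seed(8)
  informants <- tibble::tibble(
    informant_id = sprintf("i%02d", 1:40), ethnic_group = "g",
    age = sample(35:77, 40, replace = TRUE),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  s1 <- tibble::tibble(
    informant_id = informants$informant_id,
    n_species_cited = sample(0:10, 40, replace = TRUE)
  )
  s2 <- s1
  s2$n_species_cited <- s1$n_species_cited + 7L
  expect_equal(
    compare_groups(s2, informants, "age")$statistic,
    compare_groups(s1, informants, "age")$statistic
  )
  expect_equal(
    age_knowledge_fit(s2, informants)$r_squared,
    age_knowledge_fit(s1, informants)$r_squared
  )
})

test_that("the age regression recovers exact fits and rejects degenerate input", {
  informants <- tibble::tibble(
    informant_id = paste0("i", 1:5), ethnic_group = "g",
    age = c(35L, 45L, 55L, 65L, 75L),
    gender = "Male", education = "Primary", religion = "Protestant"
  )
  lin <- tibble::tibble(
    informant_id = informants$informant_id,
    n_species_cited = as.integer(2 + informants$age %/% 5)
  )
  fit_lin <- suppressWarnings( # exact fit: lm's perfect-fit note is expected
    age_knowledge_fit(lin, informants, curvilinear = FALSE)
  )
  expect_equal(fit_lin$r_squared, 1)
  expect_named(fit_lin$coefficients, c("intercept", "linear"))

  # three points, three parameters: the quadratic interpolates exactly
  inf3 <- informants[1:3, ]
  inf3$age <- c(30L, 50L, 70L)
  sc3 <- tibble::tibble(
    informant_id = inf3$informant_id, n_species_cited = c(3L, 7L, 5L)
  )
  fit_q <- age_knowledge_fit(sc3, inf3, curvilinear = TRUE)
  expect_equal(fit_q$r_squared, 1)
  expect_equal(fit_q$fitted_curve(c(30, 50, 70)), c(3, 7, 5))

  inf_const <- informants
  inf_const$age <- 50L
  expect_error(age_knowledge_fit(lin, inf_const, curvilinear = FALSE),
    class = "eb_domain_error"
  )
})

test_that("the quadratic model never fits worse than the straight line", {
  for (seed in c(3, 4, 5)) {
    cfg <- sim_config(seed = seed)
    inf <- simulate_informants(cfg)
    sc <- simulate_knowledge_counts(cfg, inf)
    r2_lin <- age_knowledge_fit(sc, inf, curvilinear = FALSE)$r_squared
    r2_quad <- age_knowledge_fit(sc, inf, curvilinear = TRUE)$r_squared
    expect_gte(r2_quad, r2_lin)
  }
})

test_that("age binning uses the survey's class edges", {
  expect_equal(as.character(age_bin(c(44, 45, 64, 65, 77))),
    c("35-44", "45-54", "55-64", "65+", "65+"))
  expect_warning(b <- age_bin(c(30, 40)), "below the lowest")
  expect_equal(as.character(b), c("<35", "35-44"))
})

test_that("the knowledge summary covers every demographic variable", {
  ds <- simulate_study(sim_config(seed = 5))
  tab <- knowledge_summary(ds)
  expect_setequal(unique(tab$variable), c("age", "gender", "education", "religion"))
  expect_equal(sum(tab$n[tab$variable == "age"]), 189)
  expect_true(all(tab$sd >= 0))
})
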