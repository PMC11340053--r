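#' Per-informant knowledge scores
#'
#' The knowledge score of an informant is the number of distinct medicinal
#' species they cite, the response variable of every socio-demographic
#' comparison. Informants with no use reports score 0.
#'
#' @param ds An `eb_dataset`.
#' @return A tibble with columns `informant_id`, `n_species_cited`, one row
#'   per informant in the dataset.
#' @export
knowledge_scores <- function(ds) {
  stopifnot(inherits(ds, "eb_dataset"))
  cited <- ds$reports |>
    dplyr::group_by(.data$informant_id) |>
    dplyr::summarise(n_species_cited = dplyr::n_distinct(.data$species_id), .groups = "drop")
  out <- tibble::tibble(informant_id = ds$informants$informant_id)
  out$n_species_cited <- cited$n_species_cited[match(out$informant_id, cited$informant_id)]
  out$n_species_cited[is.na(out$n_species_cited)] <- 0L
  out$n_species_cited <- as.integer(out$n_species_cited)
  out
}

#' Age-class binning
#'
#' Assigns ages to the survey's four age classes (35-44, 45-54, 55-64, 65+).
#' Ages below the lowest edge fall into an out-of-range bin with a warning;
#' alternative edges can be supplied for other designs.
#'
#' @param age Integer vector of ages in years.
#' @param breaks Increasing vector of lower bin edges; the last bin is
#'   open-ended.
#' @return Factor of bin labels, levels ordered by age.
#' @examples
#' age_bin(c(44, 45, 65)) # "35-44", "45-54", "65+"
#' @export
age_bin <- function(age, breaks = c(35, 45, 55, 65)) {
  stopifnot(is.numeric(age), length(breaks) >= 2, !is.unsorted(breaks))
  labels <- c(
    paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
    paste0(breaks[length(breaks)], "+")
  )
  under <- paste0("<", breaks[1])
  idx <- findInterval(age, breaks)
  if (any(idx == 0)) {
    rlang::warn(sprintf(
      "%d age(s) below the lowest bin edge (%d); assigned to out-of-range bin '%s'",
      sum(idx == 0), breaks[1], under
    ))
  }
  out <- c(under, labels)[idx + 1]
  factor(out, levels = if (any(idx == 0)) c(under, labels) else labels)
}

demographic_variable <- function(informants, variable) {
  switch(variable,
    age = age_bin(informants$age),
    gender = factor(informants$gender),
    education = factor(informants$education),
    religion = factor(informants$religion),
    stop_domain(sprintf(
      "unknown demographic variable '%s' (use age, gender, education or religion)",
      variable
    ))
  )
}

#' Compare knowledge scores across demographic groups
#'
#' Nonparametric comparison of per-informant knowledge scores across the
#' levels of one demographic variable: a Kruskal-Wallis rank test (with tie
#' correction, df = levels - 1) for three or more levels, and the two-sample
#' Wilcoxon rank-sum test for exactly two levels (the conventional choice for
#' independent gender groups). Per-level means use the sample (n - 1) standard
#' deviation. Empty levels are dropped with a warning; when every score is
#' identical the statistic is 0 and p = 1 by convention (there is no evidence
#' of any difference).
#'
#' @param scores Tibble from [knowledge_scores()].
#' @param informants Informant demographics table.
#' @param variable One of `"age"`, `"gender"`, `"education"`, `"religion"`.
#' @return An object of class `eb_group_comparison`: a list with `variable`,
#'   `levels` (tibble of label, n, mean, sd), `test_name`, `statistic`, `df`
#'   (NA for the rank-sum test) and `p_value`.
#' @export
compare_groups <- function(scores, informants, variable) {
  check_columns(scores, c("informant_id", "n_species_cited"), "scores")
  informants <- tibble::as_tibble(informants)
  x <- scores$n_species_cited[match(informants$informant_id, scores$informant_id)]
  if (any(is.na(x))) {
    stop_integrity("some informants have no knowledge score")
  }
  g <- demographic_variable(informants, variable)
  empty <- levels(g)[table(g) == 0]
  if (length(empty) > 0) {
    rlang::warn(sprintf("dropping empty level(s): %s", paste(empty, collapse = ", ")))
    g <- droplevels(g)
  }
  k <- nlevels(g)
  if (k < 2) {
    stop_domain("need at least two nonempty levels to compare")
  }
  lev <- tibble::tibble(
    label = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, stats::sd))
  )
  if (length(unique(x)) == 1) {
    test_name <- if (k == 2) "Wilcoxon rank-sum" else "Kruskal-Wallis"
    res <- list(statistic = 0, df = if (k > 2) k - 1L else NA_integer_, p_value = 1)
  } else if (k == 2) {
    ht <- stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE)
    test_name <- "Wilcoxon rank-sum"
    res <- list(
      statistic = unname(ht$statistic), df = NA_integer_,
      p_value = ht$p.value
    )
  } else {
    ht <- stats::kruskal.test(x, g)
    test_name <- "Kruskal-Wallis"
    res <- list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value
    )
  }
  structure(
    list(
      variable = variable, levels = lev, test_name = test_name,
      statistic = res$statistic, df = res$df, p_value = res$p_value
    ),
    class = "eb_group_comparison"
  )
}

#' @export
print.eb_group_comparison <- function(x, ...) {
  cat(sprintf("<knowledge comparison by %s>\n", x$variable))
  for (i in seq_len(nrow(x$levels))) {
    cat(sprintf(
      "  %-20s n = %3d   %.2f +/- %.2f\n",
      x$levels$label[i], x$levels$n[i], x$levels$mean[i], x$levels$sd[i]
    ))
  }
  df_txt <- if (is.na(x$df)) "" else sprintf(", df = %d", x$df)
  cat(sprintf(
    "  %s: statistic = %.3f%s, p = %s\n",
    x$test_name, x$statistic, df_txt, format_p(x$p_value)
  ))
  invisible(x)
}

# display convention: 4 decimals, floored at 0.0001; raw value kept in object
format_p <- function(p) {
  if (is.na(p)) {
    return("NA")
  }
  if (p < 1e-4) "0.0001" else sprintf("%.4f", p)
}

#' Regression of knowledge on age
#'
#' Least-squares fit of the knowledge score on age, optionally with a
#' quadratic term to capture the curvilinear pattern in which knowledge rises
#' through middle age and falls again among the oldest informants. The
#' returned R-squared is the coefficient of determination of the chosen model.
#'
#' @param scores Tibble from [knowledge_scores()].
#' @param informants Informant demographics table.
#' @param curvilinear Include the age^2 term (default `TRUE`).
#' @return An object of class `eb_age_fit`: list with `coefficients`
#'   (intercept, linear and -- when curvilinear -- quadratic), `r_squared`,
#'   `fitted_curve` (a function of age), `curvilinear` and the underlying
#'   `model`.
#' @export
age_knowledge_fit <- function(scores, informants, curvilinear = TRUE) {
  check_columns(scores, c("informant_id", "n_species_cited"), "scores")
  informants <- tibble::as_tibble(informants)
  df <- tibble::tibble(
    age = as.numeric(informants$age),
    score = as.numeric(
      scores$n_species_cited[match(informants$informant_id, scores$informant_id)]
    )
  )
  if (any(is.na(df$score))) {
    stop_integrity("some informants have no knowledge score")
  }
  n_distinct_ages <- length(unique(df$age))
  needed <- if (curvilinear) 3 else 2
  if (n_distinct_ages < needed) {
    stop_domain(sprintf(
      "need at least %d distinct ages for this fit (got %d)",
      needed, n_distinct_ages
    ))
  }
  fml <- if (curvilinear) score ~ age + I(age^2) else score ~ age
  model <- stats::lm(fml, data = df)
  coefs <- stats::coef(model)
  names(coefs) <- c("intercept", "linear", if (curvilinear) "quadratic")
  r2 <- summary(model)$r.squared
  fitted_curve <- function(age) {
    y <- coefs[["intercept"]] + coefs[["linear"]] * age
    if (curvilinear) y <- y + coefs[["quadratic"]] * age^2
    unname(y)
  }
  structure(
    list(
      coefficients = coefs, r_squared = r2, fitted_curve = fitted_curve,
      curvilinear = curvilinear, model = model
    ),
    class = "eb_age_fit"
  )
}

#' @export
print.eb_age_fit <- function(x, ...) {
  kind <- if (x$curvilinear) "quadratic" else "linear"
  cat(sprintf("<age-knowledge %s fit>\n", kind))
  cat("  coefficients:", paste(sprintf(
    "%s = %.4g", names(x$coefficients),
    x$coefficients
  ), collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.3f\n", x$r_squared))
  invisible(x)
}

#' Knowledge summary across demographic variables
#'
#' Per-level informant counts, means and standard deviations of the knowledge
#' score together with the group-test p-value, for each demographic variable:
#' the standard summary table of an ethnobotanical knowledge survey.
#'
#' @param ds An `eb_dataset`.
#' @param variables Demographic variables to summarise.
#' @return A tibble with columns `variable`, `level`, `n`, `mean`, `sd`,
#'   `p_value` (raw), `p_display` (4 decimals, floored at 0.0001).
#' @export
knowledge_summary <- function(ds, variables = c("age", "gender", "education", "religion")) {
  stopifnot(inherits(ds, "eb_dataset"))
  scores <- knowledge_scores(ds)
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(scores, ds$informants, v)
    out <- cmp$levels
    out$variable <- v
    out$p_value <- cmp$p_value
    out$p_display <- format_p(cmp$p_value)
    out
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "label"] <- "level"
  out[c("variable", "level", "n", "mean", "sd", "p_value", "p_display")]
}

#' Scatter plot of knowledge against age with the fitted curve
#'
#' @param ds An `eb_dataset`.
#' @param curvilinear Fit a quadratic (default) or straight line.
#' @return A ggplot object.
#' @export
plot_age_knowledge <- function(ds, curvilinear = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_age_knowledge() requires the ggplot2 package")
  }
  scores <- knowledge_scores(ds)
  fit <- age_knowledge_fit(scores, ds$informants, curvilinear = curvilinear)
  df <- tibble::tibble(
    age = as.numeric(ds$informants$age),
    score = scores$n_species_cited[match(ds$informants$informant_id, scores$informant_id)]
  )
  grid <- tibble::tibble(age = seq(min(df$age), max(df$age), length.out = 200))
  grid$score <- fit$fitted_curve(grid$age)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "Age (years)", y = "Distinct medicinal species cited",
      subtitle = sprintf("R² = %.2f", fit$r_squared)
    )
}
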