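#' Display rounding for index tables
#'
#' Centralised display conventions: UV to 3 decimals, ICF to 2, FL to 2, RPL
#' to 2, ROP to the nearest integer -- all half-up, matching how these indices
#' are customarily printed. Raw full-precision values stay in the computed
#' tables; only rendered output is rounded.
#'
#' @param tab An index tibble (from [uv_table()], [icf_table()] or
#'   [priority_table()]).
#' @return The tibble with its index columns rounded for display.
#' @export
format_index_table <- function(tab) {
  digits <- c(uv = 3, icf = 2, fl = 2, rpl = 2, rop = 0)
  for (col in intersect(names(digits), names(tab))) {
    tab[[col]] <- round_half_up(tab[[col]], digits[[col]])
  }
  tab
}

#' Render a data frame as a markdown pipe table
#'
#' @param df A data frame (already display-rounded).
#' @return Character vector of markdown lines.
#' @export
format_markdown_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("| ", paste(rep("---", ncol(df)), collapse = " | "), " |")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}

write_table_pair <- function(tab, out_dir, stem) {
  shown <- format_index_table(tab)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  md <- file.path(out_dir, paste0(stem, ".md"))
  utils::write.csv(shown, csv, row.names = FALSE)
  writeLines(format_markdown_table(shown), md)
  c(csv, md)
}

#' Write a run manifest
#'
#' Records what produced the files in an output directory: the command, the
#' configuration snapshot, MD5 digests of the input files, the package version
#' and a timestamp. A run is replayable from its manifest.
#'
#' @param out_dir Output directory.
#' @param command Name of the command that ran.
#' @param config Configuration list to snapshot (may be `NULL`).
#' @param inputs Character vector of input file paths to digest.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, command, config = NULL, inputs = character()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  manifest <- list(
    command = command,
    config = config,
    input_digests = digests,
    tool_version = as.character(utils::packageVersion("ethnoindices")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

config_snapshot <- function(cfg) {
  lapply(unclass(cfg), function(x) {
    if (inherits(x, "tbl_df") || is.data.frame(x)) as.list(x) else x
  })
}

#' Run the survey simulator and write the dataset
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()], or `NULL` for the default configuration.
#' @param seed Optional seed override recorded in the manifest.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(out_dir, config = NULL, seed = NULL) {
  cfg <- config %||% sim_config()
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
  }
  ds <- simulate_study(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_eb_dataset(ds, out_dir)
  snap <- config_snapshot(cfg)
  if (!is.null(seed)) snap$seed_override <- as.integer(seed)
  write_manifest(out_dir, "simulate", config = snap)
  invisible(out_dir)
}

#' Compute and write all index tables for a dataset
#'
#' Writes, for the requested group (or each ethnic group plus the pooled
#' survey), the use-value, consensus and fidelity/priority tables as CSV and
#' markdown with the standard display rounding, plus a manifest.
#'
#' @param ds An `eb_dataset`.
#' @param out_dir Output directory.
#' @param group Group label, `"all"`, or `NULL` (default) for every group and
#'   the pooled survey.
#' @param min_citations Minimum-citation threshold (default 3).
#' @param inputs Input file paths to digest into the manifest.
#' @return Invisibly, the files written.
#' @export
run_indices <- function(ds, out_dir, group = NULL, min_citations = 3,
                        inputs = character()) {
  stopifnot(inherits(ds, "eb_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- group %||% c(sort(unique(ds$informants$ethnic_group)), "all")
  files <- character()
  for (g in groups) {
    stem <- gsub("[^A-Za-z0-9]+", "_", tolower(g))
    files <- c(
      files,
      write_table_pair(
        uv_table(ds, g, min_citations = min_citations),
        out_dir, paste0("use_value_", stem)
      ),
      write_table_pair(icf_table(ds, g), out_dir, paste0("consensus_", stem)),
      write_table_pair(
        priority_table(ds, g, min_citations = min_citations),
        out_dir, paste0("priority_", stem)
      )
    )
  }
  write_manifest(out_dir, "indices",
    config = list(group = groups, min_citations = min_citations),
    inputs = inputs
  )
  invisible(files)
}

#' Compute and write the demographic knowledge report
#'
#' Writes the knowledge summary table (per-level n, mean, SD and test
#' p-values) and the age-regression fit report; warns and skips comparisons
#' that need more than one level.
#'
#' @param ds An `eb_dataset`.
#' @param out_dir Output directory.
#' @param curvilinear Include the quadratic age term (default `TRUE`).
#' @param inputs Input file paths to digest into the manifest.
#' @return Invisibly, the files written.
#' @export
run_demographics <- function(ds, out_dir, curvilinear = TRUE,
                             inputs = character()) {
  stopifnot(inherits(ds, "eb_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- knowledge_scores(ds)
  rows <- list()
  for (v in c("age", "gender", "education", "religion")) {
    cmp <- tryCatch(compare_groups(scores, ds$informants, v),
      eb_domain_error = function(e) {
        rlang::warn(sprintf("skipping comparison by %s: %s", v, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(cmp)) next
    lev <- cmp$levels
    lev$variable <- v
    lev$test <- cmp$test_name
    lev$statistic <- cmp$statistic
    lev$p_value <- cmp$p_value
    rows[[v]] <- lev
  }
  summary_tab <- dplyr::bind_rows(rows)
  if (nrow(summary_tab) > 0) {
    summary_tab$mean <- round_half_up(summary_tab$mean, 2)
    summary_tab$sd <- round_half_up(summary_tab$sd, 2)
    names(summary_tab)[names(summary_tab) == "label"] <- "level"
    summary_tab <- summary_tab[c(
      "variable", "level", "n", "mean", "sd",
      "test", "statistic", "p_value"
    )]
  }
  csv <- file.path(out_dir, "knowledge_summary.csv")
  utils::write.csv(summary_tab, csv, row.names = FALSE)
  writeLines(format_markdown_table(summary_tab), file.path(out_dir, "knowledge_summary.md"))

  fit <- age_knowledge_fit(scores, ds$informants, curvilinear = curvilinear)
  fit_report <- list(
    model = if (curvilinear) "quadratic" else "linear",
    coefficients = as.list(fit$coefficients),
    r_squared = fit$r_squared
  )
  jsonlite::write_json(fit_report, file.path(out_dir, "age_fit.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(out_dir, "demographics",
    config = list(curvilinear = curvilinear), inputs = inputs
  )
  invisible(c(csv, file.path(out_dir, "age_fit.json")))
}
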