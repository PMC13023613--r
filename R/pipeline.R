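#' Write a simulated cohort to disk
#'
#' Generates a preset (or custom) cohort and writes the expression counts
#' TSV, the metadata TSV and a small JSON manifest recording the preset,
#' seed and package version, so a run can be reproduced exactly.
#'
#' @param preset_name A preset name (see [preset()]) or a [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(preset_name, seed, dir) {
  cfg <- if (inherits(preset_name, "sim_config")) preset_name
         else preset(preset_name)
  cohort <- if (!is.null(cfg$timepoints)) simulate_longitudinal(cfg, seed)
            else simulate_cohort(cfg, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_expression(cohort$expression, paths$expression)
  write_metadata(cohort$metadata, paths$metadata)
  jsonlite::write_json(
    list(preset = if (is.character(preset_name)) preset_name else "custom",
         seed = as.integer(seed),
         n_genes = nrow(cohort$expression),
         n_samples = ncol(cohort$expression),
         package_version = as.character(utils::packageVersion("sepsispanel"))),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Run the full panel analysis end to end
#'
#' Orchestrates normalize (when given raw counts), score, the requested
#' group and paired contrasts, rule evaluation, and longitudinal
#' monitoring, writing each result table to `out_dir`: `scores.tsv`,
#' `comparisons.tsv`, `rule_report.json`, `deltas.tsv` and `run_log.txt`
#' with per-stage sample and gene counts.
#'
#' @param expression An [expression_matrix()] or path to an expression
#'   file readable by [read_expression()].
#' @param metadata A metadata tibble or path readable by
#'   [read_metadata()].
#' @param scale Declared scale used when `expression` is a path.
#' @param contrasts List of length-2 character vectors `c(group_a,
#'   group_b)` for Welch contrasts over every panel.
#' @param paired Optional length-2 character vector `c(timepoint_a,
#'   timepoint_b)`; adds paired contrasts per panel and the monitoring
#'   delta/reversal tables.
#' @param rule A [rule_spec()] evaluated against outcomes, or `NULL` to
#'   skip rule evaluation.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list with `scores`, `comparisons`, `rule` (a `rule_eval` or
#'   `NULL`), `deltas`, `reversal_summary` and `log` (character lines).
#' @export
run_pipeline <- function(expression, metadata,
                         scale = c("raw_counts", "log2_normalized"),
                         contrasts = list(), paired = NULL,
                         rule = rule_spec(), out_dir = NULL) {
  scale <- match.arg(scale)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  if (is.character(expression)) {
    expression <- read_expression(expression, scale = scale)
  }
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- as_sample_records(metadata)
  note("input: ", nrow(expression), " genes x ", ncol(expression),
       " samples (", attr(expression, "scale"), "), ",
       nrow(metadata), " metadata records")

  if (attr(expression, "scale") == "raw_counts") {
    expression <- normalize_log2(expression)
    note("normalized raw counts to log2 CPM")
  } else {
    note("input already log2-normalized; no re-normalization")
  }
  scores <- score_samples(expression)
  note("scored ", nrow(scores), " samples against ",
       length(unique(builtin_panels()$panel)), " panels")

  comparisons <- list()
  for (ct in contrasts) {
    for (p in panel_order()) {
      comparisons <- c(comparisons,
                       list(two_group_contrast(scores, metadata,
                                               ct[1], ct[2], p)))
    }
    note("two-group contrast: ", ct[1], " vs ", ct[2])
  }
  deltas <- NULL
  reversal_summary <- NULL
  if (!is.null(paired)) {
    for (p in panel_order()) {
      comparisons <- c(comparisons,
                       list(paired_contrast(scores, metadata,
                                            paired[1], paired[2], p)))
    }
    deltas <- flag_reversals(
      compute_deltas(scores, metadata, paired[1], paired[2])
    )
    reversal_summary <- summarize_reversals(deltas)
    note("paired contrast and monitoring: ", paired[1], " -> ", paired[2])
  }
  comparisons <- if (length(comparisons) > 0) dplyr::bind_rows(comparisons)
                 else NULL

  rule_eval <- NULL
  if (!is.null(rule)) {
    known_ids <- metadata$sample_id[metadata$outcome != "unknown"]
    if (length(known_ids) > 0) {
      preds <- apply_rule(scores, metadata, rule)
      n_uneval <- sum(preds$predicted == "unevaluable" &
                        preds$sample_id %in% known_ids)
      if (n_uneval == length(known_ids)) {
        warning("all known-outcome samples unevaluable under the rule; ",
                "evaluation skipped", call. = FALSE)
        note("rule evaluation skipped: all samples unevaluable")
      } else {
        rule_eval <- evaluate_rule(preds, metadata)
        if (rule_eval$n_unevaluable > 0) {
          warning(rule_eval$n_unevaluable,
                  " known-outcome sample(s) unevaluable under the rule",
                  call. = FALSE)
        }
        note("rule evaluated on ", rule_eval$n_evaluated,
             " known-outcome samples")
      }
    } else {
      note("no known outcomes; rule evaluation skipped")
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scores(scores, file.path(out_dir, "scores.tsv"))
    if (!is.null(comparisons)) {
      readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
    }
    if (!is.null(deltas)) {
      readr::write_tsv(deltas, file.path(out_dir, "deltas.tsv"))
    }
    if (!is.null(rule_eval)) {
      jsonlite::write_json(
        list(rule = unclass(rule), evaluation = unclass(rule_eval)),
        file.path(out_dir, "rule_report.json"),
        auto_unbox = TRUE, pretty = TRUE, null = "null"
      )
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(scores = scores, comparisons = comparisons, rule = rule_eval,
       deltas = deltas, reversal_summary = reversal_summary,
       log = log_lines)
}
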