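#' Per-subject panel-score changes between two time points
#'
#' Computes, for every subject present at both time points, the change in
#' each panel score (to minus from). Subjects lacking either time point
#' are skipped with a message giving the count.
#'
#' @param scores Score tibble from [score_samples()].
#' @param records Metadata tibble with `subject_id` and `timepoint`.
#' @param from_tp,to_tp Time-point labels.
#' @param panels Panel (score column) names to difference.
#' @return A tibble with `subject_id`, `panel`, `from`, `to`, `delta`.
#' @export
compute_deltas <- function(scores, records, from_tp, to_tp,
                           panels = intersect(panel_order(), names(scores))) {
  df <- join_scores(scores, records)
  a <- df[df$timepoint %in% from_tp, c("subject_id", panels)]
  b <- df[df$timepoint %in% to_tp, c("subject_id", panels)]
  pair <- dplyr::inner_join(a, b, by = "subject_id", suffix = c("_a", "_b"))
  n_skipped <- length(union(a$subject_id, b$subject_id)) - nrow(pair)
  if (n_skipped > 0) {
    message("skipped ", n_skipped, " subject(s) without both time points")
  }
  if (nrow(pair) == 0) {
    stop("no subject has scores at both '", from_tp, "' and '", to_tp, "'",
         call. = FALSE)
  }
  out <- lapply(panels, function(p) {
    tibble::tibble(subject_id = pair$subject_id, panel = p,
                   from = from_tp, to = to_tp,
                   delta = pair[[paste0(p, "_b")]] - pair[[paste0(p, "_a")]])
  })
  dplyr::bind_rows(out)
}

#' Flag reversal of dysregulation in score deltas
#'
#' A delta is a reversal when its sign is opposite to the panel's sepsis
#' dysregulation direction and strictly nonzero: a falling NDrG
#' (direction +1) or a rising HLAd/LYMd (direction -1) during treatment.
#' Bidirectional panels (direction 0: ISGa, GBPs) get a missing flag —
#' sign-based reversal is not meaningful when both directions occur in
#' disease.
#'
#' @param deltas Delta tibble from [compute_deltas()].
#' @param panels Panel definition tibble carrying directions
#'   ([builtin_panels()] by default).
#' @return `deltas` with a logical `reversal` column (`NA` for
#'   direction-0 panels).
#' @export
flag_reversals <- function(deltas, panels = builtin_panels()) {
  dirs <- panels[!duplicated(panels$panel), c("panel", "direction")]
  out <- dplyr::left_join(deltas, dirs, by = "panel")
  out$reversal <- ifelse(
    out$direction == 0L, NA,
    sign(out$delta) == -out$direction & out$delta != 0
  )
  out$direction <- NULL
  out
}

#' Cohort reversal summary per panel
#'
#' @param deltas Flagged delta tibble from [flag_reversals()].
#' @return A tibble with `panel`, `n`, `n_reversed`, `fraction_reversed`
#'   (`NA` fractions for bidirectional panels).
#' @export
summarize_reversals <- function(deltas) {
  deltas |>
    dplyr::group_by(.data$panel) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_reversed = sum(.data$reversal, na.rm = TRUE),
      fraction_reversed = if (all(is.na(.data$reversal))) NA_real_
        else mean(.data$reversal, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Responder versus non-responder longitudinal contrasts
#'
#' Reproduces the treatment-response analysis layout: (i) within-group
#' paired contrasts between the two time points for each group and panel,
#' and (ii) the cross-group unpaired contrast between `group_a` at the
#' later time point and `group_b` at the earlier one — the comparison that
#' separates recovered responders from newly admitted non-responders.
#'
#' @param scores Score tibble.
#' @param records Metadata tibble.
#' @param group_a,group_b Group labels (conventionally responders and
#'   non-responders).
#' @param timepoints Length-2 character vector `c(earlier, later)`.
#' @param panels Panel names to contrast.
#' @return A comparison tibble (rows from [paired_contrast()] and
#'   [two_group_contrast()]) with an extra `contrast` column naming each
#'   comparison.
#' @export
responder_contrast <- function(scores, records, group_a, group_b,
                               timepoints,
                               panels = c("NDrG", "HLAd", "LYMd")) {
  stopifnot(length(timepoints) == 2)
  tp1 <- timepoints[1]; tp2 <- timepoints[2]
  rows <- list()
  for (g in c(group_a, group_b)) {
    for (p in panels) {
      r <- paired_contrast(scores, records, tp1, tp2, p, group = g)
      r$contrast <- paste0(g, ": ", tp1, " -> ", tp2)
      rows <- c(rows, list(r))
    }
  }
  rec_a <- records[records$timepoint %in% tp2, ]
  rec_b <- records[records$timepoint %in% tp1, ]
  cross_records <- dplyr::bind_rows(
    rec_a[rec_a$group %in% group_a, ],
    rec_b[rec_b$group %in% group_b, ]
  )
  for (p in panels) {
    r <- two_group_contrast(scores, cross_records, group_b, group_a, p)
    r$contrast <- paste0(group_a, "@", tp2, " vs ", group_b, "@", tp1)
    rows <- c(rows, list(r))
  }
  dplyr::bind_rows(rows)
}
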