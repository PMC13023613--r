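#' Specify a survivor-identification rule
#'
#' A rule is an OR over up to three clauses, each with a strict
#' inequality: composite (NDrG - HLAd) score below a threshold (default
#' 1.50), SOFA score below a threshold (default 8), and optionally GBPs
#' score above a threshold (default 8.5, the exploratory extension).
#' Setting a threshold to `NULL` disables that clause; at least one clause
#' must stay enabled. A sample is predicted `survivor` when any enabled
#' clause fires; samples missing an input of any enabled clause are
#' `unevaluable`.
#'
#' @param composite Composite-score threshold (predict survivor when
#'   composite < threshold), or `NULL` to disable.
#' @param sofa SOFA threshold (survivor when SOFA < threshold), or `NULL`.
#' @param gbps GBPs threshold (survivor when GBPs > threshold), or `NULL`.
#' @return A `rule_spec` object.
#' @examples
#' rule_spec()                       # composite < 1.5 OR SOFA < 8
#' rule_spec(sofa = NULL)            # composite-only rule
#' rule_spec(gbps = 8.5)             # add the GBPs extension
#' @export
rule_spec <- function(composite = 1.50, sofa = 8, gbps = NULL) {
  thresholds <- list(composite = composite, sofa = sofa, gbps = gbps)
  enabled <- !vapply(thresholds, is.null, logical(1))
  if (!any(enabled)) {
    stop("at least one rule clause must be enabled", call. = FALSE)
  }
  for (nm in names(thresholds)[enabled]) {
    if (!is.finite(thresholds[[nm]])) {
      stop("threshold for '", nm, "' must be finite", call. = FALSE)
    }
  }
  structure(thresholds, class = "rule_spec")
}

#' @export
print.rule_spec <- function(x, ...) {
  parts <- c(
    if (!is.null(x$composite)) paste0("(NDrG-HLAd) < ", x$composite),
    if (!is.null(x$sofa)) paste0("SOFA < ", x$sofa),
    if (!is.null(x$gbps)) paste0("GBPs > ", x$gbps)
  )
  cat("<rule_spec> predict survivor when:", paste(parts, collapse = " OR "),
      "\n")
  invisible(x)
}

#' Apply a survivor-identification rule to scored samples
#'
#' @param scores Score tibble from [score_samples()] (needs `composite`
#'   and/or `GBPs` columns depending on the enabled clauses).
#' @param records Metadata tibble (needs `sofa` if the SOFA clause is
#'   enabled).
#' @param rule A [rule_spec()].
#' @return A tibble with `sample_id` and `predicted` in
#'   `{"survivor", "not_identified", "unevaluable"}`.
#' @export
apply_rule <- function(scores, records, rule = rule_spec()) {
  stopifnot(inherits(rule, "rule_spec"))
  df <- join_scores(scores, records)
  clause_vals <- list()
  if (!is.null(rule$composite)) {
    if (!"composite" %in% names(df)) df$composite <- NA_real_
    clause_vals$composite <- df$composite < rule$composite
  }
  if (!is.null(rule$sofa)) {
    if (!"sofa" %in% names(df)) df$sofa <- NA_integer_
    clause_vals$sofa <- df$sofa < rule$sofa
  }
  if (!is.null(rule$gbps)) {
    if (!"GBPs" %in% names(df)) df$GBPs <- NA_real_
    clause_vals$gbps <- df$GBPs > rule$gbps
  }
  cl <- do.call(cbind, clause_vals)
  unevaluable <- apply(cl, 1, anyNA)
  fired <- apply(cl, 1, any)
  predicted <- dplyr::case_when(
    unevaluable ~ "unevaluable",
    fired ~ "survivor",
    .default = "not_identified"
  )
  tibble::tibble(sample_id = df$sample_id, predicted = predicted)
}

#' Evaluate rule predictions against observed outcomes
#'
#' Confusion counts treat predicted/observed `survivor` as the positive
#' class. Samples with unknown outcome or unevaluable predictions are
#' excluded from the counts and tallied separately. The published "false
#' positive rate" is ambiguous between two denominators, so both
#' fractions are reported explicitly: `false_discovery_fraction` =
#' FP / (TP + FP) (0 when nothing is predicted) and
#' `fpr_among_nonsurvivors` = FP / (FP + TN).
#'
#' @param predictions Tibble from [apply_rule()].
#' @param records Metadata tibble with `outcome`.
#' @return A `rule_eval` object: confusion counts (`tp`, `fp`, `fn`,
#'   `tn`), `sensitivity`, `false_positives`, the two fractions above,
#'   `n_evaluated`, `n_unknown_outcome`, `n_unevaluable`.
#' @export
evaluate_rule <- function(predictions, records) {
  df <- dplyr::inner_join(predictions, records[, c("sample_id", "outcome")],
                          by = "sample_id")
  n_unknown <- sum(df$outcome == "unknown")
  n_uneval <- sum(df$predicted == "unevaluable" & df$outcome != "unknown")
  known <- df[df$outcome != "unknown" & df$predicted != "unevaluable", ]
  if (nrow(known) == 0) {
    stop("no samples with known outcome to evaluate", call. = FALSE)
  }
  pred_pos <- known$predicted == "survivor"
  obs_pos <- known$outcome == "survivor"
  tp <- sum(pred_pos & obs_pos)
  fp <- sum(pred_pos & !obs_pos)
  fn <- sum(!pred_pos & obs_pos)
  tn <- sum(!pred_pos & !obs_pos)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         false_positives = fp,
         false_discovery_fraction = if (tp + fp > 0) fp / (tp + fp) else 0,
         fpr_among_nonsurvivors = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         n_evaluated = nrow(known),
         n_unknown_outcome = n_unknown,
         n_unevaluable = n_uneval),
    class = "rule_eval"
  )
}

#' @export
print.rule_eval <- function(x, ...) {
  cat("<rule_eval> ", x$n_evaluated, " evaluated (",
      x$n_unknown_outcome, " unknown outcome, ",
      x$n_unevaluable, " unevaluable)\n", sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f | FP/(TP+FP) %.3f | FP/(FP+TN) %.3f\n",
              x$sensitivity, x$false_discovery_fraction,
              x$fpr_among_nonsurvivors))
  invisible(x)
}

#' Tidy confusion counts of a rule evaluation
#'
#' @param x A `rule_eval` object.
#' @param ... Unused.
#' @return A tibble with one row per confusion cell.
#' @method tidy rule_eval
#' @export
tidy.rule_eval <- function(x, ...) {
  tibble::tibble(
    predicted = c("survivor", "survivor", "not_identified", "not_identified"),
    outcome = c("survivor", "non-survivor", "survivor", "non-survivor"),
    n = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' One-row metric summary of a rule evaluation
#'
#' @param x A `rule_eval` object.
#' @param ... Unused.
#' @return A one-row tibble of the derived metrics.
#' @method glance rule_eval
#' @export
glance.rule_eval <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity,
    false_positives = x$false_positives,
    false_discovery_fraction = x$false_discovery_fraction,
    fpr_among_nonsurvivors = x$fpr_among_nonsurvivors,
    n_evaluated = x$n_evaluated,
    n_unknown_outcome = x$n_unknown_outcome,
    n_unevaluable = x$n_unevaluable
  )
}

composite_outcome_frame <- function(scores, records) {
  df <- join_scores(scores, records)
  df <- df[df$outcome != "unknown", ]
  if (any(is.na(df$composite))) {
    stop("missing composite values among known-outcome samples: ",
         paste(df$sample_id[is.na(df$composite)], collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Largest composite threshold with zero false positives
#'
#' Finds the threshold at which the composite clause
#' `composite < threshold` admits no known non-survivor: the minimum
#' composite value among non-survivors. Returns the survivor sensitivity
#' achieved there.
#'
#' @param scores Score tibble with a `composite` column.
#' @param records Metadata tibble with `outcome`.
#' @return A one-row tibble: `threshold`, `sensitivity`, `n_survivors`,
#'   `n_nonsurvivors`.
#' @export
zero_fp_threshold <- function(scores, records) {
  df <- composite_outcome_frame(scores, records)
  surv <- df$composite[df$outcome == "survivor"]
  nonsurv <- df$composite[df$outcome == "non-survivor"]
  if (length(surv) < 1 || length(nonsurv) < 1) {
    stop("need at least one known survivor and one known non-survivor",
         call. = FALSE)
  }
  theta <- min(nonsurv)
  tibble::tibble(threshold = theta,
                 sensitivity = mean(surv < theta),
                 n_survivors = length(surv),
                 n_nonsurvivors = length(nonsurv))
}

#' Sweep the composite threshold
#'
#' Evaluates the composite-only rule over a grid of thresholds. The
#' default-rule threshold 1.50 is always included in the grid. Both
#' sensitivity and the false-positive count are non-decreasing in the
#' threshold.
#'
#' @param scores Score tibble with a `composite` column.
#' @param records Metadata tibble with `outcome`.
#' @param grid Numeric vector of thresholds.
#' @return A tibble with `threshold`, `sensitivity`, `fp`, sorted by
#'   threshold.
#' @export
threshold_sweep <- function(scores, records,
                            grid = seq(-2, 6, by = 0.25)) {
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  df <- composite_outcome_frame(scores, records)
  surv <- df$composite[df$outcome == "survivor"]
  nonsurv <- df$composite[df$outcome == "non-survivor"]
  grid <- sort(unique(c(grid, 1.50)))
  tibble::tibble(
    threshold = grid,
    sensitivity = vapply(grid, function(th) mean(surv < th), numeric(1)),
    fp = vapply(grid, function(th) sum(nonsurv < th), numeric(1))
  )
}
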