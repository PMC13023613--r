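join_scores <- function(scores, records) {
  dplyr::inner_join(scores, records, by = "sample_id")
}

pull_panel <- function(scores, panel) {
  if (!panel %in% names(scores)) {
    stop("no score column for panel '", panel, "'", call. = FALSE)
  }
  scores[[panel]]
}

comparison_row <- function(panel, group_a, group_b, n_a, n_b,
                           mean_diff, statistic, df, p_value, method) {
  tibble::tibble(panel = panel, group_a = group_a, group_b = group_b,
                 n_a = n_a, n_b = n_b, mean_diff = mean_diff,
                 statistic = statistic, df = df, p_value = p_value,
                 method = method)
}

#' Welch two-group contrast of a panel score
#'
#' Compares a panel score (or the composite) between two sample groups
#' with the Welch unequal-variance t test. The reported mean difference is
#' group B minus group A, so calling with `group_a` = control puts the
#' sepsis-direction effect on its usual sign.
#'
#' @param scores Score tibble from [score_samples()].
#' @param records Metadata tibble with `group` labels.
#' @param group_a,group_b Group labels to compare.
#' @param panel Panel (score column) name, e.g. `"NDrG"` or `"composite"`.
#' @return A one-row comparison tibble: `panel`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_diff` (B - A), `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
two_group_contrast <- function(scores, records, group_a, group_b, panel) {
  df <- join_scores(scores, records)
  a <- pull_panel(df[df$group %in% group_a, ], panel)
  b <- pull_panel(df[df$group %in% group_b, ], panel)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need n >= 2 (got ", length(a), " and ", length(b), ")",
         call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    stop("zero variance in both groups; the Welch test is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  comparison_row(panel, group_a, group_b, length(a), length(b),
                 mean(b) - mean(a), unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, "welch_t")
}

#' Paired contrast of a panel score between two time points
#'
#' Computes per-subject deltas (time point B minus A) over subjects
#' present at both time points and applies the paired t test. Subjects
#' lacking either time point are dropped with a message.
#'
#' @param scores Score tibble.
#' @param records Metadata tibble with `subject_id` and `timepoint`.
#' @param timepoint_a,timepoint_b Time-point labels (delta = B - A).
#' @param panel Panel name.
#' @param group Optional group label(s) to restrict the subjects.
#' @return A one-row comparison tibble (see [two_group_contrast()]); `n_a`
#'   and `n_b` both equal the number of complete pairs.
#' @export
paired_contrast <- function(scores, records, timepoint_a, timepoint_b,
                            panel, group = NULL) {
  df <- join_scores(scores, records)
  if (!is.null(group)) df <- df[df$group %in% group, ]
  a <- df[df$timepoint %in% timepoint_a, c("subject_id", panel)]
  b <- df[df$timepoint %in% timepoint_b, c("subject_id", panel)]
  pair <- dplyr::inner_join(a, b, by = "subject_id",
                            suffix = c("_a", "_b"))
  pair <- pair[stats::complete.cases(pair), ]
  n_dropped <- length(union(a$subject_id, b$subject_id)) - nrow(pair)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " subject(s) without both time points")
  }
  d <- pair[[paste0(panel, "_b")]] - pair[[paste0(panel, "_a")]]
  n <- length(d)
  if (n < 2) stop("need >= 2 complete pairs (got ", n, ")", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("degenerate paired contrast: all deltas identical (sd = 0)",
         call. = FALSE)
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  comparison_row(panel, timepoint_a, timepoint_b, n, n, mean(d), tstat,
                 n - 1, 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE),
                 "paired_t")
}

#' Tukey HSD multi-group contrasts of a panel score
#'
#' All pairwise group comparisons with family-wise adjusted p-values from
#' the studentized range distribution, using the pooled within-group mean
#' square and the Tukey-Kramer standard error for unequal group sizes.
#'
#' @param scores Score tibble.
#' @param records Metadata tibble.
#' @param groups Character vector of group labels to compare (>= 2).
#' @param panel Panel name.
#' @return A comparison tibble with one row per group pair; `statistic` is
#'   the signed studentized statistic (B - A over the Tukey-Kramer SE) and
#'   `p_value` is family-wise adjusted.
#' @export
tukey_contrasts <- function(scores, records, groups, panel) {
  df <- join_scores(scores, records)
  df <- df[df$group %in% groups & !is.na(df[[panel]]), ]
  vals <- split(df[[panel]], factor(df$group, levels = groups))
  ns <- vapply(vals, length, integer(1))
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(ns < 2)) {
    stop("every group needs n >= 2 (", paste(groups[ns < 2], collapse = ", "),
         " too small)", call. = FALSE)
  }
  k <- length(groups)
  n_tot <- sum(ns)
  mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1))) /
    (n_tot - k)
  df_resid <- n_tot - k
  means <- vapply(vals, mean, numeric(1))
  pairs <- utils::combn(groups, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[[ga]] + 1 / ns[[gb]]))
    qstat <- (means[[gb]] - means[[ga]]) / se
    p <- stats::ptukey(abs(qstat), nmeans = k, df = df_resid,
                       lower.tail = FALSE)
    comparison_row(panel, ga, gb, ns[[ga]], ns[[gb]],
                   means[[gb]] - means[[ga]], qstat, df_resid, p,
                   "tukey_hsd")
  })
  dplyr::bind_rows(out)
}

#' Permutation-based family-wise contrast check
#'
#' A seeded max-|difference| permutation test over all group pairs,
#' provided as an assumption-light cross-check of [tukey_contrasts()].
#'
#' @inheritParams tukey_contrasts
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @return A comparison tibble with method `"permutation_fwer"`.
#' @export
permutation_contrasts <- function(scores, records, groups, panel,
                                  n_perm = 10000, seed = 1) {
  df <- join_scores(scores, records)
  df <- df[df$group %in% groups & !is.na(df[[panel]]), ]
  g <- factor(df$group, levels = groups)
  x <- df[[panel]]
  ns <- table(g)
  max_absdiff <- function(xx) {
    m <- tapply(xx, g, mean)
    max(abs(outer(m, m, "-")))
  }
  pairs <- utils::combn(groups, 2)
  obs_means <- tapply(x, g, mean)
  null_max <- withr::with_seed(as.integer(seed), {
    replicate(n_perm, max_absdiff(sample(x)))
  })
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    d <- obs_means[[gb]] - obs_means[[ga]]
    p <- (1 + sum(null_max >= abs(d))) / (1 + n_perm)
    comparison_row(panel, ga, gb, ns[[ga]], ns[[gb]], d, NA_real_,
                   NA_real_, p, "permutation_fwer")
  })
  dplyr::bind_rows(out)
}

#' Pearson correlation between a panel score and the SOFA score
#'
#' Complete-case Pearson correlation; samples missing either the score or
#' SOFA are excluded.
#'
#' @param scores Score tibble.
#' @param records Metadata tibble with a `sofa` column.
#' @param panel Panel name.
#' @return A one-row tibble: `panel`, `r`, `n`, `p_value`.
#' @export
score_sofa_correlation <- function(scores, records, panel) {
  df <- join_scores(scores, records)
  ok <- !is.na(df[[panel]]) & !is.na(df$sofa)
  x <- df[[panel]][ok]
  y <- df$sofa[ok]
  if (length(x) < 3) {
    stop("need >= 3 samples with both score and SOFA (got ", length(x), ")",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in score or SOFA; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(panel = panel, r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value)
}

#' Principal component analysis of the panel scores
#'
#' Standardizes the five panel scores (unit variance) and
#' eigendecomposes; loadings signs are fixed so each component's
#' largest-magnitude loading is positive, making orientations
#' reproducible.
#'
#' @param scores Score tibble with all panel columns present.
#' @param k Number of components to retain.
#' @param panels Panel (column) names to use.
#' @return A `panel_pca` object: `loadings` (panels x k), `scores` (tibble
#'   of sample component scores), `variance_explained` (length-k fractions
#'   of total variance), `sdev`.
#' @export
pca_panels <- function(scores, k = 2, panels = panel_order()) {
  missing_cols <- setdiff(panels, names(scores))
  if (length(missing_cols) > 0) {
    stop("missing score columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(scores[, panels])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < k + 1) {
    stop("need at least k + 1 = ", k + 1, " complete samples", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant panel column(s): ",
         paste(panels[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")[, seq_len(k), drop = FALSE]
  comp <- sweep(pc$x, 2, flip, "*")[, seq_len(k), drop = FALSE]
  structure(
    list(loadings = rot,
         scores = tibble::tibble(sample_id = scores$sample_id[keep],
                                 tibble::as_tibble(comp)),
         variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
         sdev = pc$sdev),
    class = "panel_pca"
  )
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("<panel_pca> ", nrow(x$scores), " samples, ",
      ncol(x$loadings), " components\n", sep = "")
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the loadings of a panel PCA
#'
#' @param x A `panel_pca` object.
#' @param ... Unused.
#' @return A long tibble: `panel`, `component`, `loading`.
#' @method tidy panel_pca
#' @export
tidy.panel_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "panel") |>
    tidyr::pivot_longer(-"panel", names_to = "component",
                        values_to = "loading")
}

#' One-row summary of a panel PCA
#'
#' @param x A `panel_pca` object.
#' @param ... Unused.
#' @return A tibble with `n`, `k` and the cumulative variance explained.
#' @method glance panel_pca
#' @export
glance.panel_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), k = ncol(x$loadings),
                 cum_variance_explained = sum(x$variance_explained))
}
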