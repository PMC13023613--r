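# In-code fixtures shared across the test files.

# log2-scale matrix holding all 26 panel genes at a given value
full_panel_matrix <- function(value = 8, samples = c("s1", "s2"),
                              extra_genes = character()) {
  genes <- c(builtin_panels()$gene, extra_genes)
  m <- matrix(value, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  expression_matrix(m, scale = "log2_normalized")
}

# scores/records pair for two plain groups with given per-sample values
group_fixture <- function(a, b, labels = c("A", "B"), panel = "NDrG") {
  n <- length(a) + length(b)
  ids <- sprintf("s%02d", seq_len(n))
  scores <- tibble::tibble(sample_id = ids)
  scores[[panel]] <- c(a, b)
  records <- as_sample_records(tibble::tibble(
    sample_id = ids,
    group = rep(labels, c(length(a), length(b)))
  ))
  list(scores = scores, records = records)
}

# paired two-timepoint fixture from per-subject (before, after) values
paired_fixture <- function(before, after, panel = "NDrG",
                           tps = c("T1", "T2")) {
  n <- length(before)
  subj <- sprintf("p%02d", seq_len(n))
  scores <- tibble::tibble(sample_id = c(paste0(subj, "_a"),
                                         paste0(subj, "_b")))
  scores[[panel]] <- c(before, after)
  records <- as_sample_records(tibble::tibble(
    sample_id = scores$sample_id,
    subject_id = rep(subj, 2),
    timepoint = rep(tps, each = n)
  ))
  list(scores = scores, records = records)
}

# outcome fixture: composite (and optional sofa) values per outcome class
outcome_fixture <- function(surv_composite, nonsurv_composite,
                            surv_sofa = NULL, nonsurv_sofa = NULL) {
  n_s <- length(surv_composite); n_n <- length(nonsurv_composite)
  ids <- c(sprintf("surv%02d", seq_len(n_s)),
           sprintf("dead%02d", seq_len(n_n)))
  scores <- tibble::tibble(sample_id = ids,
                           composite = c(surv_composite, nonsurv_composite))
  records <- as_sample_records(tibble::tibble(
    sample_id = ids,
    outcome = rep(c("survivor", "non-survivor"), c(n_s, n_n)),
    sofa = if (is.null(surv_sofa)) NA_integer_ else c(surv_sofa, nonsurv_sofa)
  ))
  list(scores = scores, records = records)
}

# a cohort of 78 ICU patients whose composite/SOFA values realize the
# published confusion counts: composite rule 45/60 with 0 FP, SOFA rule
# 36/60 with 2 FP, OR-combination 54/60 with 2 FP
published_rule_cohort <- function() {
  surv_comp <- c(rep(1.0, 27), rep(1.0, 18), rep(2.0, 9), rep(2.0, 6))
  surv_sofa <- c(rep(5L, 27), rep(10L, 18), rep(5L, 9), rep(12L, 6))
  nonsurv_comp <- rep(2.5, 18)
  nonsurv_sofa <- c(rep(6L, 2), rep(15L, 16))
  outcome_fixture(surv_comp, nonsurv_comp, surv_sofa, nonsurv_sofa)
}

# brute-force oracle: best zero-false-positive composite threshold by
# exhaustive search over all candidate cut points
brute_force_zero_fp <- function(surv, nonsurv) {
  cand <- sort(unique(c(surv, nonsurv, Inf)))
  best <- list(threshold = -Inf, sensitivity = 0)
  for (th in cand) {
    if (sum(nonsurv < th) == 0) {
      s <- mean(surv < th)
      if (s >= best$sensitivity) best <- list(threshold = th, sensitivity = s)
    }
  }
  best
}

# tiny noiseless simulation config (single group unless given)
noiseless_config <- function(groups = NULL, ...) {
  if (is.null(groups)) {
    groups <- list(list(group = "g", n = 4,
                        mu = c(NDrG = 9, ISGa = 6, GBPs = 7,
                               HLAd = 7.5, LYMd = 6)))
  }
  sim_config(groups, sigma = 0, tau = 0, phi = 0, delta_sd = 0,
             n_background = 200, ...)
}
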