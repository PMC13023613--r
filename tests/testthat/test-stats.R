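test_that("Welch contrast matches hand-evaluated formulas", {
  fx <- group_fixture(c(1, 2, 3), c(2, 4, 6))
  ct <- two_group_contrast(fx$scores, fx$records, "A", "B", "NDrG")
  # Welch oracle evaluated directly from the formulas
  se2 <- var(c(1, 2, 3)) / 3 + var(c(2, 4, 6)) / 3
  t_exp <- (mean(c(1, 2, 3)) - mean(c(2, 4, 6))) / sqrt(se2)
  df_exp <- se2^2 / ((var(c(1, 2, 3)) / 3)^2 / 2 + (var(c(2, 4, 6)) / 3)^2 / 2)
  expect_equal(ct$mean_diff, 2)
  expect_equal(ct$statistic, t_exp)   # -1.549193
  expect_equal(ct$df, df_exp)         # 2.941176
  expect_equal(ct$statistic, -1.549193, tolerance = 1e-6)
  expect_equal(ct$df, 2.941176, tolerance = 1e-6)
})

test_that("identical groups give zero difference and p = 1", {
  fx <- group_fixture(c(1, 2, 3), c(1, 2, 3))
  ct <- two_group_contrast(fx$scores, fx$records, "A", "B", "NDrG")
  expect_equal(ct$mean_diff, 0)
  expect_equal(ct$p_value, 1)
})

test_that("a pure shift is recovered as the mean difference", {
  set.seed(1)
  fx <- group_fixture(rep(0, 4) + rnorm(4, sd = 1e-6),
                      rep(5, 4) + rnorm(4, sd = 1e-6))
  ct <- two_group_contrast(fx$scores, fx$records, "A", "B", "NDrG")
  expect_equal(ct$mean_diff, 5, tolerance = 1e-4)
})

test_that("swapping groups negates the difference and keeps the p-value", {
  set.seed(2)
  fx <- group_fixture(rnorm(6), rnorm(8, 1))
  ab <- two_group_contrast(fx$scores, fx$records, "A", "B", "NDrG")
  ba <- two_group_contrast(fx$scores, fx$records, "B", "A", "NDrG")
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("two_group_contrast rejects degenerate inputs", {
  fx <- group_fixture(c(1), c(2, 3))
  expect_error(two_group_contrast(fx$scores, fx$records, "A", "B", "NDrG"),
               "n >= 2")
  fx2 <- group_fixture(c(1, 1), c(2, 2))
  expect_error(two_group_contrast(fx2$scores, fx2$records, "A", "B", "NDrG"),
               "zero variance")
})

test_that("paired contrast matches the closed-form t at df = 2", {
  fx <- paired_fixture(c(0, 0, 0), c(1, 2, 3))
  ct <- paired_contrast(fx$scores, fx$records, "T1", "T2", "NDrG")
  expect_equal(ct$mean_diff, 2)
  expect_equal(ct$statistic, 2 * sqrt(3), tolerance = 1e-9)  # 3.4641
  expect_equal(ct$df, 2)
  # closed-form t CDF at df = 2: F(t) = 1/2 + t / (2 sqrt(t^2 + 2))
  t0 <- 2 * sqrt(3)
  p_exp <- 2 * (1 - (0.5 + t0 / (2 * sqrt(t0^2 + 2))))
  expect_equal(ct$p_value, p_exp, tolerance = 1e-9)  # 0.0741799
})

test_that("paired contrast drops incomplete pairs and checks degeneracy", {
  fx <- paired_fixture(c(1, 2, 3), c(2, 3, 5))
  extra <- tibble::tibble(sample_id = "lonely_a", NDrG = 4)
  scores <- dplyr::bind_rows(fx$scores, extra)
  records <- dplyr::bind_rows(
    fx$records,
    as_sample_records(tibble::tibble(sample_id = "lonely_a",
                                     subject_id = "lonely",
                                     timepoint = "T1"))
  )
  expect_message(
    ct <- paired_contrast(scores, records, "T1", "T2", "NDrG"),
    "dropped 1"
  )
  expect_equal(ct$n_a, 3)
  expect_equal(ct$mean_diff, mean(c(1, 1, 2)))

  fx0 <- paired_fixture(c(1, 2), c(1, 2))
  expect_error(paired_contrast(fx0$scores, fx0$records, "T1", "T2", "NDrG"),
               "degenerate")
})

test_that("near-null paired deltas give a near-zero mean difference", {
  set.seed(3)
  fx <- paired_fixture(rnorm(6), rnorm(6, sd = 1e-6) + rnorm(6))
  # rebuild with after = before + tiny jitter
  before <- rnorm(6)
  fx <- paired_fixture(before, before + rnorm(6, sd = 1e-6))
  ct <- paired_contrast(fx$scores, fx$records, "T1", "T2", "NDrG")
  expect_lt(abs(ct$mean_diff), 1e-5)
})

test_that("Tukey contrasts agree with the base-R Tukey HSD oracle", {
  set.seed(4)
  vals <- list(A = rnorm(8, 0), B = rnorm(6, 1), C = rnorm(10, 0.5))
  fx <- group_fixture(vals$A, vals$B)
  ids <- sprintf("c%02d", seq_along(vals$C))
  scores <- dplyr::bind_rows(fx$scores,
                             tibble::tibble(sample_id = ids, NDrG = vals$C))
  records <- dplyr::bind_rows(
    fx$records,
    as_sample_records(tibble::tibble(sample_id = ids, group = "C"))
  )
  res <- tukey_contrasts(scores, records, c("A", "B", "C"), "NDrG")

  df <- dplyr::inner_join(scores, records, by = "sample_id")
  fit <- stats::aov(NDrG ~ group, data = df)
  oracle <- stats::TukeyHSD(fit)$group
  key <- paste0(res$group_b, "-", res$group_a)
  expect_equal(res$mean_diff, unname(oracle[key, "diff"]), tolerance = 1e-9)
  expect_equal(res$p_value, unname(oracle[key, "p adj"]), tolerance = 1e-7)
})

test_that("with two groups the Tukey p equals the pooled-variance t-test p", {
  set.seed(5)
  a <- rnorm(7); b <- rnorm(9, 0.8)
  fx <- group_fixture(a, b)
  res <- tukey_contrasts(fx$scores, fx$records, c("A", "B"), "NDrG")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  # studentized statistic is sqrt(2) times the pooled t
  expect_equal(abs(res$statistic), sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-9)
})

test_that("Tukey adjusted p-values dominate pairwise unadjusted ones", {
  set.seed(6)
  groups <- c("A", "B", "C", "D")
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:24),
                           NDrG = rnorm(24, rep(c(0, 0.5, 1, 0.2), each = 6)))
  records <- as_sample_records(tibble::tibble(
    sample_id = scores$sample_id, group = rep(groups, each = 6)
  ))
  res <- tukey_contrasts(scores, records, groups, "NDrG")
  for (j in seq_len(nrow(res))) {
    a <- scores$NDrG[records$group == res$group_a[j]]
    b <- scores$NDrG[records$group == res$group_b[j]]
    expect_gte(res$p_value[j],
               stats::t.test(a, b, var.equal = TRUE)$p.value - 1e-12)
  }
})

test_that("three identical groups are not separated; a 10-SD shift is", {
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:9),
                           NDrG = rep(c(1, 2, 3), 3))
  records <- as_sample_records(tibble::tibble(
    sample_id = scores$sample_id, group = rep(c("A", "B", "C"), each = 3)
  ))
  res <- tukey_contrasts(scores, records, c("A", "B", "C"), "NDrG")
  expect_equal(res$p_value, rep(1, 3), tolerance = 1e-9)

  set.seed(7)
  scores2 <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:24),
    NDrG = rnorm(24, rep(c(0, 0, 0, 10), each = 6), sd = 1)
  )
  records2 <- as_sample_records(tibble::tibble(
    sample_id = scores2$sample_id, group = rep(c("A", "B", "C", "D"), each = 6)
  ))
  res2 <- tukey_contrasts(scores2, records2, c("A", "B", "C", "D"), "NDrG")
  shifted <- res2[res2$group_a == "D" | res2$group_b == "D", ]
  expect_true(all(shifted$p_value < 1e-3))
  # permutation cross-check flags the same pairs at small n
  perm <- permutation_contrasts(scores2, records2, c("A", "B", "C", "D"),
                                "NDrG", n_perm = 2000, seed = 1)
  pshift <- perm[perm$group_a == "D" | perm$group_b == "D", ]
  expect_true(all(pshift$p_value < 0.01))
})

test_that("score-SOFA correlation is complete-case Pearson", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"), NDrG = c(1, 2, 3))
  rec <- as_sample_records(tibble::tibble(sample_id = c("a", "b", "c"),
                                          sofa = c(2L, 4L, 6L)))
  expect_equal(score_sofa_correlation(sc, rec, "NDrG")$r, 1)

  rec2 <- as_sample_records(tibble::tibble(sample_id = c("a", "b", "c"),
                                           sofa = c(6L, 4L, 5L)))
  expect_equal(score_sofa_correlation(sc, rec2, "NDrG")$r, -0.5)

  sc4 <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        NDrG = c(1, 2, 3, 9))
  rec4 <- as_sample_records(tibble::tibble(
    sample_id = c("a", "b", "c", "d"), sofa = c(6L, 4L, 5L, NA)
  ))
  res <- score_sofa_correlation(sc4, rec4, "NDrG")
  expect_equal(res$n, 3)
  expect_equal(res$r, -0.5)

  rec_small <- as_sample_records(tibble::tibble(sample_id = c("a", "b"),
                                                sofa = c(1L, 2L)))
  expect_error(score_sofa_correlation(sc[1:2, ], rec_small, "NDrG"), ">= 3")
  rec_flat <- as_sample_records(tibble::tibble(sample_id = c("a", "b", "c"),
                                               sofa = c(4L, 4L, 4L)))
  expect_error(score_sofa_correlation(sc, rec_flat, "NDrG"), "zero variance")
})

make_pca_scores <- function(n, f) {
  # f: function(i) returning the 5 panel values
  m <- t(vapply(seq_len(n), f, numeric(5)))
  colnames(m) <- c("NDrG", "ISGa", "GBPs", "HLAd", "LYMd")
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%04d", seq_len(n))),
                   tibble::as_tibble(m))
}

test_that("PCA on uncorrelated panels is near-isotropic", {
  set.seed(8)
  sc <- make_pca_scores(2000, function(i) rnorm(5))
  pc <- pca_panels(sc, k = 5)
  expect_equal(pc$variance_explained, rep(0.2, 5), tolerance = 0.05)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-9)
})

test_that("a two-factor structure loads as published: NDrG/HLAd/LYMd on PC1", {
  set.seed(9)
  sc <- make_pca_scores(500, function(i) {
    f1 <- rnorm(1); f2 <- rnorm(1)
    c(f1, f2, f2, -f1, -f1) + rnorm(5, sd = 0.3)
  })
  pc <- pca_panels(sc, k = 2)
  l <- abs(pc$loadings)
  expect_true(min(l[c("NDrG", "HLAd", "LYMd"), 1]) >
                max(l[c("ISGa", "GBPs"), 1]))
  expect_true(min(l[c("ISGa", "GBPs"), 2]) >
                max(l[c("NDrG", "HLAd", "LYMd"), 2]))
})

test_that("PC1 variance fraction matches the eigendecomposition oracle", {
  set.seed(10)
  sc <- make_pca_scores(300, function(i) {
    f <- rnorm(1)
    c(f, 0.5 * f, 0.2 * f, -f, -0.8 * f) + rnorm(5, sd = 0.4)
  })
  pc <- pca_panels(sc, k = 1)
  ev <- eigen(stats::cor(as.matrix(sc[, -1])))$values
  expect_equal(pc$variance_explained[1], ev[1] / 5, tolerance = 1e-9)
})

test_that("PCA fixes loading signs and rejects constant panels", {
  set.seed(11)
  sc <- make_pca_scores(50, function(i) rnorm(5))
  pc <- pca_panels(sc, k = 3)
  for (j in 1:3) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  sc$GBPs <- 1
  expect_error(pca_panels(sc, k = 2), "constant")
})

test_that("tidy and glance methods summarize a panel PCA", {
  set.seed(12)
  sc <- make_pca_scores(40, function(i) rnorm(5))
  pc <- pca_panels(sc, k = 2)
  td <- generics::tidy(pc)
  expect_equal(nrow(td), 10)
  expect_named(td, c("panel", "component", "loading"))
  gl <- generics::glance(pc)
  expect_equal(gl$n, 40)
  expect_equal(gl$k, 2)
})
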