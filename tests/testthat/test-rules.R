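test_that("rule clauses use strict inequalities and OR semantics", {
  scores <- tibble::tibble(sample_id = c("a", "b", "c"),
                           composite = c(1.49, 1.50, 2.0))
  records <- as_sample_records(tibble::tibble(
    sample_id = c("a", "b", "c"), sofa = c(10L, 10L, 7L),
    outcome = "survivor"
  ))
  comp_only <- apply_rule(scores, records, rule_spec(sofa = NULL))
  expect_equal(comp_only$predicted,
               c("survivor", "not_identified", "not_identified"))
  combined <- apply_rule(scores, records, rule_spec())
  expect_equal(combined$predicted[3], "survivor")  # SOFA clause fires
})

test_that("the GBPs extension clause fires above its threshold", {
  scores <- tibble::tibble(sample_id = c("a", "b"),
                           composite = c(3, 3), GBPs = c(8.6, 8.5))
  records <- as_sample_records(tibble::tibble(sample_id = c("a", "b"),
                                              sofa = c(20L, 20L)))
  preds <- apply_rule(scores, records, rule_spec(gbps = 8.5))
  expect_equal(preds$predicted, c("survivor", "not_identified"))
})

test_that("samples missing an enabled clause input are unevaluable", {
  scores <- tibble::tibble(sample_id = c("a", "b"), composite = c(0.5, 0.5))
  records <- as_sample_records(tibble::tibble(
    sample_id = c("a", "b"), sofa = c(NA_integer_, 5L)
  ))
  preds <- apply_rule(scores, records, rule_spec())
  expect_equal(preds$predicted, c("unevaluable", "survivor"))
})

test_that("rule_spec requires an enabled, finite clause", {
  expect_error(rule_spec(composite = NULL, sofa = NULL), "at least one")
  expect_error(rule_spec(composite = Inf), "finite")
})

test_that("evaluation reproduces the published worked examples", {
  # 45/60 survivors with zero false positives
  e1 <- evaluate_rule(
    tibble::tibble(sample_id = sprintf("s%02d", 1:78),
                   predicted = rep(c("survivor", "not_identified"),
                                   c(45, 33))),
    as_sample_records(tibble::tibble(
      sample_id = sprintf("s%02d", 1:78),
      outcome = rep(c("survivor", "non-survivor"), c(60, 18))
    ))
  )
  expect_equal(c(e1$tp, e1$fp, e1$fn, e1$tn), c(45, 0, 15, 18))
  expect_equal(e1$sensitivity, 0.75)
  expect_equal(e1$false_positives, 0)

  # 54/60 survivors with 2 false positives
  e2 <- evaluate_rule(
    tibble::tibble(
      sample_id = sprintf("s%02d", 1:78),
      predicted = rep(c("survivor", "not_identified", "survivor",
                        "not_identified"), c(54, 6, 2, 16))
    ),
    as_sample_records(tibble::tibble(
      sample_id = sprintf("s%02d", 1:78),
      outcome = rep(c("survivor", "non-survivor"), c(60, 18))
    ))
  )
  expect_equal(e2$sensitivity, 0.90)
  expect_equal(e2$false_discovery_fraction, 2 / 56)
  expect_equal(e2$fpr_among_nonsurvivors, 2 / 18)
})

test_that("unknown outcomes and unevaluable predictions are tallied apart", {
  preds <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          predicted = c("survivor", "unevaluable",
                                        "survivor", "not_identified"))
  recs <- as_sample_records(tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    outcome = c("survivor", "survivor", "unknown", "non-survivor")
  ))
  ev <- evaluate_rule(preds, recs)
  expect_equal(ev$n_evaluated, 2)
  expect_equal(ev$n_unknown_outcome, 1)
  expect_equal(ev$n_unevaluable, 1)
  expect_error(
    evaluate_rule(preds[3, ], recs[3, ]),
    "no samples"
  )
})

test_that("confusion counts partition the known outcomes (random fixtures)", {
  set.seed(20)
  for (i in 1:25) {
    n_s <- sample(3:20, 1); n_n <- sample(2:10, 1)
    fx <- outcome_fixture(rnorm(n_s, 1), rnorm(n_n, 3),
                          sample(0:24, n_s, TRUE), sample(0:24, n_n, TRUE))
    ev <- evaluate_rule(apply_rule(fx$scores, fx$records), fx$records)
    expect_equal(ev$tp + ev$fn, n_s)
    expect_equal(ev$fp + ev$tn, n_n)
    expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, ev$n_evaluated)
  }
})

test_that("zero_fp_threshold matches the hand example and edge orderings", {
  fx <- outcome_fixture(c(0.5, 1.0, 2.0), c(1.8, 3.0))
  z <- zero_fp_threshold(fx$scores, fx$records)
  expect_equal(z$threshold, 1.8)
  expect_equal(z$sensitivity, 2 / 3)

  worst <- outcome_fixture(c(2, 3, 4), c(0.5, 1))
  expect_equal(zero_fp_threshold(worst$scores, worst$records)$sensitivity, 0)
  perfect <- outcome_fixture(c(0, 1), c(2, 3))
  expect_equal(zero_fp_threshold(perfect$scores,
                                 perfect$records)$sensitivity, 1)
})

test_that("zero_fp_threshold re-applied through the rule gives zero FP", {
  set.seed(21)
  for (i in 1:20) {
    fx <- outcome_fixture(rnorm(sample(2:12, 1), 1),
                          rnorm(sample(1:8, 1), 2))
    z <- zero_fp_threshold(fx$scores, fx$records)
    ev <- evaluate_rule(
      apply_rule(fx$scores, fx$records,
                 rule_spec(composite = z$threshold, sofa = NULL)),
      fx$records
    )
    expect_equal(ev$fp, 0)
    expect_equal(ev$sensitivity, z$sensitivity)
  }
})

test_that("threshold_sweep hits its limits and the worked fixture", {
  fx <- outcome_fixture(c(0.5, 1.0, 2.0), c(1.8, 3.0))
  sw <- threshold_sweep(fx$scores, fx$records, grid = c(-100, 1.9, 100))
  expect_equal(sw$sensitivity[sw$threshold == 100], 1)
  expect_equal(sw$fp[sw$threshold == 100], 2)
  expect_equal(sw$sensitivity[sw$threshold == -100], 0)
  expect_equal(sw$fp[sw$threshold == -100], 0)
  expect_equal(sw$sensitivity[sw$threshold == 1.9], 2 / 3)
  expect_equal(sw$fp[sw$threshold == 1.9], 1)
  expect_true(1.50 %in% sw$threshold)
  expect_error(threshold_sweep(fx$scores, fx$records, grid = numeric()),
               "empty")
})

test_that("adding the SOFA clause never hurts sensitivity (OR monotonicity)", {
  set.seed(22)
  for (i in 1:20) {
    n_s <- sample(4:15, 1); n_n <- sample(2:8, 1)
    fx <- outcome_fixture(rnorm(n_s, 1), rnorm(n_n, 2.5),
                          sample(0:24, n_s, TRUE), sample(0:24, n_n, TRUE))
    comp <- evaluate_rule(
      apply_rule(fx$scores, fx$records, rule_spec(sofa = NULL)), fx$records
    )
    both <- evaluate_rule(
      apply_rule(fx$scores, fx$records, rule_spec()), fx$records
    )
    expect_gte(both$sensitivity, comp$sensitivity)
    expect_gte(both$fp, comp$fp)
  }
})

test_that("missing composite values among known outcomes are reported", {
  fx <- outcome_fixture(c(1, NA), c(2))
  expect_error(zero_fp_threshold(fx$scores, fx$records), "surv02")
})
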