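test_that("the linear estimator recovers a deterministic outcome exactly", {
  m <- make_model("fig1b",
                  coef = list("E->R0" = 0, "R0->R" = 0, "R->D" = 0,
                              "sd:D" = 0))
  cohort <- simulate_cohort(m, 2000, 8)
  # a perfect fit is the point here; summary.lm warns about it
  est <- suppressWarnings(fit_adjusted_difference(cohort))
  expect_equal(est$value, 0.3, tolerance = 1e-12)
  expect_lt(est$se, 1e-8)
  expect_equal(est$estimator, "unadjusted")
})

test_that("design validation rejects bad adjustment requests", {
  cohort <- simulate_cohort(make_model("fig1b"), 1000, 9)
  expect_error(fit_adjusted_difference(cohort, "E"), "exposure or outcome")
  expect_error(fit_adjusted_difference(cohort, "R0"), "unmeasured")

  frozen <- simulate_cohort(apply_do(make_model("fig1b"), c(E = 1)), 500, 2)
  expect_error(fit_adjusted_difference(frozen), "zero-variance")
})

test_that("log odds ratio matches the 2x2 cross-product", {
  # counts (E=1,D=1)=50, (E=1,D=0)=50, (E=0,D=1)=25, (E=0,D=0)=75: OR = 3
  df <- data.frame(E = rep(c(1, 1, 0, 0), c(50, 50, 25, 75)),
                   D = rep(c(1, 0, 1, 0), c(50, 50, 25, 75)))
  roles <- node_roles(causal_dag(rbind(c("E", "D"))), "E", "D")
  cohort <- structure(list(full_population = df, selected = df,
                           seed = 0L, n = nrow(df), roles = roles,
                           do = numeric(0)),
                      class = "simulated_cohort")
  est <- fit_adjusted_odds_ratio(cohort)
  expect_equal(est$value, log(3), tolerance = 1e-8)
  expect_true(attr(est, "noncollapsible"))

  # null association on a balanced table
  null_df <- data.frame(E = rep(c(1, 1, 0, 0), each = 25),
                        D = rep(c(1, 0, 1, 0), times = 25))
  cohort$full_population <- cohort$selected <- null_df
  expect_equal(fit_adjusted_odds_ratio(cohort)$value, 0, tolerance = 1e-8)

  # perfect separation is rejected
  sep_df <- data.frame(E = rep(c(1, 0), each = 50),
                       D = rep(c(1, 0), each = 50))
  cohort$full_population <- cohort$selected <- sep_df
  expect_error(fit_adjusted_odds_ratio(cohort), "separation")
})

test_that("selection weights satisfy their contracts", {
  m <- make_model("fig1b")
  cohort <- simulate_cohort(m, 50000, 21)

  # predictors {E} only: weights constant within exposure groups, so the
  # weighted difference equals the unweighted difference of group means
  w_e <- estimate_selection_weights(cohort, "E")
  sel <- selected_view(cohort)
  expect_equal(length(unique(round(w_e$w[sel$E == 1], 12))), 1L)
  expect_equal(length(unique(round(w_e$w[sel$E == 0], 12))), 1L)
  weighted <- fit_adjusted_difference(cohort, weights = w_e)
  unweighted <- fit_adjusted_difference(cohort)
  expect_equal(weighted$value, unweighted$value, tolerance = 1e-10)
  expect_equal(weighted$estimator, "ipw")

  # equal weights reduce the weighted estimator to the unweighted one
  w_flat <- w_e
  w_flat$w <- rep(2, length(w_flat$w))
  expect_equal(fit_adjusted_difference(cohort, weights = w_flat)$value,
               unweighted$value, tolerance = 1e-10)

  # all probabilities in (0,1], weights positive and finite
  wv <- estimate_selection_weights(cohort, c("E", "R0"))
  expect_true(all(wv$p > 0 & wv$p <= 1))
  expect_true(all(is.finite(wv$w) & wv$w > 0))

  expect_error(estimate_selection_weights(cohort, "nope"), "unknown")
  expect_error(estimate_selection_weights(cohort, c("E", "R0"),
                                          p_floor = 0.9), "positivity")
})

test_that("replicate_bias applies the pre-registered verdict rule", {
  m <- make_model("fig1b")
  rep_adj <- replicate_bias(m, "adjust:R", replicates = 6, n = 20000,
                            master_seed = 41)
  expect_equal(rep_adj$verdict, "recovers_cde")
  expect_equal(rep_adj$truth_total, 0.5)
  expect_equal(rep_adj$truth_cde, 0.3)
  expect_length(rep_adj$estimates, 6L)

  rep_none <- replicate_bias(m, "none", replicates = 8, n = 50000,
                             master_seed = 41)
  expect_equal(rep_none$verdict, "biased")

  expect_error(replicate_bias(m, "none", replicates = 1), ">= 2")
  expect_error(replicate_bias(m, "frobnicate"), "unknown strategy")

  # verdict stabilizes across disjoint master seeds
  rep_adj2 <- replicate_bias(m, "adjust:R", replicates = 6, n = 20000,
                             master_seed = 4242)
  expect_equal(rep_adj2$verdict, rep_adj$verdict)

  df <- as.data.frame(rep_adj)
  expect_equal(df$verdict, "recovers_cde")
  expect_equal(df$model_label, "fig1b")
})

test_that("IPW recovers the total effect only when correctly specified", {
  m <- make_model("fig1b")
  good <- replicate_bias(m, "ipw:E,R0", replicates = 8, n = 1e5,
                         master_seed = 13)
  expect_equal(good$verdict, "recovers_total")
  # omitting the risk factor from the selection model leaves the bias
  bad <- replicate_bias(m, "ipw:E", replicates = 8, n = 1e5,
                        master_seed = 13)
  expect_equal(bad$verdict, "biased")
})
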