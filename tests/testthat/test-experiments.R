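# Reduced-budget experiment runs; the full default-budget runs live in
# test-acceptance.R.

small_config <- function(seed = 1) {
  experiment_config(replicates = 8, n = 50000, master_seed = seed)
}

test_that("the effect grid is concordant at a reduced budget and a second seed", {
  grid <- run_effect_grid(small_config(seed = 202))
  applicable <- grid[!is.na(grid$concordant), ]
  expect_gte(nrow(applicable), 16L)
  expect_true(all(applicable$concordant))
  # IPW cells masked where inapplicable: no selection arrow from the risk
  # factor (models C, D) or a post-migration arrow out of S
  skipped <- grid[is.na(grid$concordant), ]
  expect_setequal(skipped$model_label,
                  c("C", "D", "postmigration_variant"))
  expect_true(all(skipped$simulation_verdict == "skipped"))
})

test_that("the no-adjustment column reproduces the summary-table pattern", {
  grid <- run_effect_grid(small_config(seed = 77))
  none <- grid[grid$strategy_label == "none", ]
  expect_equal(none$simulation_verdict[none$model_label == "A"], "biased")
  expect_equal(none$simulation_verdict[none$model_label == "B"], "biased")
  expect_equal(none$simulation_verdict[none$model_label == "C"],
               "recovers_total")
  expect_equal(none$simulation_verdict[none$model_label == "D"],
               "recovers_total")
})

test_that("grid output is byte-identical across re-runs", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- experiment_config(replicates = 3, n = 5000, master_seed = 5)
  run_effect_grid(cfg, out_dir = dir1)
  run_effect_grid(cfg, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "grid.csv")),
                   readLines(file.path(dir2, "grid.csv")))
})

test_that("preeclampsia adjustment models classify as expected", {
  res <- preeclampsia_example()
  expect_equal(res$without_SES$effect_type, "BIASED")
  expect_equal(res$with_SES$effect_type, "CONTROLLED_DIRECT")
  # the SES-omitting model leaves the selection path through R02/SES open
  open <- vapply(res$without_SES$open_noncausal_paths, path_string,
                 character(1L))
  expect_true(any(grepl("R02", open)))

  # post-migration arrows (S -> SES, SES -> maternal age) change nothing:
  # every measured risk factor remains an adjusted mediator
  res2 <- preeclampsia_example(postmigration_arrows = TRUE)
  expect_equal(res2$without_SES$effect_type, "BIASED")
  expect_equal(res2$with_SES$effect_type, "CONTROLLED_DIRECT")
})

test_that("attenuation bias vanishes at zero measurement noise and grows with it", {
  att <- attenuation_study(noise_grid = c(0, 0.5, 1),
                           config = small_config(seed = 3))
  expect_equal(nrow(att), 3L)
  expect_true(attr(att, "zero_at_origin"))
  expect_true(attr(att, "monotone"))
  expect_gt(att$abs_bias[att$noise_sd == 1],
            att$abs_bias[att$noise_sd == 0])
  expect_error(attenuation_study(noise_grid = c(0.5, 1)), "include 0")

  single <- attenuation_study(noise_grid = 0, config = small_config(seed = 3))
  expect_equal(nrow(single), 1L)
  expect_true(attr(single, "zero_at_origin"))
})

test_that("ignoring an exposure-mediator interaction biases the CDE", {
  # more replicates than the other reduced-budget runs: the 3-SE recovery
  # check needs a stable spread estimate
  int_config <- experiment_config(replicates = 20, n = 20000, master_seed = 9)
  res <- interaction_study(int_config)
  correct <- res[res$fit == "correct", ]
  misspec <- res[res$fit == "misspecified", ]
  expect_true(correct$recovers_cde)
  expect_false(misspec$recovers_cde)
  expect_equal(correct$truth_cde, 0.3)

  # no interaction: both fits agree
  res0 <- suppressMessages(
    interaction_study(int_config, interaction = 0))
  expect_lt(abs(res0$mean_estimate[1L] - res0$mean_estimate[2L]), 0.01)
  expect_true(all(res0$recovers_cde))
})
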