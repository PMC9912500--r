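test_that("classifier reproduces the combined mediator/selection verdicts", {
  dag <- fig1b_dag()
  roles <- fig1b_roles(dag)

  adj <- classify_adjusted_effect(dag, roles, "R")
  expect_equal(adj$effect_type, "CONTROLLED_DIRECT")
  expect_length(adj$open_noncausal_paths, 0L)
  expect_equal(path_string(adj$blocked_causal_paths[[1L]]), "E-R0-R-D")
  expect_setequal(adj$conditioning_set, c("R", "S"))

  unadj <- classify_adjusted_effect(dag, roles, character(0))
  expect_equal(unadj$effect_type, "BIASED")
  expect_equal(path_string(unadj$open_noncausal_paths[[1L]]), "E-S-R0-R-D")
})

test_that("mediator-outcome confounding needs the extra adjustment", {
  m <- make_model("fig1c")
  expect_equal(classify_adjusted_effect(m$dag, m$roles, "R")$effect_type,
               "BIASED")
  expect_equal(classify_adjusted_effect(m$dag, m$roles, c("R", "C"))$effect_type,
               "CONTROLLED_DIRECT")
})

test_that("selection-only, mediator-only, and neither-role models classify correctly", {
  b <- make_model("fig1d", time_constant = TRUE)  # time-constant risk factor
  expect_equal(classify_adjusted_effect(b$dag, b$roles, "R")$effect_type,
               "TOTAL")
  expect_equal(classify_adjusted_effect(b$dag, b$roles, character(0))$effect_type,
               "BIASED")

  cc <- make_model("modelC")
  expect_equal(classify_adjusted_effect(cc$dag, cc$roles, "R")$effect_type,
               "CONTROLLED_DIRECT")
  expect_equal(classify_adjusted_effect(cc$dag, cc$roles, character(0))$effect_type,
               "TOTAL")

  d <- make_model("modelD")
  expect_equal(classify_adjusted_effect(d$dag, d$roles, character(0))$effect_type,
               "TOTAL")
  expect_equal(classify_adjusted_effect(d$dag, d$roles, "R")$effect_type,
               "TOTAL")
})

test_that("a causal path through the selection node counts as blocked", {
  # membership itself changes the measured risk factor (S -> R): the
  # directed path E -> S -> R -> D is held fixed by the S = 1 restriction,
  # so adjusted estimates are controlled direct, not total
  pm <- make_model("fig1d_postmigration")
  cls <- classify_adjusted_effect(pm$dag, pm$roles, c("R", "C"))
  expect_equal(cls$effect_type, "CONTROLLED_DIRECT")
  expect_true("E-S-R-D" %in%
                vapply(cls$blocked_causal_paths, path_string, character(1L)))
  expect_equal(classify_adjusted_effect(pm$dag, pm$roles, "R")$effect_type,
               "BIASED")
})

test_that("adjustment sets are validated", {
  dag <- fig1b_dag()
  roles <- fig1b_roles(dag)
  expect_error(classify_adjusted_effect(dag, roles, "R0"), "unmeasured")
  expect_error(classify_adjusted_effect(dag, roles, "E"),
               "exposure or outcome")
  expect_error(classify_adjusted_effect(dag, roles, "D"),
               "exposure or outcome")
})

test_that("classification is invariant under role-preserving relabeling", {
  relabel <- c(E = "exposure", D = "outcome", R0 = "pre", R = "meas",
               S = "sel")
  dag <- fig1b_dag()
  edges2 <- cbind(relabel[dag$edges[, 1L]], relabel[dag$edges[, 2L]])
  dag2 <- causal_dag(edges2)
  roles2 <- node_roles(dag2, "exposure", "outcome", selection = "sel",
                       risk_factors_pre = "pre",
                       risk_factors_measured = "meas")
  for (adj in list(character(0), "R")) {
    v1 <- classify_adjusted_effect(dag, fig1b_roles(dag), adj)$effect_type
    v2 <- classify_adjusted_effect(dag2, roles2,
                                   unname(relabel[adj]))$effect_type
    expect_equal(v1, v2)
  }
})
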