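test_that("model templates build the documented structures", {
  m <- make_model("fig1b")
  expect_length(m$dag$nodes, 5L)
  expect_equal(nrow(m$dag$edges), 6L)
  expect_equal(m$assignments$D$coef[["E"]], 0.3)
  expect_equal(m$assignments$S$intercept, 2.0)

  pm <- make_model("fig1d_postmigration")
  expect_true(any(pm$dag$edges[, 1L] == "S" & pm$dag$edges[, 2L] == "R"))

  tc <- make_model("fig1d", time_constant = TRUE)
  expect_false("R0" %in% tc$dag$nodes)            # merged pre/post node
  expect_true("R" %in% tc$roles$measured)

  expect_error(make_model("fig1b", coef = list("E->C" = 1)), "non-edge")
  expect_error(make_model("fig1b", coef = list("sd:R" = -1)), ">= 0")
  expect_error(make_model("nope"), "arg")
})

test_that("custom DAG models validate and simulate", {
  dag <- dag_from_strings(c("E -> D", "E -> M", "M -> D"))
  roles <- node_roles(dag, "E", "D", risk_factors_measured = "M")
  m <- make_model(dag = dag, roles = roles,
                  coef = list("E->D" = 0.1, "E->M" = 1, "M->D" = 0.2))
  truth <- analytic_effects(m)
  expect_equal(truth$total_effect, 0.3)
  expect_equal(truth$cde, 0.1)
})

test_that("simulation is reproducible and respects the assignments", {
  m <- make_model("fig1b")
  a <- simulate_cohort(m, 1000, 11)
  b <- simulate_cohort(m, 1000, 11)
  expect_identical(a$full_population, b$full_population)
  expect_identical(a$selected, b$selected)
  expect_true(all(a$selected$S == 1))
  expect_error(simulate_cohort(m, 0, 1), ">= 1")

  # parameter recovery at moderate n: each regression of a node on its
  # parents returns the generating coefficient within 3 classical SEs
  big <- simulate_cohort(m, 50000, 5)$full_population
  f <- stats::lm(D ~ E + R, data = big)
  expect_lt(abs(stats::coef(f)[["E"]] - 0.3),
            3 * sqrt(stats::vcov(f)["E", "E"]))
  expect_lt(abs(stats::coef(f)[["R"]] - 0.4),
            3 * sqrt(stats::vcov(f)["R", "R"]))
})

test_that("simulated joint distribution satisfies the DAG's independencies", {
  # fig1c implies e.g. E independent of C, and R independent of E given R0;
  # partial correlations at n = 1e5 should be within sampling noise of 0
  m <- make_model("fig1c")
  df <- simulate_cohort(m, 1e5, 31)$full_population
  z_corr <- function(x, y) abs(cor(x, y)) * sqrt(length(x))
  expect_lt(z_corr(df$E, df$C), 4)
  r_resid <- stats::resid(stats::lm(R ~ R0, data = df))
  e_resid <- stats::resid(stats::lm(E ~ R0, data = df))
  expect_lt(z_corr(r_resid, e_resid), 4)
  # ...whereas d-connected pairs show association
  expect_gt(z_corr(df$E, df$R0), 10)
})

test_that("do-interventions sever incoming edges and fix values", {
  m <- make_model("fig1b")
  m1 <- apply_do(m, c(E = 1))
  expect_equal(m1$assignments$E, list(type = "constant", value = 1))
  expect_true(all(simulate_cohort(m1, 100, 1)$full_population$E == 1))

  m2 <- apply_do(m, c(E = 1, R = 0.5))
  expect_length(m2$dag$parents[["R"]], 0L)
  expect_true(all(simulate_cohort(m2, 100, 1)$full_population$R == 0.5))

  expect_error(apply_do(m, c(nope = 1)), "unknown")

  # do on the selection node contradicts selected-view statistics
  ms <- apply_do(m, c(S = 1))
  cohort <- simulate_cohort(ms, 100, 1)
  expect_error(selected_view(cohort), "do-intervention")
})

test_that("do(E) leaves marginals of non-descendants unchanged", {
  m <- make_model("fig1c")
  obs <- simulate_cohort(m, 1e5, 17)$full_population
  int <- simulate_cohort(apply_do(m, c(E = 1)), 1e5, 18)$full_population
  # C is a non-descendant of E: same standard-normal marginal
  expect_lt(abs(mean(obs$C) - mean(int$C)), 4 * sqrt(2 / 1e5))
  expect_lt(abs(stats::sd(obs$C) - stats::sd(int$C)), 0.02)
})

test_that("cohorts round-trip through CSV", {
  m <- make_model("fig1b")
  cohort <- simulate_cohort(m, 500, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path, m$roles)
  expect_equal(back$full_population, cohort$full_population,
               ignore_attr = TRUE)
  expect_equal(nrow(back$selected), nrow(cohort$selected))
  expect_equal(names(back$full_population), names(cohort$full_population))
})
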