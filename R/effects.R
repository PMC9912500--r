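# Ground-truth effects via the do-operator: analytic linear path tracing for
# linear-Gaussian mediation, Monte Carlo contrasts otherwise.

# Remove the selection node's outgoing edges (used for the
# "total effect excluding S-paths" reading).
.strip_selection_outedges <- function(model) {
  s <- model$roles$selection
  if (is.null(s) || !length(model$dag$children[[s]])) return(model)
  keep <- model$dag$edges[, 1L] != s
  model$dag <- causal_dag(model$dag$edges[keep, , drop = FALSE],
                          nodes = model$dag$nodes)
  for (v in model$dag$nodes) {
    a <- model$assignments[[v]]
    if (!is.null(a$coef) && s %in% names(a$coef)) {
      a$coef <- a$coef[setdiff(names(a$coef), s)]
      model$assignments[[v]] <- a
    }
  }
  model
}

# Expected value of every continuous node under do(exposure = e) and
# optionally do(mediators = m), by linear mean propagation in topological
# order. Refuses when a path from the exposure to the outcome passes through
# the (logistic) selection node, which breaks linearity.
.propagate_means <- function(model, e, fixed = numeric(0)) {
  roles <- model$roles
  mu <- stats::setNames(rep(NA_real_, length(model$dag$nodes)),
                        model$dag$nodes)
  for (v in topological_order(model$dag)) {
    a <- model$assignments[[v]]
    if (v == roles$exposure && a$type != "constant") { mu[v] <- e; next }
    if (v %in% names(fixed)) { mu[v] <- fixed[[v]]; next }
    mu[v] <- switch(a$type,
      constant = a$value,
      bernoulli = a$p,
      logistic = NA_real_,  # only acceptable when S has no outcome-bound path
      linear = {
        m <- a$intercept
        for (p in names(a$coef)) m <- m + a$coef[[p]] * mu[[p]]
        if (!is.null(a$interaction))
          m <- m + a$interaction$coef * mu[[a$interaction$exposure]] *
            mu[[a$interaction$mediator]]
        m
      })
  }
  mu
}

#' Analytic total and controlled direct effects
#'
#' Computes the ground-truth total effect (difference in the outcome mean
#' under `do(exposure = 1)` vs `do(exposure = 0)`) and the controlled direct
#' effect at a mediator reference value, by linear path tracing (equivalently
#' mean propagation) through the linear-Gaussian assignments. Both the total
#' including paths through the selection node and the total excluding them
#' are reported; for every model without an arrow out of S these coincide.
#'
#' Models in which the selection node causally affects the outcome (an S-to-R
#' arrow) are refused: the logistic selection link breaks path-product
#' linearity, and [mc_effects()] must be used instead.
#'
#' @param model A [make_model()] structural model.
#' @param m_reference Mediator reference value for the controlled direct
#'   effect (all measured risk-factor mediators are fixed at this value).
#'   With no exposure-mediator interaction the CDE does not depend on it.
#' @return An object of class `truth_values` with `total_effect`,
#'   `total_effect_excluding_S_paths`, `cde`, `m_reference`,
#'   `method = "analytic"`, and `mc_se = NULL`.
#' @examples
#' analytic_effects(make_model("fig1b"))  # total 0.5, cde 0.3
#' @export
analytic_effects <- function(model, m_reference = 0) {
  stopifnot(inherits(model, "structural_model"))
  roles <- model$roles
  s <- roles$selection
  if (!is.null(s) && length(model$dag$children[[s]]))
    stop("analytic total effects are refused for models with an arrow out of ",
         "the selection node (the logistic link breaks linear path tracing); ",
         "use mc_effects()")
  out <- roles$outcome
  tot <- .propagate_means(model, 1)[[out]] - .propagate_means(model, 0)[[out]]
  mediators <- intersect(roles$risk_factors_measured,
                         dag_ancestors(model$dag, out, include_self = FALSE))
  fixed <- stats::setNames(rep(m_reference, length(mediators)), mediators)
  cde <- .propagate_means(model, 1, fixed)[[out]] -
         .propagate_means(model, 0, fixed)[[out]]
  structure(
    list(total_effect = tot, total_effect_excluding_S_paths = tot,
         cde = cde, m_reference = m_reference, method = "analytic",
         mc_se = NULL),
    class = "truth_values")
}

#' Monte Carlo total and controlled direct effects
#'
#' Simulates do-intervention contrasts on the full population:
#' `total = mean(D | do(E = 1)) - mean(D | do(E = 0))` and
#' `cde = mean(D | do(E = 1, R = m)) - mean(D | do(E = 0, R = m))`, with all
#' measured risk-factor mediators fixed at `m`. The two arms of each
#' contrast share a seed (common random numbers), and the reported Monte
#' Carlo standard error is that of the paired difference. The total
#' excluding paths through the selection node is computed on the model with
#' the selection node's outgoing edges severed.
#'
#' @inheritParams analytic_effects
#' @param n Rows per arm.
#' @param seed Integer seed.
#' @return A `truth_values` object with `method = "monte_carlo"` and `mc_se`
#'   a named vector (`total`, `total_excluding_S`, `cde`).
#' @export
mc_effects <- function(model, n, seed, m_reference = 0) {
  stopifnot(inherits(model, "structural_model"))
  roles <- model$roles
  contrast <- function(mod, fixed, sd_seed) {
    d1 <- simulate_cohort(apply_do(mod, c(stats::setNames(1, roles$exposure),
                                          fixed)), n, sd_seed)
    d0 <- simulate_cohort(apply_do(mod, c(stats::setNames(0, roles$exposure),
                                          fixed)), n, sd_seed)
    diff <- d1$full_population[[roles$outcome]] -
            d0$full_population[[roles$outcome]]
    c(mean(diff), stats::sd(diff) / sqrt(n))
  }
  seeds <- derive_seeds(seed, 3L)
  mediators <- intersect(roles$risk_factors_measured,
                         dag_ancestors(model$dag, roles$outcome,
                                       include_self = FALSE))
  fixed <- stats::setNames(rep(m_reference, length(mediators)), mediators)

  tot <- contrast(model, numeric(0), seeds[1L])
  tot_ex <- contrast(.strip_selection_outedges(model), numeric(0), seeds[2L])
  cde <- contrast(model, fixed, seeds[3L])
  structure(
    list(total_effect = tot[1L], total_effect_excluding_S_paths = tot_ex[1L],
         cde = cde[1L], m_reference = m_reference, method = "monte_carlo",
         mc_se = c(total = tot[2L], total_excluding_S = tot_ex[2L],
                   cde = cde[2L])),
    class = "truth_values")
}

#' @export
print.truth_values <- function(x, ...) {
  cat(sprintf("ground-truth effects (%s):\n", x$method))
  cat(sprintf("  total effect:                 %.5f\n", x$total_effect))
  cat(sprintf("  total excluding S-paths:      %.5f\n",
              x$total_effect_excluding_S_paths))
  cat(sprintf("  controlled direct (m = %g):   %.5f\n", x$m_reference, x$cde))
  if (!is.null(x$mc_se))
    cat("  mc se:", paste(sprintf("%s %.2g", names(x$mc_se), x$mc_se),
                          collapse = ", "), "\n")
  invisible(x)
}
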