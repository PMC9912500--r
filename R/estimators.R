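# Regression estimators whose behavior the effect-type classifier predicts,
# the IPW estimator for recovering total effects under selection on the risk
# factor, and replicate-level bias quantification.

#' Adjusted mean-difference estimator
#'
#' Least-squares coefficient of the exposure from a linear model of the
#' outcome on the exposure plus the adjustment set, fit by default on the
#' selected view (the S = 1 sample, the common analysis in practice).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param adjust_set Character vector of measured covariates (may be empty).
#'   The exposure and outcome are rejected; so are unmeasured nodes.
#' @param use_selected_only Fit on the selected view (default) or the full
#'   population (diagnostics).
#' @param weights Optional [estimate_selection_weights()] result; when given,
#'   a weighted fit is performed and a robust sandwich standard error is
#'   reported (weighting induces heteroscedasticity).
#' @param include_interaction Add the exposure-by-mediator product term (the
#'   mediator being the first adjusted measured risk factor); the estimate is
#'   then the controlled direct effect read at `m_reference`.
#' @param m_reference Mediator value at which the interaction fit is read.
#' @return An object of class `effect_estimate`: `value`, `se`, `estimator`
#'   (`"unadjusted"`, `"adjusted"`, or `"ipw"`), `adjustment_set`, `n_used`,
#'   `weighted`.
#' @export
fit_adjusted_difference <- function(cohort, adjust_set = character(0),
                                    use_selected_only = TRUE, weights = NULL,
                                    include_interaction = FALSE,
                                    m_reference = 0) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  roles <- cohort$roles
  adjust_set <- unique(as.character(adjust_set))
  if (length(intersect(adjust_set, c(roles$exposure, roles$outcome))))
    stop("the adjustment set may not contain the exposure or outcome")
  bad <- setdiff(adjust_set, roles$measured)
  if (length(bad))
    stop("adjustment set contains unmeasured node(s): ",
         paste(bad, collapse = ", "))
  data <- if (use_selected_only) selected_view(cohort) else
    cohort$full_population
  if (!nrow(data)) stop("the selected view is empty")

  for (v in c(roles$exposure, adjust_set)) {
    if (stats::var(data[[v]]) == 0)
      stop("zero-variance design column: ", v)
  }

  rhs <- c(roles$exposure, adjust_set)
  interaction_term <- NULL
  if (include_interaction) {
    med <- intersect(adjust_set, roles$risk_factors_measured)
    if (!length(med))
      stop("include_interaction requires a measured risk factor in the adjustment set")
    interaction_term <- paste0(roles$exposure, ":", med[1L])
    rhs <- c(rhs, interaction_term)
  }
  fml <- stats::reformulate(rhs, response = roles$outcome)

  w <- NULL
  estimator <- if (length(adjust_set)) "adjusted" else "unadjusted"
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "weight_vector"))
    if (!use_selected_only)
      stop("selection weights apply to the selected view only")
    if (length(weights$w) != nrow(data))
      stop("weight vector length does not match the selected view")
    w <- weights$w
    estimator <- "ipw"
  }

  fit <- if (is.null(w)) stats::lm(fml, data = data)
         else stats::lm(fml, data = data, weights = w)
  vc <- if (is.null(w)) stats::vcov(fit) else sandwich::vcovHC(fit, type = "HC0")
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular design: ",
                      paste(names(cf)[is.na(cf)], collapse = ", "))

  e <- roles$exposure
  if (include_interaction) {
    it <- intersect(c(interaction_term,
                      sub("^(.*):(.*)$", "\\2:\\1", interaction_term)),
                    names(cf))[1L]
    value <- cf[[e]] + m_reference * cf[[it]]
    se <- sqrt(vc[e, e] + m_reference^2 * vc[it, it] +
                 2 * m_reference * vc[e, it])
  } else {
    value <- cf[[e]]
    se <- sqrt(vc[e, e])
  }
  structure(
    list(value = unname(value), se = unname(se), estimator = estimator,
         adjustment_set = sort(adjust_set), n_used = nrow(data),
         weighted = !is.null(w)),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s%s estimate: %.5f (se %.5f, n = %d)\n",
              x$estimator,
              if (length(x$adjustment_set))
                paste0(" [", paste(x$adjustment_set, collapse = ", "), "]")
              else "",
              x$value, x$se, x$n_used))
  invisible(x)
}

#' Adjusted log-odds-ratio estimator
#'
#' Logistic-regression coefficient of the exposure after dichotomizing the
#' outcome at `threshold` (or using it as is when already binary). Reported
#' on the log-odds scale and flagged non-collapsible: unlike the mean
#' difference, conditional and marginal odds ratios differ even without
#' confounding, so classifier verdicts are checked on the linear scale.
#'
#' @inheritParams fit_adjusted_difference
#' @param threshold Dichotomization cut point for a continuous outcome.
#' @return An `effect_estimate` (log odds ratio) with attribute
#'   `noncollapsible = TRUE`.
#' @export
fit_adjusted_odds_ratio <- function(cohort, adjust_set = character(0),
                                    threshold = 0, use_selected_only = TRUE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  roles <- cohort$roles
  data <- if (use_selected_only) selected_view(cohort) else
    cohort$full_population
  y <- data[[roles$outcome]]
  if (!all(y %in% c(0, 1))) y <- as.integer(y > threshold)
  if (length(unique(y)) < 2L) stop("dichotomized outcome is constant")
  data$.y <- y
  fml <- stats::reformulate(c(roles$exposure, adjust_set), response = ".y")
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = data))
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10))
    stop("perfect separation (fitted probabilities of 0 or 1); the log ",
         "odds ratio is not identified")
  est <- structure(
    list(value = unname(stats::coef(fit)[[roles$exposure]]),
         se = unname(sqrt(stats::vcov(fit)[roles$exposure, roles$exposure])),
         estimator = if (length(adjust_set)) "adjusted" else "unadjusted",
         adjustment_set = sort(unique(adjust_set)), n_used = nrow(data),
         weighted = FALSE),
    class = "effect_estimate")
  attr(est, "noncollapsible") <- TRUE
  est
}

#' Inverse-probability-of-selection weights
#'
#' Fits a logistic model of the selection indicator on the given predictors
#' over the *full* population (the estimator's data requirement: the risk
#' factor distribution must be known both for the selected sample and for
#' the origin population), evaluates the selection probability p for every
#' selected row, and returns weights 1/p.
#'
#' @param cohort A [simulate_cohort()] result with a selection node and full
#'   population available.
#' @param predictors Character vector of predictor nodes; defaults to the
#'   parents of the selection node (the correctly specified model).
#' @param normalization `"none"` (default) or `"mean-one"` (weights rescaled
#'   to mean 1; leaves weighted least squares invariant).
#' @param p_floor Reject when any fitted selection probability falls below
#'   this positivity floor.
#' @return An object of class `weight_vector`: `p`, `w`, `predictors`,
#'   `normalization`.
#' @export
estimate_selection_weights <- function(cohort, predictors = NULL,
                                       normalization = c("none", "mean-one"),
                                       p_floor = 1e-6) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  normalization <- match.arg(normalization)
  roles <- cohort$roles
  if (is.null(roles$selection))
    stop("the cohort's model has no selection node")
  full <- cohort$full_population
  sel <- selected_view(cohort)
  if (is.null(predictors)) {
    stop("`predictors` must name the selection-model covariates")
  }
  predictors <- unique(as.character(predictors))
  if (!all(predictors %in% names(full)))
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, names(full)), collapse = ", "))
  fml <- stats::reformulate(predictors, response = roles$selection)
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = full))
  p <- stats::predict(fit, newdata = sel, type = "response")
  if (any(p < p_floor))
    stop("positivity violation: fitted selection probability below ",
         format(p_floor), " for ", sum(p < p_floor), " selected row(s)")
  w <- 1 / p
  if (normalization == "mean-one") w <- w / mean(w)
  structure(list(p = unname(p), w = unname(w), predictors = predictors,
                 normalization = normalization),
            class = "weight_vector")
}

#' Parse an estimation-strategy label
#'
#' Strategies are written `"none"`, `"adjust:R,C"`, or `"ipw:E,R0"` (the
#' `ipw` node list names the selection-model predictors; when omitted, the
#' parents of the selection node are used).
#'
#' @param strategy Strategy string, or an already-parsed list.
#' @return A list with `type` (`"none"`, `"adjust"`, `"ipw"`) and `nodes`.
#' @export
parse_strategy <- function(strategy) {
  if (is.list(strategy)) {
    stopifnot(strategy$type %in% c("none", "adjust", "ipw"))
    strategy$nodes <- as.character(strategy$nodes %||% character(0))
    return(strategy)
  }
  stopifnot(is.character(strategy), length(strategy) == 1L)
  parts <- strsplit(strategy, ":", fixed = TRUE)[[1L]]
  type <- parts[1L]
  if (!type %in% c("none", "adjust", "ipw"))
    stop("unknown strategy: ", strategy)
  nodes <- if (length(parts) > 1L)
    trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) else character(0)
  if (type == "adjust" && !length(nodes))
    stop("strategy 'adjust' needs at least one node, e.g. \"adjust:R\"")
  list(type = type, nodes = nodes)
}

strategy_label <- function(strategy) {
  if (!length(strategy$nodes)) strategy$type
  else paste0(strategy$type, ":", paste(strategy$nodes, collapse = ","))
}

#' Replicate-level bias of an estimation strategy
#'
#' Repeatedly simulates cohorts from the model, applies the estimation
#' strategy to each selected sample, and compares the mean estimate with the
#' ground-truth total and controlled direct effects. The verdict follows a
#' pre-registered decision rule: the strategy `recovers_total`
#' (`recovers_cde`) when the mean lies within `tolerance` combined Monte
#' Carlo standard errors of that truth while the other truth is excluded at
#' the same criterion; `biased` when both are excluded; when the two truths
#' coincide (no mediation) ties resolve to `recovers_total`. The combined
#' standard error adds the truth's own Monte Carlo error when the truth had
#' to be simulated (models with an arrow out of the selection node, where
#' [analytic_effects()] refuses).
#'
#' @param model A [make_model()] structural model.
#' @param strategy A [parse_strategy()] label or list.
#' @param replicates Number of simulation replicates (>= 2).
#' @param n Rows per replicate (full population).
#' @param master_seed Integer; replicate seeds are derived via
#'   [derive_seeds()].
#' @param m_reference Mediator reference value for the CDE truth and for
#'   interaction fits.
#' @param tolerance Multiplier on the combined Monte Carlo standard error.
#' @param misspecify_interaction Omit the exposure-mediator product term from
#'   the adjusted fit even when the generating model has one (demonstrates
#'   interaction-misspecification bias).
#' @param n_truth Rows used for Monte Carlo truths when analytic truths are
#'   unavailable.
#' @return An object of class `bias_report`: `model_label`, `strategy_label`,
#'   `mean_estimate`, `mc_se_of_mean`, `truth_total`, `truth_cde`, `verdict`,
#'   `replicates`, `n_per_replicate`, plus the per-replicate `estimates`.
#' @export
replicate_bias <- function(model, strategy, replicates = 20, n = 200000,
                           master_seed = 1, m_reference = 0, tolerance = 3,
                           misspecify_interaction = FALSE, n_truth = 2e6) {
  stopifnot(inherits(model, "structural_model"))
  if (replicates < 2) stop("`replicates` must be >= 2")
  strategy <- parse_strategy(strategy)
  roles <- model$roles

  truth_seed <- derive_seeds(master_seed, replicates + 1L)[replicates + 1L]
  truths <- tryCatch(analytic_effects(model, m_reference),
                     error = function(e)
                       mc_effects(model, n_truth, truth_seed, m_reference))
  truth_se <- if (is.null(truths$mc_se)) c(total = 0, cde = 0) else
    truths$mc_se[c("total", "cde")]

  has_interaction <- !is.null(model$assignments[[roles$outcome]]$interaction)
  seeds <- derive_seeds(master_seed, replicates)
  estimates <- vapply(seeds, function(s) {
    cohort <- simulate_cohort(model, n, s)
    est <- switch(strategy$type,
      none = fit_adjusted_difference(cohort),
      adjust = fit_adjusted_difference(
        cohort, strategy$nodes,
        include_interaction = has_interaction && !misspecify_interaction,
        m_reference = m_reference),
      ipw = {
        preds <- if (length(strategy$nodes)) strategy$nodes else
          model$dag$parents[[roles$selection]]
        w <- estimate_selection_weights(cohort, preds)
        fit_adjusted_difference(cohort, character(0), weights = w)
      })
    est$value
  }, numeric(1L))

  mean_est <- mean(estimates)
  mcse <- stats::sd(estimates) / sqrt(replicates)
  verdict <- .bias_verdict(mean_est, mcse, truths$total_effect, truths$cde,
                           truth_se, tolerance)
  structure(
    list(model_label = model$template %||% "custom",
         strategy_label = strategy_label(strategy),
         mean_estimate = mean_est, mc_se_of_mean = mcse,
         truth_total = truths$total_effect, truth_cde = truths$cde,
         truth_method = truths$method,
         verdict = verdict, replicates = replicates, n_per_replicate = n,
         estimates = estimates),
    class = "bias_report")
}

.bias_verdict <- function(mean_est, mcse, truth_total, truth_cde, truth_se,
                          tolerance) {
  tol_total <- tolerance * sqrt(mcse^2 + truth_se[["total"]]^2)
  tol_cde <- tolerance * sqrt(mcse^2 + truth_se[["cde"]]^2)
  near_total <- abs(mean_est - truth_total) <= tol_total
  near_cde <- abs(mean_est - truth_cde) <= tol_cde
  coincide <- abs(truth_total - truth_cde) <=
    tolerance * sqrt(truth_se[["total"]]^2 + truth_se[["cde"]]^2) + 1e-12
  if (coincide) {
    if (near_total) "recovers_total" else "biased"
  } else if (near_total && !near_cde) {
    "recovers_total"
  } else if (near_cde && !near_total) {
    "recovers_cde"
  } else if (!near_total && !near_cde) {
    "biased"
  } else {
    "inconclusive"  # both truths covered; needs a larger budget
  }
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias report: model %s, strategy %s\n",
              x$model_label, x$strategy_label))
  cat(sprintf("  mean estimate %.5f (mc se %.5f; %d replicates of n = %d)\n",
              x$mean_estimate, x$mc_se_of_mean, x$replicates,
              x$n_per_replicate))
  cat(sprintf("  truths (%s): total %.5f, cde %.5f\n", x$truth_method,
              x$truth_total, x$truth_cde))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
as.data.frame.bias_report <- function(x, ...) {
  data.frame(model_label = x$model_label, strategy_label = x$strategy_label,
             mean_estimate = x$mean_estimate,
             mc_se_of_mean = x$mc_se_of_mean,
             truth_total = x$truth_total, truth_cde = x$truth_cde,
             verdict = x$verdict, replicates = x$replicates,
             n_per_replicate = x$n_per_replicate,
             stringsAsFactors = FALSE)
}
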