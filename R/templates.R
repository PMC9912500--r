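# Model templates for the canonical causal structures of selection-sampled
# (immigrant) datasets. E = country of birth (binary exposure), D = health
# outcome, R0 = unmeasured pre-migration risk factor, R = the same risk
# factor measured post-migration, S = dataset membership (binary, sample
# restricted to S = 1), C = mediator-outcome confounder.
#
# Default coefficients (see the methods vignette for rationale): E->D 0.3,
# E->R0 0.5, R0->R 1.0, R->D 0.4, C->R0 0.5, C->D 0.5, S->R 0.5 in the
# post-migration variant; selection is logistic with intercept 2.0 and
# coefficients E->S -2.5, R0->S -1.5; P(E = 1) = 0.5; continuous nodes have
# standard-normal noise.

.default_coefs <- c("E->D" = 0.3, "E->R0" = 0.5, "R0->R" = 1.0, "R->D" = 0.4,
                    "E->S" = -2.5, "R0->S" = -1.5,
                    "C->R0" = 0.5, "C->D" = 0.5, "S->R" = 0.5)

.template_edges <- function(template, time_constant, postmigration_arrows) {
  switch(template,
    fig1a = c("E -> D", "E -> R0", "R0 -> D"),
    fig1b = c("E -> D", "E -> R0", "R0 -> R", "R -> D", "E -> S", "R0 -> S"),
    fig1c = c("E -> D", "E -> R0", "R0 -> R", "R -> D", "E -> S", "R0 -> S",
              "C -> R0", "C -> D"),
    fig1d = if (time_constant)
              c("E -> D", "R -> D", "E -> S", "R -> S", "C -> R", "C -> D")
            else
              c("E -> D", "R0 -> R", "R -> D", "E -> S", "R0 -> S",
                "C -> R0", "C -> D"),
    modelC = c("E -> D", "E -> R0", "R0 -> R", "R -> D", "E -> S"),
    modelD = c("E -> D", "R0 -> R", "R -> D", "E -> S"),
    fig1d_postmigration = c("E -> D", "R0 -> R", "R -> D", "E -> S",
                            "R0 -> S", "C -> R0", "C -> D", "S -> R"),
    fig2_preeclampsia = {
      base <- c("E -> D", "E -> S",
                paste0("E -> R0", 1:3),
                paste0("R0", 1:3, " -> R", 1:3),
                paste0("R", 1:3, " -> D"),
                paste0("R0", 1:3, " -> S"))
      if (postmigration_arrows) base <- c(base, "S -> R2", "R2 -> R3")
      base
    },
    stop("unknown template: ", template))
}

.template_roles <- function(template, dag, time_constant) {
  if (template == "fig1a") {
    return(node_roles(dag, "E", "D", risk_factors_measured = "R0",
                      measured = "R0"))
  }
  if (template == "fig2_preeclampsia") {
    return(node_roles(dag, "E", "D", selection = "S",
                      risk_factors_pre = paste0("R0", 1:3),
                      risk_factors_measured = paste0("R", 1:3),
                      measured = paste0("R", 1:3)))
  }
  has_C <- "C" %in% dag$nodes
  pre <- intersect("R0", dag$nodes)
  node_roles(dag, "E", "D", selection = "S",
             risk_factors_pre = pre,
             risk_factors_measured = "R",
             confounders = if (has_C) "C" else character(0),
             measured = c("R", if (has_C) "C"))
}

# Default linear coefficients for a template DAG, keyed "from->to".
.template_coefs <- function(dag, template) {
  keys <- paste0(dag$edges[, 1L], "->", dag$edges[, 2L])
  vals <- .default_coefs[keys]
  names(vals) <- keys
  if (template == "fig2_preeclampsia") {
    vals[grep("^E->R0", keys)] <- 0.5
    vals[grep("^R0[0-9]->R[0-9]$", keys)] <- 1.0
    vals[grep("^R[0-9]->D$", keys)] <- 0.3
    vals[grep("^R0[0-9]->S$", keys)] <- -0.5
    vals["E->S"] <- -2.5
    vals["S->R2"] <- 0.5
    vals["R2->R3"] <- 0.3
  }
  if (template == "fig1a") vals["R0->D"] <- 0.4
  if (template == "fig1d") {
    # merged time-constant variant: R plays the pre-migration role
    vals[keys == "R->S"] <- -1.5
    vals[keys == "C->R"] <- 0.5
  }
  if (anyNA(vals)) stop("internal: no default coefficient for ",
                        paste(keys[is.na(vals)], collapse = ", "))
  vals
}

#' Construct a parameterized structural causal model
#'
#' Builds a fully parameterized linear-Gaussian structural model with a
#' Bernoulli exposure and (when present) a logistic selection node, either
#' from a named template or from a custom DAG with roles.
#'
#' Templates: `fig1a` (pre-migration national data, risk factor a mediator),
#' `fig1b` (risk factor both mediator and selection factor), `fig1c` (fig1b
#' plus a measured mediator-outcome confounder C), `fig1d` (selection factor
#' only: no exposure-to-risk-factor arrow, with C), `modelC` (mediator only:
#' fig1b without the R0-to-S arrow), `modelD` (neither mediator nor selection
#' factor), `fig1d_postmigration` (fig1d plus an S-to-R arrow: membership
#' itself changes the measured risk factor), and `fig2_preeclampsia` (the
#' refugee/preeclampsia illustration with three risk-factor pairs).
#'
#' @param template Template name, or `NULL` when supplying `dag` + `roles`.
#' @param dag,roles Custom model: a [causal_dag()] and matching
#'   [node_roles()]. Edge coefficients default to 0.3 (override via `coef`),
#'   noise standard deviations to 1, intercepts to 0 (selection intercept 2).
#' @param coef Named list/vector of overrides. Edge coefficients are keyed
#'   `"A->B"` (an unknown edge is rejected); noise standard deviations
#'   `"sd:NODE"`; intercepts `"intercept:NODE"`; the exposure prevalence
#'   `"p:E"`.
#' @param interaction Optional numeric exposure-mediator interaction
#'   coefficient added to the outcome assignment (between the exposure and
#'   the first measured risk factor that is a parent of the outcome).
#' @param time_constant For `fig1d`: treat the risk factor as time constant
#'   (e.g. sex), i.e. the pre-migration and measured risk factor are the same
#'   node R, which is then measured (the "R0 = R" case).
#' @param postmigration_arrows For `fig2_preeclampsia`: include the S-to-SES
#'   and SES-to-maternal-age arrows.
#' @return An object of class `structural_model`.
#' @examples
#' m <- make_model("fig1b")
#' m
#' make_model("fig1b", coef = list("E->D" = 0))
#' @export
make_model <- function(template = NULL, dag = NULL, roles = NULL,
                       coef = list(), interaction = NULL,
                       time_constant = FALSE, postmigration_arrows = FALSE) {
  if (!is.null(template)) {
    template <- match.arg(template,
      c("fig1a", "fig1b", "fig1c", "fig1d", "modelC", "modelD",
        "fig1d_postmigration", "fig2_preeclampsia"))
    dag <- dag_from_strings(
      .template_edges(template, time_constant, postmigration_arrows))
    roles <- .template_roles(template, dag, time_constant)
    coefs <- .template_coefs(dag, template)
  } else {
    if (is.null(dag) || is.null(roles))
      stop("supply either `template` or both `dag` and `roles`")
    stopifnot(inherits(dag, "causal_dag"), inherits(roles, "node_roles"))
    keys <- paste0(dag$edges[, 1L], "->", dag$edges[, 2L])
    coefs <- stats::setNames(rep(0.3, length(keys)), keys)
  }

  sds <- stats::setNames(rep(1, length(dag$nodes)), dag$nodes)
  intercepts <- stats::setNames(rep(0, length(dag$nodes)), dag$nodes)
  p_exposure <- 0.5
  if (!is.null(roles$selection)) intercepts[roles$selection] <- 2.0

  coef <- unlist(coef)
  for (key in names(coef)) {
    val <- as.numeric(coef[[key]])
    if (grepl("^sd:", key)) {
      node <- sub("^sd:", "", key); .check_nodes(dag, node)
      if (val < 0) stop("noise standard deviation must be >= 0")
      sds[node] <- val
    } else if (grepl("^intercept:", key)) {
      node <- sub("^intercept:", "", key); .check_nodes(dag, node)
      intercepts[node] <- val
    } else if (grepl("^p:", key)) {
      if (val <= 0 || val >= 1) stop("exposure prevalence must be in (0,1)")
      p_exposure <- val
    } else {
      k <- gsub("[[:space:]]", "", key)
      if (!k %in% names(coefs))
        stop("coefficient references a non-edge: ", key)
      coefs[k] <- val
    }
  }

  interaction_spec <- NULL
  if (!is.null(interaction)) {
    stopifnot(is.numeric(interaction), length(interaction) == 1L)
    med <- intersect(roles$risk_factors_measured,
                     dag$parents[[roles$outcome]])
    if (!length(med))
      stop("interaction requires a measured risk factor that is a parent of the outcome")
    interaction_spec <- list(exposure = roles$exposure, mediator = med[1L],
                             coef = interaction)
  }

  assignments <- .build_assignments(dag, roles, coefs, sds, intercepts,
                                    p_exposure, interaction_spec)
  model <- structure(
    list(dag = dag, roles = roles, assignments = assignments,
         template = template, do = numeric(0)),
    class = "structural_model")
  validate_structural_model(model)
  model
}

.build_assignments <- function(dag, roles, coefs, sds, intercepts,
                               p_exposure, interaction_spec) {
  out <- list()
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    pc <- if (length(pa))
      stats::setNames(coefs[paste0(pa, "->", v)], pa) else numeric(0)
    out[[v]] <-
      if (v == roles$exposure) {
        list(type = "bernoulli", p = p_exposure)
      } else if (!is.null(roles$selection) && v == roles$selection) {
        list(type = "logistic", intercept = intercepts[[v]], coef = pc)
      } else {
        a <- list(type = "linear", intercept = intercepts[[v]], coef = pc,
                  sd = sds[[v]])
        if (v == roles$outcome && !is.null(interaction_spec))
          a$interaction <- interaction_spec
        a
      }
  }
  out
}

#' Validate a structural model
#'
#' Checks the internal invariants: assignment parents match the DAG edges
#' exactly, noise standard deviations are nonnegative, probabilities lie in
#' (0,1), and an interaction appears only in the outcome assignment, between
#' the exposure and a measured mediator.
#'
#' @param model A `structural_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_structural_model <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  dag <- model$dag; roles <- model$roles
  if (!setequal(names(model$assignments), dag$nodes))
    stop("assignments must cover every DAG node")
  for (v in dag$nodes) {
    a <- model$assignments[[v]]
    pa <- dag$parents[[v]]
    switch(a$type,
      bernoulli = {
        if (a$p <= 0 || a$p >= 1) stop("exposure probability must be in (0,1)")
        if (length(pa)) stop("the exposure assignment cannot have parents")
      },
      constant = NULL,
      logistic = ,
      linear = {
        if (!setequal(names(a$coef), pa))
          stop("assignment parents for ", v, " do not match DAG edges")
        if (a$type == "linear" && a$sd < 0)
          stop("noise standard deviation must be >= 0")
      },
      stop("unknown assignment type for ", v))
    if (!is.null(a$interaction)) {
      if (v != roles$outcome)
        stop("an interaction term is only allowed in the outcome assignment")
      int <- a$interaction
      if (int$exposure != roles$exposure ||
          !int$mediator %in% roles$risk_factors_measured)
        stop("interaction must be between the exposure and a measured mediator")
    }
  }
  invisible(model)
}

#' @export
print.structural_model <- function(x, ...) {
  cat("structural causal model",
      if (!is.null(x$template)) paste0("(template ", x$template, ")"), "\n")
  print(x$dag)
  if (length(x$do))
    cat("  do-interventions:",
        paste(names(x$do), "=", x$do, collapse = ", "), "\n")
  for (v in topological_order(x$dag)) {
    a <- x$assignments[[v]]
    desc <- switch(a$type,
      bernoulli = sprintf("Bernoulli(p = %g)", a$p),
      constant = sprintf("constant %g", a$value),
      logistic = sprintf("Bernoulli(logit = %g%s)", a$intercept,
                         if (length(a$coef))
                           paste0(" + ", paste(sprintf("%g*%s", a$coef,
                                                       names(a$coef)),
                                               collapse = " + ")) else ""),
      linear = sprintf("%g%s%s + N(0, %g)", a$intercept,
                       if (length(a$coef))
                         paste0(" + ", paste(sprintf("%g*%s", a$coef,
                                                     names(a$coef)),
                                             collapse = " + ")) else "",
                       if (!is.null(a$interaction))
                         sprintf(" + %g*%s*%s", a$interaction$coef,
                                 a$interaction$exposure,
                                 a$interaction$mediator) else "",
                       a$sd))
    cat(sprintf("  %s := %s\n", v, desc))
  }
  invisible(x)
}
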