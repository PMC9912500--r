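#' Assign causal roles to DAG nodes
#'
#' Declares which node is the exposure (country of birth, E), the outcome
#' (health outcome, D), the optional selection indicator (dataset membership,
#' S -- always conditioned because the analyzed sample is restricted to
#' S = 1), which nodes are unmeasured pre-migration risk factors (R0-type),
#' measured post-migration risk factors (R-type), mediator-outcome
#' confounders (C-type), and which nodes are measured and therefore eligible
#' for adjustment sets.
#'
#' @param dag A [causal_dag()].
#' @param exposure,outcome Single node labels; must differ.
#' @param selection Optional single node label.
#' @param risk_factors_pre Character vector of unmeasured pre-migration risk
#'   factor nodes. Never allowed in adjustment sets.
#' @param risk_factors_measured Character vector of measured risk factor
#'   nodes; must be a subset of `measured`.
#' @param confounders Character vector of mediator-outcome confounder nodes
#'   (measured or unmeasured).
#' @param measured Character vector of adjustable nodes. Defaults to
#'   `risk_factors_measured` plus any confounders not declared unmeasured.
#' @return An object of class `node_roles`.
#' @export
node_roles <- function(dag, exposure, outcome, selection = NULL,
                       risk_factors_pre = character(0),
                       risk_factors_measured = character(0),
                       confounders = character(0),
                       measured = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  stopifnot(is.character(exposure), length(exposure) == 1L,
            is.character(outcome), length(outcome) == 1L)
  if (exposure == outcome) stop("exposure and outcome must differ")
  if (is.null(measured)) measured <- union(risk_factors_measured, confounders)
  all_roles <- c(exposure, outcome, selection, risk_factors_pre,
                 risk_factors_measured, confounders, measured)
  .check_nodes(dag, all_roles, "role node")
  if (!is.null(selection)) {
    stopifnot(length(selection) == 1L)
    if (selection %in% c(exposure, outcome))
      stop("the selection node cannot be the exposure or outcome")
  }
  if (length(setdiff(risk_factors_measured, measured)))
    stop("risk_factors_measured must be a subset of measured")
  if (length(intersect(risk_factors_pre, measured)))
    stop("pre-migration (unmeasured) risk factors cannot be measured: ",
         paste(intersect(risk_factors_pre, measured), collapse = ", "))
  if (!is.null(selection) && selection %in% measured)
    stop("the selection node is conditioned by sample restriction, not adjustment")
  structure(
    list(exposure = exposure, outcome = outcome, selection = selection,
         risk_factors_pre = sort(unique(risk_factors_pre)),
         risk_factors_measured = sort(unique(risk_factors_measured)),
         confounders = sort(unique(confounders)),
         measured = sort(unique(measured))),
    class = "node_roles")
}

#' @export
print.node_roles <- function(x, ...) {
  cat("node roles: exposure", x$exposure, "| outcome", x$outcome)
  if (!is.null(x$selection)) cat(" | selection", x$selection, "(restricted to 1)")
  cat("\n")
  show <- function(lab, v) if (length(v)) cat(" ", lab, paste(v, collapse = ", "), "\n")
  show("unmeasured pre-migration risk factors:", x$risk_factors_pre)
  show("measured risk factors:", x$risk_factors_measured)
  show("confounders:", x$confounders)
  show("measured (adjustable):", x$measured)
  invisible(x)
}
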