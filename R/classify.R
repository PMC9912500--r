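#' Classify the estimand obtained by regression adjustment
#'
#' Given a causal DAG with node roles and a user-supplied adjustment set,
#' decides which estimand the adjusted exposure coefficient corresponds to:
#'
#' * `BIASED` -- at least one non-causal exposure--outcome path is open given
#'   the conditioning set (adjustment set plus the selection node, since the
#'   analyzed sample is restricted to S = 1);
#' * `CONTROLLED_DIRECT` -- no non-causal path is open, but at least one
#'   directed exposure-to-outcome path is blocked by the conditioning set
#'   (some mediation is removed);
#' * `TOTAL` -- no non-causal path open and no causal path blocked.
#'
#' A directed path running through the selection node itself counts as a
#' blocked causal path (restriction to S = 1 holds it fixed), so such models
#' classify as `CONTROLLED_DIRECT` rather than `TOTAL`.
#'
#' "Causal path" means a fully directed path from exposure to outcome in the
#' full DAG, before conditioning; the near-blocking attenuation argument
#' (adjusting for a noisy proxy largely adjusts for its parent) is
#' deliberately *not* modeled graphically -- graph verdicts are strict, and
#' the quantitative attenuation is measured by [attenuation_study()].
#'
#' @param dag A [causal_dag()].
#' @param roles A [node_roles()] for `dag`.
#' @param adjust_set Character vector of measured nodes to adjust for (may be
#'   empty). The exposure, outcome, unmeasured nodes, and the selection node
#'   are rejected.
#' @param condition_selection Condition on the selection node (the default;
#'   the dataset is restricted to S = 1)? Set `FALSE` to classify the
#'   estimand of an estimator that undoes selection, such as inverse
#'   probability weighting.
#' @return An object of class `effect_classification` with `effect_type`
#'   (one of `"TOTAL"`, `"CONTROLLED_DIRECT"`, `"BIASED"`),
#'   `open_noncausal_paths`, `blocked_causal_paths` (lists of `dag_path`),
#'   and `conditioning_set`.
#' @examples
#' dag <- causal_dag(rbind(c("E", "D"), c("E", "R0"), c("R0", "R"),
#'                         c("R", "D"), c("E", "S"), c("R0", "S")))
#' roles <- node_roles(dag, "E", "D", selection = "S",
#'                     risk_factors_pre = "R0", risk_factors_measured = "R")
#' classify_adjusted_effect(dag, roles, "R")           # CONTROLLED_DIRECT
#' classify_adjusted_effect(dag, roles, character(0))  # BIASED
#' @export
classify_adjusted_effect <- function(dag, roles, adjust_set = character(0),
                                     condition_selection = TRUE) {
  stopifnot(inherits(dag, "causal_dag"), inherits(roles, "node_roles"))
  adjust_set <- unique(as.character(adjust_set))
  if (length(intersect(adjust_set, c(roles$exposure, roles$outcome))))
    stop("the adjustment set may not contain the exposure or outcome")
  unmeasured <- setdiff(adjust_set, roles$measured)
  if (length(unmeasured))
    stop("adjustment set contains unmeasured node(s): ",
         paste(unmeasured, collapse = ", "))

  conditioning <- adjust_set
  if (condition_selection && !is.null(roles$selection))
    conditioning <- union(conditioning, roles$selection)
  conditioning <- sort(conditioning)

  paths <- enumerate_paths(dag, roles$exposure, roles$outcome)
  causal <- vapply(paths, function(p) p$is_causal, logical(1L))
  open <- vapply(paths, path_open, logical(1L),
                 conditioned = conditioning, dag = dag)

  open_noncausal <- paths[!causal & open]
  blocked_causal <- paths[causal & !open]

  effect_type <-
    if (length(open_noncausal)) "BIASED"
    else if (length(blocked_causal)) "CONTROLLED_DIRECT"
    else "TOTAL"

  structure(
    list(effect_type = effect_type,
         open_noncausal_paths = open_noncausal,
         blocked_causal_paths = blocked_causal,
         conditioning_set = conditioning,
         exposure = roles$exposure, outcome = roles$outcome),
    class = "effect_classification")
}

#' @export
print.effect_classification <- function(x, ...) {
  cat(sprintf("adjusted effect of %s on %s, conditioning on {%s}: %s\n",
              x$exposure, x$outcome,
              paste(x$conditioning_set, collapse = ", "), x$effect_type))
  if (length(x$open_noncausal_paths)) {
    cat("  open non-causal paths:\n")
    for (p in x$open_noncausal_paths) cat("    ", format(p), "\n")
  }
  if (length(x$blocked_causal_paths)) {
    cat("  blocked causal paths:\n")
    for (p in x$blocked_causal_paths) cat("    ", format(p), "\n")
  }
  invisible(x)
}
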