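#' Simulate a cohort from a structural model
#'
#' Generates the full origin population node by node in topological order and
#' attaches the selected view (rows with S = 1, the analyzed
#' selection-restricted dataset). The same `(model, n, seed)` always yields
#' bit-identical tables. Noise draws are made even when a noise standard
#' deviation is zero, so cohorts simulated under different noise settings
#' from the same seed share all remaining randomness (common random numbers).
#'
#' @param model A [make_model()] structural model.
#' @param n Number of rows in the full population (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `simulated_cohort`: `full_population` (data
#'   frame, one column per node), `selected` (rows with S = 1; the full table
#'   when the model has no selection node), `seed`, `n`, and the model's
#'   `roles`.
#' @export
simulate_cohort <- function(model, n, seed) {
  stopifnot(inherits(model, "structural_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  cols <- vector("list", length(model$dag$nodes))
  names(cols) <- model$dag$nodes
  for (v in topological_order(model$dag)) {
    a <- model$assignments[[v]]
    cols[[v]] <- switch(a$type,
      bernoulli = stats::rbinom(n, 1L, a$p),
      constant  = rep(a$value, n),
      logistic  = {
        lp <- rep(a$intercept, n)
        for (p in names(a$coef)) lp <- lp + a$coef[[p]] * cols[[p]]
        stats::rbinom(n, 1L, stats::plogis(lp))
      },
      linear = {
        mu <- rep(a$intercept, n)
        for (p in names(a$coef)) mu <- mu + a$coef[[p]] * cols[[p]]
        if (!is.null(a$interaction))
          mu <- mu + a$interaction$coef *
            cols[[a$interaction$exposure]] * cols[[a$interaction$mediator]]
        mu + a$sd * stats::rnorm(n)  # noise drawn even at sd = 0 (CRN)
      })
  }
  full <- as.data.frame(cols)
  sel_node <- model$roles$selection
  do_on_selection <- !is.null(sel_node) && sel_node %in% names(model$do)
  selected <-
    if (is.null(sel_node)) full
    else if (do_on_selection) NULL
    else full[full[[sel_node]] == 1L, , drop = FALSE]
  structure(
    list(full_population = full, selected = selected, seed = as.integer(seed),
         n = n, roles = model$roles, do = model$do),
    class = "simulated_cohort")
}

#' Selected view of a simulated cohort
#'
#' The rows with S = 1 (the selection-restricted dataset). Requesting the
#' selected view of a cohort simulated under a do-intervention on the
#' selection node is a contradiction (selection was overridden, not
#' observed) and is rejected.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame of selected rows.
#' @export
selected_view <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(cohort$selected))
    stop("selected-view statistics are undefined after a do-intervention ",
         "on the selection node")
  cohort$selected
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated cohort: n =", x$n, "(full population), seed =", x$seed, "\n")
  if (!is.null(x$selected))
    cat("  selected view (S = 1):", nrow(x$selected), "rows\n")
  cat("  columns:", paste(names(x$full_population), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a do-intervention to a structural model
#'
#' Severs all incoming edges of the assigned nodes and fixes them at the
#' given constants; the result is again a valid structural model that can be
#' simulated.
#'
#' @param model A `structural_model`.
#' @param assignments Named numeric vector/list, e.g. `c(E = 1)` or
#'   `c(E = 1, R = 0)`.
#' @return The intervened `structural_model`.
#' @examples
#' m1 <- apply_do(make_model("fig1b"), c(E = 1))
#' @export
apply_do <- function(model, assignments) {
  stopifnot(inherits(model, "structural_model"))
  assignments <- unlist(assignments)
  if (!length(assignments) || is.null(names(assignments)) ||
      any(!nzchar(names(assignments))))
    stop("`assignments` must be a named numeric vector")
  .check_nodes(model$dag, names(assignments))
  keep <- !(model$dag$edges[, 2L] %in% names(assignments))
  new_dag <- causal_dag(model$dag$edges[keep, , drop = FALSE],
                        nodes = model$dag$nodes)
  for (v in names(assignments)) {
    model$assignments[[v]] <- list(type = "constant",
                                   value = as.numeric(assignments[[v]]))
  }
  model$dag <- new_dag
  model$do <- c(model$do, assignments[setdiff(names(assignments),
                                              names(model$do))])
  model$do[names(assignments)] <- as.numeric(assignments)
  validate_structural_model(model)
  model
}

#' Write / read a cohort as CSV
#'
#' The CSV holds the full population (one column per node, including the
#' selection indicator); the selected view is recovered on read. Values are
#' written with full double precision so a round trip is lossless.
#'
#' @param cohort A `simulated_cohort`.
#' @param path File path.
#' @param roles A [node_roles()] describing the columns (needed on read to
#'   rebuild the selected view).
#' @return `write_cohort_csv`: the path, invisibly. `read_cohort_csv`: a
#'   `simulated_cohort` (with `seed`/`n` taken from the file contents where
#'   recoverable; `seed` is `NA` since the CSV stores data, not RNG state).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  df <- cohort$full_population
  # full precision: format doubles via 17 significant digits
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, roles) {
  stopifnot(inherits(roles, "node_roles"))
  full <- utils::read.csv(path, check.names = FALSE)
  sel_node <- roles$selection
  selected <- if (is.null(sel_node)) full
              else full[full[[sel_node]] == 1L, , drop = FALSE]
  structure(
    list(full_population = full, selected = selected, seed = NA_integer_,
         n = nrow(full), roles = roles, do = numeric(0)),
    class = "simulated_cohort")
}
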