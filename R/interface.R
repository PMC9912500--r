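# Structured configuration, output writing, and the command dispatch behind
# the `effectpath` command-line script (inst/cli/effectpath.R).

.config_defaults <- function() {
  list(command = "grid", model = "fig1b", coef = list(), n = 200000L,
       replicates = 20L, seed = 1L, m_reference = 0,
       noise_grid = c(0, 0.1, 0.25, 0.5, 1.0), interaction = 0.2,
       adjust = character(0), predictors = NULL, time_constant = FALSE,
       postmigration_arrows = FALSE, out = NULL, verbose = FALSE)
}

.config_commands <- c("simulate", "classify", "grid", "attenuation",
                      "interaction", "example-preeclampsia")

#' Parse a run configuration
#'
#' Reads a YAML configuration file and/or a list of flag overrides, validates
#' every key, fills defaults, and returns a run configuration. Unknown keys
#' and type mismatches are rejected by name, so a misspelled key cannot
#' silently fall back to a default.
#'
#' Recognized keys: `command` (one of simulate, classify, grid, attenuation,
#' interaction, example-preeclampsia), `model` (template name), `coef`
#' (named coefficient overrides, e.g. `"E->D": 0`), `n`, `replicates`,
#' `seed`, `m_reference`, `noise_grid`, `interaction`, `adjust` (adjustment
#' set for `classify`), `predictors` (IPW selection-model covariates),
#' `time_constant`, `postmigration_arrows`, `out` (output directory),
#' `verbose`.
#'
#' @param path Optional path to a YAML file.
#' @param overrides Named list applied on top of the file (command-line
#'   flags).
#' @return A list of class `run_config`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  config <- .config_defaults()
  supplied <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    supplied <- yaml::read_yaml(path)
    if (is.null(supplied)) supplied <- list()
  }
  supplied <- utils::modifyList(supplied, overrides)
  unknown <- setdiff(names(supplied), names(config))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  for (key in names(supplied)) config[[key]] <- supplied[[key]]

  if (!is.character(config$command) ||
      !config$command %in% .config_commands)
    stop("unknown command: ", config$command, " (expected one of ",
         paste(.config_commands, collapse = ", "), ")")
  for (key in c("n", "replicates", "seed")) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || v != as.integer(v))
      stop("configuration key `", key, "` must be a single integer")
    config[[key]] <- as.integer(v)
  }
  for (key in c("m_reference", "interaction")) {
    if (!is.numeric(config[[key]]) || length(config[[key]]) != 1L)
      stop("configuration key `", key, "` must be a single number")
  }
  if (!is.numeric(config$noise_grid))
    stop("configuration key `noise_grid` must be numeric")
  for (key in c("time_constant", "postmigration_arrows", "verbose")) {
    if (!is.logical(config[[key]]) || length(config[[key]]) != 1L)
      stop("configuration key `", key, "` must be TRUE or FALSE")
  }
  if (!is.list(config$coef) && !is.null(names(config$coef)))
    config$coef <- as.list(config$coef)
  config$adjust <- as.character(config$adjust)
  structure(config, class = "run_config")
}

# Deterministic CSV writer: fixed significant digits, no quoting surprises.
.write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write experiment outputs and a run log
#'
#' Writes the result tables as CSV into the configured output directory plus
#' a `run_log.txt` capturing the full effective configuration, master seed,
#' and package/R versions -- everything needed to reproduce the run exactly.
#' Deterministic commands produce byte-identical files on re-runs.
#'
#' @param results Named list of data frames (and/or character vectors, which
#'   are written as plain text).
#' @param config A [parse_config()] result with a non-`NULL` `out`.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out)) stop("no output directory configured (`out`)")
  ok <- dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out)) stop("cannot create output directory: ",
                                    config$out)
  files <- character(0)
  for (name in names(results)) {
    obj <- results[[name]]
    if (is.data.frame(obj)) {
      f <- file.path(config$out, paste0(name, ".csv"))
      .write_table(obj, f)
    } else {
      f <- file.path(config$out, paste0(name, ".txt"))
      writeLines(as.character(obj), f)
    }
    files <- c(files, f)
  }
  log_file <- file.path(config$out, "run_log.txt")
  cfg <- unclass(config)
  cfg$out <- NULL
  writeLines(c(
    paste0("effectpath ", as.character(utils::packageVersion("effectpath")),
           " | R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("command: ", config$command),
    paste0("master seed: ", config$seed),
    "effective configuration:",
    strsplit(yaml::as.yaml(cfg), "\n")[[1L]]), log_file)
  invisible(c(files, log_file))
}

#' Run an effectpath command
#'
#' Dispatches a [parse_config()] configuration to the corresponding
#' experiment or utility and (when `out` is set) writes its outputs.
#'
#' @param config A `run_config`.
#' @return The command's result object, invisibly for commands whose main
#'   product is files.
#' @export
effectpath_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  econfig <- experiment_config(replicates = config$replicates, n = config$n,
                               master_seed = config$seed)
  model <- function() make_model(config$model, coef = config$coef,
                                 time_constant = config$time_constant,
                                 postmigration_arrows =
                                   config$postmigration_arrows)
  result <- switch(config$command,
    simulate = {
      cohort <- simulate_cohort(model(), config$n, config$seed)
      if (!is.null(config$out)) {
        dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
        write_cohort_csv(cohort, file.path(config$out, "cohort.csv"))
        write_outputs(list(), config)
      }
      cohort
    },
    classify = {
      m <- model()
      cls <- classify_adjusted_effect(m$dag, m$roles, config$adjust)
      if (config$verbose || is.null(config$out)) print(cls)
      if (!is.null(config$out)) {
        txt <- c(utils::capture.output(print(cls)), "",
                 "dot format:", dag_to_dot(m$dag, m$roles))
        write_outputs(list(classification = txt), config)
      }
      cls
    },
    grid = {
      grid <- run_effect_grid(econfig, out_dir = config$out)
      if (!is.null(config$out)) write_outputs(list(), config)
      .print_grid_summary(grid, config$verbose)
      grid
    },
    attenuation = {
      att <- attenuation_study(config$noise_grid, econfig)
      if (!is.null(config$out)) write_outputs(list(attenuation = att), config)
      att
    },
    interaction = {
      res <- interaction_study(econfig, interaction = config$interaction,
                               m_reference = config$m_reference)
      if (!is.null(config$out)) write_outputs(list(interaction = res), config)
      res
    },
    `example-preeclampsia` = {
      res <- preeclampsia_example(config$postmigration_arrows)
      for (nm in names(res)) {
        cat("adjustment model", if (nm == "without_SES") "1 (SES omitted):"
            else "2 (SES included):", "\n")
        print(res[[nm]])
      }
      if (!is.null(config$out)) {
        txt <- unlist(lapply(names(res), function(nm) {
          c(paste0("adjustment model ", nm, ":"),
            utils::capture.output(print(res[[nm]])), "")
        }))
        write_outputs(list(preeclampsia = txt), config)
      }
      res
    })
  invisible(result)
}

.print_grid_summary <- function(grid, verbose) {
  applicable <- grid[!is.na(grid$concordant), , drop = FALSE]
  cat(sprintf("effect grid: %d cells (%d applicable), %d concordant\n",
              nrow(grid), nrow(applicable), sum(applicable$concordant)))
  if (verbose) {
    print(grid, digits = 4)
  } else {
    print(grid[, c("model_label", "strategy_label", "classifier_verdict",
                   "simulation_verdict", "concordant")])
  }
  invisible(grid)
}
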