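#' Enumerate all simple paths between two nodes
#'
#' Lists every simple path between `x` and `y` in the DAG, ignoring edge
#' direction, together with per-step direction flags and a causality flag
#' (`TRUE` iff every edge points from `x` toward `y` along the sequence).
#' Paths are returned in deterministic lexicographic order of their node
#' sequences so diagnostics are reproducible.
#'
#' @param dag A [causal_dag()].
#' @param x,y Distinct node labels.
#' @return A list of objects of class `dag_path`, each with `nodes`
#'   (character vector), `directions` (`"forward"`/`"backward"` per step,
#'   forward meaning the edge points from `nodes[k]` to `nodes[k+1]`), and
#'   `is_causal`.
#' @examples
#' dag <- causal_dag(rbind(c("E", "D"), c("E", "R0"), c("R0", "R"),
#'                         c("R", "D"), c("E", "S"), c("R0", "S")))
#' length(enumerate_paths(dag, "E", "D"))  # 3
#' @export
enumerate_paths <- function(dag, x, y) {
  stopifnot(inherits(dag, "causal_dag"))
  .check_nodes(dag, c(x, y))
  if (x == y) stop("`x` and `y` must differ")
  if (!nrow(dag$edges)) return(list())
  g <- igraph::graph_from_edgelist(dag$edges, directed = TRUE)
  g <- igraph::add_vertices(g, length(setdiff(dag$nodes, igraph::V(g)$name)),
                            name = setdiff(dag$nodes, igraph::V(g)$name))
  ug <- igraph::as_undirected(g, mode = "collapse")
  raw <- igraph::all_simple_paths(ug, from = x, to = y)
  paths <- lapply(raw, function(vp) .make_path(dag, igraph::V(ug)$name[vp]))
  keys <- vapply(paths, function(p) paste(p$nodes, collapse = "\r"), character(1L))
  paths[order(keys)]
}

.make_path <- function(dag, nodes) {
  k <- length(nodes) - 1L
  dirs <- character(k)
  edge_key <- paste(dag$edges[, 1L], dag$edges[, 2L], sep = "\r")
  for (i in seq_len(k)) {
    fwd <- paste(nodes[i], nodes[i + 1L], sep = "\r") %in% edge_key
    dirs[i] <- if (fwd) "forward" else "backward"
  }
  structure(list(nodes = nodes, directions = dirs,
                 is_causal = all(dirs == "forward")),
            class = "dag_path")
}

#' @export
print.dag_path <- function(x, ...) {
  arrows <- ifelse(x$directions == "forward", "->", "<-")
  cat(paste0(x$nodes[1L],
             paste0(" ", arrows, " ", x$nodes[-1L], collapse = "")),
      if (x$is_causal) " [causal]" else " [non-causal]", "\n", sep = "")
  invisible(x)
}

#' @export
format.dag_path <- function(x, ...) {
  arrows <- ifelse(x$directions == "forward", "->", "<-")
  paste0(x$nodes[1L], paste0(" ", arrows, " ", x$nodes[-1L], collapse = ""))
}

#' Is a path open given a conditioning set?
#'
#' Applies the d-separation path rules: an interior chain or fork node blocks
#' the path when conditioned; an interior collider blocks the path unless it,
#' or one of its descendants, is conditioned.
#'
#' @param path A `dag_path` from [enumerate_paths()].
#' @param conditioned Character vector of conditioned nodes (possibly empty).
#' @param dag The `causal_dag` the path lives in (needed for collider
#'   descendants).
#' @return `TRUE` if the path is open (transmits association), else `FALSE`.
#' @export
path_open <- function(path, conditioned, dag) {
  stopifnot(inherits(path, "dag_path"), inherits(dag, "causal_dag"))
  .check_nodes(dag, conditioned, "conditioning node")
  n <- length(path$nodes)
  if (n <= 2L) return(TRUE)  # a single edge has no interior node to block
  for (i in 2L:(n - 1L)) {
    into  <- path$directions[i - 1L] == "forward"
    outof <- path$directions[i] == "forward"
    node <- path$nodes[i]
    if (into && !outof) {  # collider: -> node <-
      open_step <- length(intersect(dag_descendants(dag, node), conditioned)) > 0L
    } else {               # chain or fork
      open_step <- !(node %in% conditioned)
    }
    if (!open_step) return(FALSE)
  }
  TRUE
}
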