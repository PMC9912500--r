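#' Build a causal directed acyclic graph
#'
#' Constructs a validated causal DAG from an edge list. Nodes are inferred
#' from the edge endpoints; isolated nodes (nodes with no edges) can be added
#' through `nodes`.
#'
#' @param edges Edge list: a two-column character matrix, a data frame, or a
#'   list of length-2 character vectors, each row/element an ordered pair
#'   (cause, effect).
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node labels.
#' @return An object of class `causal_dag` with components `nodes` (sorted
#'   character vector), `edges` (two-column character matrix with columns
#'   `from`, `to`, sorted for determinism), and `parents`/`children` adjacency
#'   lists.
#' @details Validation enforces: nonempty text labels, no self-loops, no
#'   duplicate edges, and acyclicity. A cycle is reported with a witness (the
#'   node labels involved).
#' @examples
#' dag <- causal_dag(rbind(c("E", "D"), c("E", "R0"), c("R0", "R"),
#'                         c("R", "D"), c("E", "S"), c("R0", "S")))
#' dag
#' @seealso [dag_from_strings()], [enumerate_paths()], [d_separated()]
#' @export
causal_dag <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix (or list of pairs) of node labels")
  }
  storage.mode(edges) <- "character"
  labels <- c(as.vector(edges), nodes)
  if (length(labels) && (anyNA(labels) || any(!nzchar(labels)))) {
    stop("node labels must be nonempty text")
  }
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed: ",
           paste(unique(edges[edges[, 1L] == edges[, 2L], 1L]), collapse = ", "))
    }
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      dup <- edges[duplicated(key), , drop = FALSE]
      stop("duplicate edge: ", dup[1L, 1L], " -> ", dup[1L, 2L])
    }
  }
  node_set <- sort(unique(labels))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("from", "to")
  # integer adjacency (node order = `nodes`) kept alongside the label lists:
  # the d-separation and reachability queries run on indexes
  ei <- cbind(match(edges[, 1L], node_set), match(edges[, 2L], node_set))
  pidx <- lapply(seq_along(node_set), function(i) ei[ei[, 2L] == i, 1L])
  cidx <- lapply(seq_along(node_set), function(i) ei[ei[, 1L] == i, 2L])
  dag <- structure(
    list(nodes = node_set, edges = edges,
         parents  = .adjacency(node_set, edges, by = "to"),
         children = .adjacency(node_set, edges, by = "from"),
         pidx = pidx, cidx = cidx),
    class = "causal_dag")
  cyc <- .find_cycle(dag)
  if (!is.null(cyc)) {
    stop("graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  dag
}

.adjacency <- function(nodes, edges, by) {
  other <- if (by == "to") "from" else "to"
  out <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(edges[edges[, by] == v, other])
  })
  out
}

# Kahn's algorithm; returns NULL when acyclic, else the nodes of a residual
# cycle as a witness for the error message.
.find_cycle <- function(dag) {
  indeg <- vapply(dag$parents, length, integer(1L))
  remaining <- dag$nodes
  repeat {
    zero <- remaining[indeg[remaining] == 0L]
    if (!length(zero)) break
    remaining <- setdiff(remaining, zero)
    for (v in zero) {
      kids <- intersect(dag$children[[v]], remaining)
      indeg[kids] <- indeg[kids] - 1L
    }
  }
  if (length(remaining)) remaining else NULL
}

#' Topological order of a causal DAG
#'
#' Deterministic (Kahn's algorithm with lexicographic tie-break), so
#' simulation output is reproducible across platforms.
#'
#' @param dag A `causal_dag`.
#' @return Character vector of node labels in topological order.
#' @export
topological_order <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  indeg <- vapply(dag$parents, length, integer(1L))
  remaining <- dag$nodes
  out <- character(0)
  while (length(remaining)) {
    zero <- sort(remaining[indeg[remaining] == 0L])
    v <- zero[1L]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    kids <- intersect(dag$children[[v]], remaining)
    indeg[kids] <- indeg[kids] - 1L
  }
  out
}

.check_nodes <- function(dag, x, what = "node") {
  missing <- setdiff(x, dag$nodes)
  if (length(missing)) {
    stop("unknown ", what, ": ", paste(missing, collapse = ", "))
  }
  invisible(x)
}

#' Ancestors / descendants of a node set
#'
#' @param dag A `causal_dag`.
#' @param nodes Character vector of node labels.
#' @param include_self Include the query nodes themselves?
#' @return Sorted character vector.
#' @export
dag_ancestors <- function(dag, nodes, include_self = TRUE) {
  .relatives(dag, nodes, "pidx", include_self)
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, nodes, include_self = TRUE) {
  .relatives(dag, nodes, "cidx", include_self)
}

.relatives <- function(dag, nodes, which_adj, include_self) {
  .check_nodes(dag, nodes)
  idx <- .reach(dag[[which_adj]], match(nodes, dag$nodes), length(dag$nodes))
  out <- dag$nodes[idx]
  out <- if (include_self) union(out, nodes) else setdiff(out, nodes)
  sort(out)
}

# integer BFS: indexes reachable from `start` through adjacency list `adj`
# (start nodes included only if revisited)
.reach <- function(adj, start, n_nodes) {
  seen <- logical(n_nodes)
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Build a DAG from "A -> B" edge strings
#'
#' Convenience constructor used by the structured configuration format.
#'
#' @param strings Character vector of edges written as `"A -> B"`.
#' @param nodes Optional isolated nodes.
#' @return A `causal_dag`.
#' @examples
#' dag_from_strings(c("E -> D", "E -> R0", "R0 -> D"))
#' @export
dag_from_strings <- function(strings, nodes = NULL) {
  parts <- strsplit(strings, "->", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed edge string: ", strings[bad][1L])
  edges <- do.call(rbind, lapply(parts, trimws))
  causal_dag(edges, nodes = nodes)
}

#' Export a DAG as dot-format text
#'
#' @param dag A `causal_dag`.
#' @param roles Optional [node_roles()]; when given, the exposure/outcome are
#'   boxed, unmeasured nodes are gray and the selection node is drawn with a
#'   double circle (the "circled S" convention for conditioning by sample
#'   restriction).
#' @return A single character string of Graphviz dot source.
#' @export
dag_to_dot <- function(dag, roles = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  decorate <- function(v) {
    if (is.null(roles)) return(sprintf("  \"%s\";", v))
    attrs <- character(0)
    if (v %in% c(roles$exposure, roles$outcome)) attrs <- c(attrs, "shape=box")
    if (!is.null(roles$selection) && v == roles$selection)
      attrs <- c(attrs, "shape=doublecircle")
    if (v %in% c(roles$risk_factors_pre,
                 setdiff(roles$confounders, roles$measured)))
      attrs <- c(attrs, "style=filled", "fillcolor=gray80")
    if (length(attrs)) sprintf("  \"%s\" [%s];", v, paste(attrs, collapse = ", "))
    else sprintf("  \"%s\";", v)
  }
  lines <- c("digraph causal_dag {",
             vapply(dag$nodes, decorate, character(1L)),
             sprintf("  \"%s\" -> \"%s\";", dag$edges[, 1L], dag$edges[, 2L]),
             "}")
  paste(lines, collapse = "\n")
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = "; "),
        "\n")
  }
  invisible(x)
}
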