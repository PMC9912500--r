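#' d-separation between two nodes
#'
#' Tests whether `x` and `y` are d-separated given a conditioning set, i.e.
#' whether every path between them is blocked, so the DAG implies their
#' conditional independence. Implemented by the moral ancestral graph
#' construction (restrict to ancestors of `{x, y}` and the conditioning set,
#' marry co-parents, drop directions, delete the conditioned nodes, and test
#' undirected reachability), which is independent of the path-enumeration
#' route in [enumerate_paths()] + [path_open()] and is cross-checked against
#' it in the test suite.
#'
#' @param dag A [causal_dag()].
#' @param x,y Distinct node labels, neither in `conditioned`.
#' @param conditioned Character vector of conditioned nodes.
#' @return `TRUE` if d-separated (no open path), else `FALSE`.
#' @examples
#' dag <- causal_dag(rbind(c("E", "S"), c("R0", "S")))
#' d_separated(dag, "E", "R0", character(0))  # TRUE: collider unconditioned
#' d_separated(dag, "E", "R0", "S")           # FALSE: conditioning opens it
#' @export
d_separated <- function(dag, x, y, conditioned = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  .check_nodes(dag, c(x, y))
  .check_nodes(dag, conditioned, "conditioning node")
  if (x == y) stop("`x` and `y` must differ")
  if (x %in% conditioned || y %in% conditioned)
    stop("`x` and `y` may not be part of the conditioning set")

  n <- length(dag$nodes)
  xi <- match(x, dag$nodes); yi <- match(y, dag$nodes)
  zi <- match(conditioned, dag$nodes)

  # ancestral set of {x, y} union Z (as a logical mask over all nodes)
  anc <- logical(n)
  start <- c(xi, yi, zi)
  anc[start] <- TRUE
  anc[.reach(dag$pidx, start, n)] <- TRUE

  # undirected adjacency restricted to the ancestral set
  m <- matrix(FALSE, n, n)
  for (v in which(anc)) {
    pa <- dag$pidx[[v]]
    pa <- pa[anc[pa]]
    if (length(pa)) {
      m[v, pa] <- TRUE; m[pa, v] <- TRUE
      # moralization: marry all co-parents of v
      if (length(pa) > 1L) { m[pa, pa] <- TRUE; diag(m)[pa] <- FALSE }
    }
  }
  if (length(zi)) { m[zi, ] <- FALSE; m[, zi] <- FALSE }

  # undirected BFS from x
  reach <- logical(n)
  reach[xi] <- TRUE
  frontier <- xi
  while (length(frontier)) {
    nxt <- which(.rowAny(m, frontier) & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  !reach[yi]
}

.rowAny <- function(m, rows) {
  if (length(rows) == 1L) m[rows, ] else colSums(m[rows, , drop = FALSE]) > 0L
}
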