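# Shared fixtures: random DAGs and the exhaustive path-based d-separation
# oracle used to cross-check the moral-graph implementation.

# Random DAG on `n_nodes` labels: orient each possible pair under a random
# topological order, keep it with probability `p_edge`. Always acyclic.
random_dag <- function(n_nodes, p_edge = 0.4) {
  labels <- sample(LETTERS[seq_len(n_nodes)])  # permuted so label order
  edges <- NULL                                #  is not the causal order
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, labels[c(i, j)])
    }
  }
  causal_dag(edges, nodes = labels)
}

# Independent oracle: d-separated iff no enumerated path is open.
oracle_dsep <- function(dag, x, y, conditioned, paths = NULL) {
  if (is.null(paths)) paths <- enumerate_paths(dag, x, y)
  !any(vapply(paths, path_open, logical(1L),
              conditioned = conditioned, dag = dag))
}

all_subsets <- function(v) {
  if (!length(v)) return(list(character(0)))
  sub <- all_subsets(v[-1L])
  c(sub, lapply(sub, function(s) c(v[1L], s)))
}

# Agreement check over every node pair and every conditioning subset (paths
# enumerated once per pair; the per-subset open/closed rules stay with
# path_open).
dsep_agrees_everywhere <- function(dag) {
  nodes <- dag$nodes
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      x <- nodes[i]; y <- nodes[j]
      paths <- enumerate_paths(dag, x, y)
      for (z in all_subsets(setdiff(nodes, c(x, y)))) {
        if (d_separated(dag, x, y, z) !=
              oracle_dsep(dag, x, y, z, paths = paths)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

fig1b_dag <- function() {
  dag_from_strings(c("E -> D", "E -> R0", "R0 -> R", "R -> D",
                     "E -> S", "R0 -> S"))
}

fig1b_roles <- function(dag = fig1b_dag()) {
  node_roles(dag, "E", "D", selection = "S", risk_factors_pre = "R0",
             risk_factors_measured = "R")
}

path_string <- function(p) paste(p$nodes, collapse = "-")
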