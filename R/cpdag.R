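# Completed partially directed acyclic graphs.
#
# The CPDAG of a DAG keeps its skeleton, directs the compelled edges (those
# oriented the same way in every member of the Markov equivalence class) and
# leaves reversible edges undirected. It is computed by orienting the
# v-structures and closing under the standard orientation-propagation rules.

#' Convert a network to its CPDAG
#'
#' Accepts a DAG or an already partially directed graph (so the operation is
#' idempotent): the skeleton is kept, unshielded colliders are directed, and
#' the orientation rules are applied to a fixpoint.
#'
#' @param net A `bn_dag` or `pdag`.
#' @return A `pdag`: list with `$amat` (entry `[i, j] = 1` means an edge
#'   `i -> j`; both `[i, j]` and `[j, i]` set means undirected) and
#'   `$levels`.
#' @export
to_cpdag <- function(net) {
  if (inherits(net, "pdag")) {
    am <- net$amat
    levels <- net$levels
  } else {
    validate_dag(net)
    am <- dag_amat(net)
    levels <- net$levels
  }
  n <- nrow(am)
  nodes <- rownames(am)
  adj <- (am | t(am)) # skeleton adjacency
  directed_in <- function(m, i, j) m[i, j] == 1L && m[j, i] == 0L

  # start undirected everywhere, then orient unshielded colliders as in input
  out <- matrix(0L, n, n, dimnames = dimnames(am))
  out[adj] <- 1L
  for (z in seq_len(n)) {
    pa <- which(vapply(seq_len(n), function(x) directed_in(am, x, z), logical(1)))
    if (length(pa) < 2) next
    for (a in seq_along(pa)) {
      for (b in seq_along(pa)) {
        if (a >= b) next
        x <- pa[a]
        y <- pa[b]
        if (!adj[x, y]) { # unshielded: x -> z <- y is compelled
          out[z, x] <- 0L
          out[z, y] <- 0L
        }
      }
    }
  }

  repeat {
    changed <- FALSE
    und <- which(out == 1L & t(out) == 1L, arr.ind = TRUE)
    for (e in seq_len(nrow(und))) {
      a <- und[e, 1]
      b <- und[e, 2]
      if (out[a, b] != 1L || out[b, a] != 1L) next
      orient <- FALSE
      # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
      for (c0 in seq_len(n)) {
        if (directed_in(out, c0, a) && !adj[c0, b] && c0 != b) {
          orient <- TRUE
          break
        }
      }
      # R2: a -> c -> b with a - b  =>  a -> b
      if (!orient) {
        for (c0 in seq_len(n)) {
          if (directed_in(out, a, c0) && directed_in(out, c0, b)) {
            orient <- TRUE
            break
          }
        }
      }
      # R3: a - c -> b and a - d -> b with c, d non-adjacent  =>  a -> b
      if (!orient) {
        mids <- which(vapply(seq_len(n), function(c0) {
          c0 != b && out[a, c0] == 1L && out[c0, a] == 1L &&
            directed_in(out, c0, b)
        }, logical(1)))
        if (length(mids) >= 2) {
          for (u in seq_along(mids)) {
            for (v in seq_along(mids)) {
              if (u < v && !adj[mids[u], mids[v]]) orient <- TRUE
            }
          }
        }
      }
      if (orient) {
        out[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(amat = out, levels = levels, nodes = nodes), class = "pdag")
}

#' @export
print.pdag <- function(x, ...) {
  am <- x$amat
  und <- sum(am == 1L & t(am) == 1L) / 2
  dir <- sum(am == 1L & t(am) == 0L)
  cat(
    "Partially directed graph:", nrow(am), "nodes,",
    dir, "directed and", und, "undirected edges\n"
  )
  invisible(x)
}

#' Directed and undirected links of a CPDAG
#'
#' @param x A `pdag`.
#' @return List with `directed` (2-column from/to matrix) and `undirected`
#'   (canonical `"A--B"` keys).
#' @export
pdag_edges <- function(x) {
  am <- x$amat
  nodes <- rownames(am)
  und <- which(am == 1L & t(am) == 1L & upper.tri(am), arr.ind = TRUE)
  dir <- which(am == 1L & t(am) == 0L, arr.ind = TRUE)
  list(
    directed = matrix(
      c(nodes[dir[, 1]], nodes[dir[, 2]]),
      ncol = 2, dimnames = list(NULL, c("from", "to"))
    ),
    undirected = if (nrow(und)) {
      paste(nodes[und[, 1]], nodes[und[, 2]], sep = "--")
    } else {
      character(0)
    }
  )
}

# Oracle: enumerate every DAG consistent with a skeleton and check which are
# Markov-equivalent to `dag` (same skeleton and v-structures); an edge is
# compelled iff it has the same orientation in all of them. Only for tiny n.
compelled_by_enumeration <- function(dag) {
  am <- dag_amat(dag)
  n <- nrow(am)
  nodes <- rownames(am)
  adj <- which((am | t(am)) & upper.tri(am), arr.ind = TRUE)
  vstructs <- function(m) {
    out <- character(0)
    for (z in seq_len(n)) {
      pa <- which(m[, z] == 1L & m[z, ] == 0L)
      if (length(pa) < 2) next
      for (a in pa) {
        for (b in pa) {
          if (a < b && !m[a, b] && !m[b, a]) {
            out <- c(out, paste(a, z, b))
          }
        }
      }
    }
    sort(out)
  }
  ref_v <- vstructs(am)
  states <- expand.grid(rep(list(1:2), nrow(adj)))
  keep <- matrix(0L, 0, n * n)
  members <- list()
  for (g in seq_len(nrow(states))) {
    m <- matrix(0L, n, n)
    for (e in seq_len(nrow(adj))) {
      if (states[g, e] == 1) {
        m[adj[e, 1], adj[e, 2]] <- 1L
      } else {
        m[adj[e, 2], adj[e, 1]] <- 1L
      }
    }
    if (any(reachability(m) & (diag(n) > 0))) next
    if (identical(vstructs(m), ref_v)) members <- c(members, list(m))
  }
  consensus <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(adj))) {
    i <- adj[e, 1]
    j <- adj[e, 2]
    dirs <- vapply(members, function(m) m[i, j] == 1L, logical(1))
    if (all(dirs)) {
      consensus[i, j] <- 1L
    } else if (all(!dirs)) {
      consensus[j, i] <- 1L
    } else {
      consensus[i, j] <- 1L
      consensus[j, i] <- 1L
    }
  }
  structure(
    list(amat = consensus, levels = dag$levels, nodes = nodes),
    class = "pdag"
  )
}
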