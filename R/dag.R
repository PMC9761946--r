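# Directed acyclic graphs over named categorical variables.
#
# A `bn_dag` stores the node order, the parent set of every node and the
# category levels of every node. Edges are kept as parent sets because every
# downstream consumer (scoring, sampling, imputation) works family by family.

#' Construct a directed network over categorical variables
#'
#' @param nodes Character vector of variable names (order is kept).
#' @param parents Named list mapping each node to the character vector of its
#'   parents. Missing entries mean "no parents".
#' @param levels Named list mapping each node to its ordered category labels.
#' @return An object of class `bn_dag`.
#' @export
bn_dag <- function(nodes, parents = list(), levels = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(levels)) {
    levels <- stats::setNames(rep(list(c("a", "b", "c")), length(nodes)), nodes)
  }
  pa <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (nm in names(parents)) {
    if (!nm %in% nodes) stop("parent list names unknown node: ", nm)
    pa[[nm]] <- as.character(parents[[nm]])
  }
  x <- structure(
    list(nodes = nodes, parents = pa, levels = levels[nodes]),
    class = "bn_dag"
  )
  validate_dag(x)
  x
}

validate_dag <- function(x) {
  stopifnot(inherits(x, "bn_dag"))
  for (nm in x$nodes) {
    p <- x$parents[[nm]]
    if (anyDuplicated(p)) stop("duplicate parents for node ", nm)
    if (nm %in% p) stop("self-loop at node ", nm)
    if (!all(p %in% x$nodes)) stop("undeclared parent of node ", nm)
    lv <- x$levels[[nm]]
    if (is.null(lv) || length(lv) < 1) stop("node ", nm, " has no levels")
  }
  if (is.null(topo_sort(x))) stop("edge relation is cyclic")
  invisible(x)
}

#' Topological order of a DAG
#'
#' @param x A `bn_dag`.
#' @return Character vector of nodes in topological order, or `NULL` if the
#'   graph is cyclic.
#' @export
topo_sort <- function(x) {
  remaining <- x$nodes
  placed <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(
      remaining,
      function(nm) all(x$parents[[nm]] %in% placed),
      logical(1)
    )]
    if (!length(ready)) return(NULL)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Edge list of a network
#'
#' @param x A `bn_dag`.
#' @return Two-column character matrix (`from`, `to`), one row per directed
#'   edge.
#' @export
dag_edges <- function(x) {
  from <- unlist(x$parents, use.names = FALSE)
  to <- rep(names(x$parents), lengths(x$parents))
  matrix(c(from, to), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

n_edges <- function(x) sum(lengths(x$parents))

#' Undirected skeleton of a network
#'
#' Drops edge orientations, returning each link as an unordered pair.
#'
#' @param x A `bn_dag` or a `pdag` (partially directed graph).
#' @return Character vector of canonical `"A--B"` pair keys (endpoints
#'   sorted), without duplicates.
#' @export
skeleton <- function(x) {
  if (inherits(x, "pdag")) {
    am <- x$amat
    idx <- which((am | t(am)) & upper.tri(am), arr.ind = TRUE)
    nodes <- rownames(am)
    if (!nrow(idx)) return(character(0))
    return(sort(paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")))
  }
  e <- dag_edges(x)
  if (!nrow(e)) return(character(0))
  sort(unique(ifelse(e[, 1] < e[, 2],
    paste(e[, 1], e[, 2], sep = "--"),
    paste(e[, 2], e[, 1], sep = "--")
  )))
}

# adjacency matrix with amat[i, j] = 1 <=> edge i -> j
dag_amat <- function(x) {
  n <- length(x$nodes)
  am <- matrix(0L, n, n, dimnames = list(x$nodes, x$nodes))
  e <- dag_edges(x)
  if (nrow(e)) am[e] <- 1L
  am
}

amat_to_dag <- function(am, levels) {
  nodes <- rownames(am)
  parents <- lapply(nodes, function(nm) nodes[am[, nm] == 1L])
  names(parents) <- nodes
  bn_dag(nodes, parents, levels)
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(
    "Directed network:", length(x$nodes), "nodes,", n_edges(x), "edges\n"
  )
  shown <- utils::head(x$nodes, 8)
  cat(
    "  nodes:", paste(shown, collapse = ", "),
    if (length(x$nodes) > 8) "..." else "", "\n"
  )
  invisible(x)
}

#' Model-string form of a network
#'
#' Writes the network in the compact `[A][B|A][C|A:B]` text form used across
#' the R Bayesian-network ecosystem (nodes in topological order, parents
#' separated by `:`).
#'
#' @param x A `bn_dag`.
#' @return A single string.
#' @export
modelstring <- function(x) {
  ord <- topo_sort(x)
  paste(vapply(ord, function(nm) {
    p <- x$parents[[nm]]
    if (length(p)) {
      paste0("[", nm, "|", paste(sort(p), collapse = ":"), "]")
    } else {
      paste0("[", nm, "]")
    }
  }, character(1)), collapse = "")
}

#' Parse a model string into a network
#'
#' @param s Model string such as `"[A][B|A]"`.
#' @param levels Optional named list of category levels (defaults to three
#'   shared levels).
#' @return A `bn_dag`.
#' @export
parse_modelstring <- function(s, levels = NULL) {
  parts <- regmatches(s, gregexpr("\\[[^]]+\\]", s))[[1]]
  parts <- substr(parts, 2, nchar(parts) - 1)
  nodes <- character(0)
  parents <- list()
  for (p in parts) {
    bits <- strsplit(p, "|", fixed = TRUE)[[1]]
    nodes <- c(nodes, bits[1])
    parents[[bits[1]]] <- if (length(bits) > 1) {
      strsplit(bits[2], ":", fixed = TRUE)[[1]]
    } else {
      character(0)
    }
  }
  bn_dag(nodes, parents, levels)
}

#' Convert a network to an igraph object
#'
#' @param x A `bn_dag` (directed) or `pdag` (mixed; undirected links become
#'   single undirected edges).
#' @return An `igraph` graph.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "pdag")) {
    am <- x$amat
    und <- (am == 1L) & (t(am) == 1L)
    dir_only <- (am == 1L) & !und
    g <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
    de <- which(dir_only == 1L, arr.ind = TRUE)
    if (nrow(de)) {
      g <- igraph::add_edges(
        g,
        rbind(rownames(am)[de[, 1]], colnames(am)[de[, 2]])
      )
    }
    return(g)
  }
  igraph::graph_from_adjacency_matrix(dag_amat(x), mode = "directed")
}

#' Serialise a network
#'
#' GraphML (via igraph) or an adjacency-list JSON with node levels.
#'
#' @param x A `bn_dag`.
#' @param file Output path.
#' @param format `"graphml"` or `"json"`.
#' @export
write_network <- function(x, file, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(x), file, format = "graphml")
  } else {
    jsonlite::write_json(
      list(nodes = x$nodes, parents = x$parents, levels = x$levels),
      file,
      auto_unbox = FALSE, pretty = TRUE
    )
  }
  invisible(file)
}

#' Read a network from an adjacency-list JSON file
#'
#' @param file Path written by [write_network()] with `format = "json"`.
#' @return A `bn_dag`.
#' @export
read_network_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  parents <- lapply(obj$parents, as.character)
  bn_dag(obj$nodes, parents, lapply(obj$levels, as.character))
}
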