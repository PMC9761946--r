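# Random parameterised networks and forward sampling.
#
# Simulation-mode defaults follow the study conditions: random DAGs with
# maximum in-degree 3 and three shared levels per node, CPT rows drawn from a
# symmetric Dirichlet with concentration 0.5 for nodes with parents and 5 for
# parentless nodes.

#' Dirichlet concentration specification for CPT sampling
#'
#' @param alpha_with_parents Concentration per cell for nodes with at least
#'   one parent. Small values give sharp, strongly informative conditional
#'   distributions.
#' @param alpha_root Concentration for parentless nodes; larger values keep
#'   root marginals close to uniform.
#' @return A `dirichlet_spec` list.
#' @export
dirichlet_spec <- function(alpha_with_parents = 0.5, alpha_root = 5) {
  stopifnot(alpha_with_parents > 0, alpha_root > 0)
  structure(
    list(alpha_with_parents = alpha_with_parents, alpha_root = alpha_root),
    class = "dirichlet_spec"
  )
}

#' Generate a random DAG
#'
#' Draws a uniform random topological order, then gives each node an
#' in-degree drawn uniformly from `0..min(max_in_degree, #predecessors)` with
#' parents chosen uniformly without replacement among its predecessors. This
#' satisfies the required structural properties (acyclic, bounded in-degree,
#' shared level set); the provenance attribute records the generator so an
#' alternative (e.g. an MCMC-based one) can be swapped in.
#'
#' @param n_nodes Number of variables (>= 2).
#' @param max_in_degree Maximum number of parents per node.
#' @param n_levels Number of category levels shared by all nodes.
#' @param seed Integer seed; the same seed gives an identical network.
#' @param connected If `TRUE`, redraw until the skeleton is weakly connected
#'   (up to 100 attempts), mimicking multi-connected generators.
#' @return A `bn_dag` with node names `X1..Xn`.
#' @export
generate_random_dag <- function(n_nodes, max_in_degree = 3, n_levels = 3,
                                seed = 1, connected = FALSE) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  stopifnot(max_in_degree >= 1, n_levels >= 2)
  nodes <- paste0("X", seq_len(n_nodes))
  lv <- stats::setNames(
    rep(list(letters[seq_len(n_levels)]), n_nodes), nodes
  )
  draw <- function(attempt) {
    with_seed(derive_seed(seed, "dag", attempt), {
      ord <- sample(nodes)
      parents <- stats::setNames(rep(list(character(0)), n_nodes), nodes)
      for (i in seq_along(ord)) {
        k_max <- min(max_in_degree, i - 1L)
        k <- sample.int(k_max + 1L, 1L) - 1L
        if (k > 0) {
          pred <- ord[seq_len(i - 1L)]
          parents[[ord[i]]] <- sort(pred[sample.int(i - 1L, k)])
        }
      }
      parents
    })
  }
  for (attempt in seq_len(if (connected) 100L else 1L)) {
    g <- bn_dag(nodes, draw(attempt), lv)
    if (!connected) break
    ig <- as_igraph(g)
    if (igraph::is_connected(ig, mode = "weak")) break
  }
  attr(g, "provenance") <- list(
    generator = "uniform-order-random-parents",
    max_in_degree = max_in_degree, seed = seed, connected = connected
  )
  g
}

# symmetric Dirichlet draws, one row per parent configuration
rdirichlet_sym <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  g / rowSums(g)
}

#' Attach random conditional probability tables to a structure
#'
#' Every CPT row (one per joint parent configuration) is drawn from a
#' symmetric Dirichlet: concentration `alpha_with_parents` for nodes with
#' parents, `alpha_root` for parentless nodes.
#'
#' @param structure A `bn_dag`.
#' @param spec A [dirichlet_spec()].
#' @param seed Integer seed.
#' @return A `bn_fit`: the structure plus `$cpts`, a named list of
#'   `q x r` matrices (rows = parent configurations in mixed-radix order with
#'   the first parent varying fastest, columns = own levels).
#' @export
sample_cpts <- function(structure, spec = dirichlet_spec(), seed = 1) {
  validate_dag(structure)
  stopifnot(inherits(spec, "dirichlet_spec"))
  cpts <- with_seed(derive_seed(seed, "cpts"), {
    lapply(stats::setNames(structure$nodes, structure$nodes), function(nm) {
      r <- length(structure$levels[[nm]])
      pa <- structure$parents[[nm]]
      q <- prod(vapply(structure$levels[pa], length, integer(1)))
      alpha <- if (length(pa)) spec$alpha_with_parents else spec$alpha_root
      m <- rdirichlet_sym(q, r, alpha)
      dimnames(m) <- list(NULL, structure$levels[[nm]])
      m
    })
  })
  structure(
    list(
      nodes = structure$nodes, parents = structure$parents,
      levels = structure$levels, cpts = cpts
    ),
    class = c("bn_fit", "bn_dag")
  )
}

validate_fit <- function(x, tol = 1e-12) {
  validate_dag(x)
  for (nm in x$nodes) {
    m <- x$cpts[[nm]]
    q <- prod(vapply(x$levels[x$parents[[nm]]], length, integer(1)))
    r <- length(x$levels[[nm]])
    stopifnot(nrow(m) == q, ncol(m) == r, all(m >= 0))
    if (any(abs(rowSums(m) - 1) > tol)) {
      stop("CPT rows of ", nm, " do not sum to 1")
    }
  }
  invisible(x)
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(
    "Parameterised network:", length(x$nodes), "nodes,",
    n_edges(x), "edges, CPTs attached\n"
  )
  invisible(x)
}

# row index into a CPT for given parent level codes (matrix rows x parents)
cpt_row_index <- function(pa_codes, pa_sizes) {
  if (!length(pa_sizes)) {
    return(rep(1L, nrow(pa_codes)))
  }
  stride <- cumprod(c(1L, utils::head(pa_sizes, -1L)))
  as.integer(1L + (pa_codes - 1L) %*% stride)
}

#' Draw complete samples from a parameterised network
#'
#' Ancestral (forward) sampling in topological order.
#'
#' @param bn A `bn_fit` from [sample_cpts()] or [fit_mle()].
#' @param n_rows Number of rows to draw.
#' @param seed Integer seed.
#' @return A `data.frame` of factors, one column per node, no missing values.
#' @export
forward_sample <- function(bn, n_rows, seed = 1) {
  stopifnot(inherits(bn, "bn_fit"), n_rows >= 1)
  ord <- topo_sort(bn)
  codes <- matrix(0L, n_rows, length(bn$nodes),
    dimnames = list(NULL, bn$nodes)
  )
  with_seed(derive_seed(seed, "sample"), {
    for (nm in ord) {
      pa <- bn$parents[[nm]]
      r <- length(bn$levels[[nm]])
      cpt <- bn$cpts[[nm]]
      rows <- cpt_row_index(
        codes[, pa, drop = FALSE],
        vapply(bn$levels[pa], length, integer(1))
      )
      u <- stats::runif(n_rows)
      cum <- cpt[rows, , drop = FALSE] %*% upper.tri(diag(r), diag = TRUE)
      # inverse-CDF draw per row against that row's conditional distribution
      codes[, nm] <- 1L + as.integer(rowSums(u > cum + 1e-15))
      codes[codes[, nm] > r, nm] <- r
    }
  })
  codes_to_table(codes, bn$levels)
}

codes_to_table <- function(codes, levels) {
  df <- as.data.frame(lapply(
    stats::setNames(colnames(codes), colnames(codes)),
    function(nm) {
      factor(levels[[nm]][codes[, nm]], levels = levels[[nm]])
    }
  ))
  df
}

table_to_codes <- function(df) {
  m <- vapply(df, as.integer, integer(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  colnames(m) <- names(df)
  m
}

table_levels <- function(df) lapply(df, levels)

#' Exact joint distribution of a small network
#'
#' Enumerates all joint configurations and multiplies CPT entries; usable as
#' an oracle on networks of up to ~8 three-level nodes.
#'
#' @param bn A `bn_fit`.
#' @return A data.frame with one row per configuration and a `prob` column.
#' @export
exact_joint <- function(bn) {
  sizes <- vapply(bn$levels, length, integer(1))
  if (prod(sizes) > 1e6) stop("network too large for enumeration")
  grid <- do.call(
    expand.grid,
    c(lapply(bn$levels, seq_along), KEEP.OUT.ATTRS = FALSE)
  )
  codes <- as.matrix(grid)
  colnames(codes) <- bn$nodes
  prob <- rep(1, nrow(codes))
  for (nm in bn$nodes) {
    pa <- bn$parents[[nm]]
    rows <- cpt_row_index(
      codes[, pa, drop = FALSE],
      vapply(bn$levels[pa], length, integer(1))
    )
    prob <- prob * bn$cpts[[nm]][cbind(rows, codes[, nm])]
  }
  out <- codes_to_table(codes, bn$levels)
  out$prob <- prob
  out
}
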