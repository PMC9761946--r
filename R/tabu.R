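# Tabu search over DAG space with single-edge moves.
#
# Greedy hill climbing over additions, deletions and reversals that preserve
# acyclicity, with a tabu list of recently visited structures (tenure-limited)
# and tolerance for a bounded number of non-improving steps past a local
# optimum.
# The search is deterministic: candidate moves are scored against a memoised
# family-score cache and ties are broken lexicographically by
# (operation, parent, child).

#' Search configuration for tabu structure learning
#'
#' @param tabu_tenure Number of iterations a just-visited structure stays
#'   forbidden.
#' @param max_non_improving Number of consecutive moves without improving the
#'   best score before stopping.
#' @param max_iterations Hard iteration cap.
#' @return A `search_config` list.
#' @export
search_config <- function(tabu_tenure = 10, max_non_improving = 10,
                          max_iterations = 500) {
  stopifnot(tabu_tenure >= 1, max_non_improving >= 1, max_iterations >= 1)
  structure(
    list(
      tabu_tenure = tabu_tenure, max_non_improving = max_non_improving,
      max_iterations = max_iterations
    ),
    class = "search_config"
  )
}

# reach[i, j] == TRUE iff a directed path of length >= 1 leads from i to j
# (Floyd-Warshall on logical rows; avoids matrix products on tiny inputs)
reachability <- function(amat) {
  r <- amat > 0
  n <- nrow(amat)
  for (k in seq_len(n)) {
    hit <- which(r[, k])
    if (length(hit)) {
      r[hit, ] <- r[hit, , drop = FALSE] |
        matrix(r[k, ], length(hit), n, byrow = TRUE)
    }
  }
  r
}

#' Learn a network structure by tabu search
#'
#' Starts from the empty graph, repeatedly applies the best admissible
#' single-edge move, and returns the best-scoring structure visited. Moves
#' that lead back to a recently visited structure are tabu for
#' `tabu_tenure` iterations unless they beat the best score seen so far
#' (aspiration). The search continues through up to `max_non_improving`
#' non-improving moves before stopping.
#'
#' @param data Complete data.frame of factors (no missing cells; impute or
#'   drop incomplete rows first).
#' @param score_cfg A [score_config()].
#' @param search_cfg A [search_config()].
#' @param seed Unused by the deterministic search; kept so callers can treat
#'   all learners uniformly.
#' @return A `bn_dag`.
#' @export
tabu_search <- function(data, score_cfg = score_config(),
                        search_cfg = search_config(), seed = 1) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  if (!nrow(data)) stop("data has no rows")
  if (anyNA(data)) stop("data contains missing cells; impute or drop first")
  nodes <- names(data)
  n <- length(nodes)
  codes_mat <- table_to_codes(data)
  sizes <- vapply(data, nlevels, integer(1))
  n_rows <- nrow(data)

  # family-score cache keyed arithmetically: a parent set is the exact
  # double 2^i1 + ... + 2^ik (unique for n <= 50), so no sorting or string
  # canonicalisation is needed on the hot path
  cache <- new.env(parent = emptyenv(), size = 8192L)
  pow2 <- 2^(seq_len(n))
  score_idx <- function(j, pa_idx, bits) {
    key <- paste0(j, "|", bits)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    val <- family_score_codes(codes_mat, j, pa_idx, sizes, score_cfg, n_rows)
    cache[[key]] <- val
    val
  }

  amat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  pa_list <- rep(list(integer(0)), n) # parent indices, ascending
  bits <- numeric(n) # sum of 2^parent per node
  fam <- vapply(seq_len(n), function(j) score_idx(j, integer(0), 0), numeric(1))
  cur <- sum(fam)
  best <- cur
  best_amat <- amat
  # tabu list of recently visited structures: fingerprint -> expiry iteration
  visited <- new.env(parent = emptyenv())
  edge_code <- function(i, j) i + n * (j - 1L)
  ecodes <- integer(0) # sorted edge codes of the current structure
  fingerprint <- function(cds) paste0("s", paste(cds, collapse = ","))
  neighbour_codes <- function(op, i, j) {
    code <- edge_code(i, j)
    if (op == 1L) { # add
      ins <- findInterval(code, ecodes)
      append(ecodes, code, after = ins)
    } else if (op == 2L) { # delete
      ecodes[ecodes != code]
    } else { # reverse
      rc <- edge_code(j, i)
      rest <- ecodes[ecodes != code]
      append(rest, rc, after = findInterval(rc, rest))
    }
  }
  visited[[fingerprint(ecodes)]] <- search_cfg$max_iterations + 1L
  non_improving <- 0L
  n_max <- 2L * n * n
  cand_op <- integer(n_max) # 1 = add, 2 = delete, 3 = reverse
  cand_i <- integer(n_max)
  cand_j <- integer(n_max)
  cand_delta <- numeric(n_max)

  for (iter in seq_len(search_cfg$max_iterations)) {
    # path-count matrix of the DAG: (I - A)^-1 - I (A nilpotent, so exact).
    # An addition i->j is acyclic iff no path j ~> i; a reversal of i->j is
    # acyclic iff the edge itself is the only i ~> j path (count == 1),
    # since a simple path through a DAG can use that edge only en bloc.
    paths <- solve(diag(n) - amat) - diag(n)
    k <- 0L

    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (amat[i, j] == 1L) {
          # deletion: always acyclic
          pa_del <- pa_list[[j]][pa_list[[j]] != i]
          d_del <- score_idx(j, pa_del, bits[j] - pow2[i]) - fam[j]
          k <- k + 1L
          cand_op[k] <- 2L
          cand_i[k] <- i
          cand_j[k] <- j
          cand_delta[k] <- d_del
          # reversal: needs no alternative i ~> j path
          if (abs(paths[i, j] - 1) < 0.5) {
            d_rev <- d_del - fam[i] +
              score_idx(i, c(pa_list[[i]], j), bits[i] + pow2[j])
            k <- k + 1L
            cand_op[k] <- 3L
            cand_i[k] <- i
            cand_j[k] <- j
            cand_delta[k] <- d_rev
          }
        } else if (amat[j, i] == 0L && paths[j, i] < 0.5) {
          d_add <- score_idx(j, c(pa_list[[j]], i), bits[j] + pow2[i]) - fam[j]
          k <- k + 1L
          cand_op[k] <- 1L
          cand_i[k] <- i
          cand_j[k] <- j
          cand_delta[k] <- d_add
        }
      }
    }
    if (!k) break
    ix <- seq_len(k)

    # walk candidates best-first; fingerprints are computed lazily, only for
    # the front-runners actually tested against the tabu list
    ord <- order(
      -cand_delta[ix], cand_op[ix], cand_i[ix], cand_j[ix],
      method = "radix"
    )
    pick <- 0L
    new_codes <- NULL
    for (p in ord) {
      nc <- neighbour_codes(cand_op[p], cand_i[p], cand_j[p])
      expiry <- visited[[fingerprint(nc)]]
      if (is.null(expiry) || expiry < iter ||
        cur + cand_delta[p] > best + 1e-10) {
        pick <- p
        new_codes <- nc
        break
      }
    }
    if (!pick) break
    op <- cand_op[pick]
    i <- cand_i[pick]
    j <- cand_j[pick]

    refresh <- function(v) {
      pa_list[[v]] <<- which(amat[, v] == 1L)
      bits[v] <<- sum(pow2[pa_list[[v]]])
      fam[v] <<- score_idx(v, pa_list[[v]], bits[v])
    }
    if (op == 1L) {
      amat[i, j] <- 1L
      refresh(j)
    } else if (op == 2L) {
      amat[i, j] <- 0L
      refresh(j)
    } else {
      amat[i, j] <- 0L
      amat[j, i] <- 1L
      refresh(j)
      refresh(i)
    }
    ecodes <- new_codes
    visited[[fingerprint(ecodes)]] <- iter + search_cfg$tabu_tenure
    cur <- sum(fam)

    if (cur > best + 1e-10) {
      best <- cur
      best_amat <- amat
      non_improving <- 0L
    } else {
      non_improving <- non_improving + 1L
      if (non_improving > search_cfg$max_non_improving) break
    }
  }

  out <- amat_to_dag(best_amat, table_levels(data))
  attr(out, "score") <- best
  out
}

#' Exhaustive best-scoring DAG (oracle for tiny problems)
#'
#' Enumerates every DAG on up to 4 nodes and returns the one with the best
#' total score; intended as an independent check of search results.
#'
#' @param data Complete data.frame of factors (2-4 columns).
#' @param score_cfg A [score_config()].
#' @return A `bn_dag` with attribute `"score"`.
#' @export
exhaustive_search <- function(data, score_cfg = score_config()) {
  nodes <- names(data)
  n <- length(nodes)
  stopifnot(n >= 2, n <= 4)
  score <- make_scorer(data, score_cfg)
  pairs <- which(
    upper.tri(matrix(0, n, n)),
    arr.ind = TRUE
  )
  best <- -Inf
  best_amat <- NULL
  # each unordered pair is absent, forward or backward: 3^(n(n-1)/2) graphs
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  for (g in seq_len(nrow(states))) {
    amat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    for (e in seq_len(nrow(pairs))) {
      st <- states[g, e]
      if (st == 1) {
        amat[pairs[e, 1], pairs[e, 2]] <- 1L
      } else if (st == 2) {
        amat[pairs[e, 2], pairs[e, 1]] <- 1L
      }
    }
    if (any(reachability(amat) & diag(n) > 0)) next
    s <- sum(vapply(seq_len(n), function(j) {
      score(nodes[j], nodes[amat[, j] == 1L])
    }, numeric(1)))
    if (s > best) {
      best <- s
      best_amat <- amat
    }
  }
  out <- amat_to_dag(best_amat, table_levels(data))
  attr(out, "score") <- best
  out
}
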