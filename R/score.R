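# Decomposable network scores for complete discrete data.
#
# BDe (BDeu prior: imaginary sample size spread uniformly over all cells),
# BDs (sparse variant: prior mass spread only over parent configurations
# observed in the data), and BIC with penalty coefficient c, i.e.
# log-likelihood minus c * (number of free parameters). All scores decompose
# over families, which is what makes local-move search cheap.

#' Score configuration
#'
#' @param score_name `"BDe"`, `"BDs"` or `"BIC"`.
#' @param imaginary_sample_size Equivalent prior sample size for BDe/BDs
#'   (default 1).
#' @param bic_penalty_coefficient Penalty per free parameter for BIC; the
#'   default `NULL` means `log(n)/2`, the classical BIC weight, filled in at
#'   scoring time from the data size.
#' @return A `score_config` list.
#' @export
score_config <- function(score_name = c("BDe", "BDs", "BIC"),
                         imaginary_sample_size = 1,
                         bic_penalty_coefficient = NULL) {
  score_name <- match.arg(score_name)
  stopifnot(imaginary_sample_size > 0)
  structure(
    list(
      score_name = score_name,
      imaginary_sample_size = imaginary_sample_size,
      bic_penalty_coefficient = bic_penalty_coefficient
    ),
    class = "score_config"
  )
}

# Family sufficient statistics: counts N_ijk as an r x q matrix
# (child level k in rows, parent configuration j in columns).
family_counts <- function(codes, node, parents, sizes) {
  r <- sizes[[node]]
  q <- if (length(parents)) prod(sizes[parents]) else 1L
  child <- codes[, node]
  if (length(parents)) {
    stride <- cumprod(c(1, sizes[parents][-length(parents)]))
    j <- as.integer((codes[, parents, drop = FALSE] - 1L) %*% stride)
    idx <- child + r * j
  } else {
    idx <- child
  }
  matrix(tabulate(idx, nbins = r * q), nrow = r)
}

#' Local (family) score of one node given a parent set
#'
#' @param node Node name.
#' @param parents Character vector of parent names (may be empty).
#' @param data Complete data.frame of factors.
#' @param cfg A [score_config()].
#' @return The family's contribution to the network log-score.
#' @export
family_score <- function(node, parents, data, cfg = score_config()) {
  if (!nrow(data)) stop("empty data")
  if (node %in% parents) stop("node cannot be its own parent")
  codes <- table_to_codes(data)
  sizes <- vapply(data, nlevels, integer(1))
  family_score_codes(codes, node, parents, sizes, cfg, nrow(data))
}

family_score_codes <- function(codes, node, parents, sizes, cfg, n) {
  counts <- family_counts(codes, node, parents, sizes)
  r <- nrow(counts)
  q <- ncol(counts)
  nij <- colSums(counts)
  if (cfg$score_name == "BIC") {
    pen <- if (is.null(cfg$bic_penalty_coefficient)) {
      log(n) * 0.5
    } else {
      cfg$bic_penalty_coefficient
    }
    pos <- counts > 0
    ll <- sum(counts[pos] * log(counts[pos] / rep(nij, each = r)[pos]))
    return(ll - pen * q * (r - 1))
  }
  iss <- cfg$imaginary_sample_size
  if (cfg$score_name == "BDs") {
    observed <- nij > 0
    q_eff <- sum(observed)
    counts <- counts[, observed, drop = FALSE]
    nij <- nij[observed]
  } else {
    q_eff <- q
  }
  aijk <- iss / (q_eff * r)
  aij <- iss / q_eff
  sum(lgamma(aij) - lgamma(aij + nij)) +
    sum(lgamma(aijk + counts) - lgamma(aijk))
}

#' Total network score
#'
#' Sum of family scores over all nodes (decomposability).
#'
#' @param dag A `bn_dag`.
#' @param data Complete data.frame of factors over the DAG's nodes.
#' @param cfg A [score_config()].
#' @return Network log-score.
#' @export
network_score <- function(dag, data, cfg = score_config()) {
  codes <- table_to_codes(data)
  sizes <- vapply(data, nlevels, integer(1))
  n <- nrow(data)
  sum(vapply(
    dag$nodes,
    function(nm) {
      family_score_codes(codes, nm, dag$parents[[nm]], sizes, cfg, n)
    },
    numeric(1)
  ))
}

# Memoising scorer over a fixed data matrix. Returns a closure
# score(node, parents) with an environment-backed cache keyed by the family.
make_scorer <- function(data, cfg) {
  codes <- table_to_codes(data)
  sizes <- vapply(data, nlevels, integer(1))
  n <- nrow(data)
  cache <- new.env(parent = emptyenv(), size = 4096L)
  function(node, parents) {
    key <- if (length(parents)) {
      paste0(node, "|", paste(sort.int(parents), collapse = ","))
    } else {
      node
    }
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    val <- family_score_codes(codes, node, parents, sizes, cfg, n)
    cache[[key]] <- val
    val
  }
}
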