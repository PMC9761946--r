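# Survey analysis stage: repeated-seed structural EM on an incomplete
# categorical table, arc-strength consensus with bimodal thresholding, and
# edge-betweenness community detection on the consensus skeleton.

#' Generate the synthetic survey fixture
#'
#' Builds a categorical table shaped like a linked health-and-retirement
#' survey extract: 29 variables with 2-4 levels, generated from a planted
#' parameterised network of five variable blocks (6, 6, 6, 6 and 5
#' variables) that are densely linked within blocks and joined by single
#' bridge edges, so that genuine communities exist to recover. Missingness
#' is then introduced by the amputation module under MAR with uneven
#' per-variable targets: one variable near 33% missing, two near 10%, the
#' remaining 26 near 1% (co-missing with the heavy variable, so missing
#' patterns overlap), leaving roughly 47% of rows complete.
#'
#' @param n_rows Number of rows (>= 100); default 5726.
#' @param seed Integer seed.
#' @return data.frame of factors with `NA`s; attributes `"planted_network"`
#'   (the generating `bn_fit`), `"planted_blocks"` (named community ids) and
#'   `"ground_truth"` (the complete table).
#' @export
generate_survey_fixture <- function(n_rows = 5726, seed = 1) {
  stopifnot(n_rows >= 100)
  blocks <- rep(1:5, c(6, 6, 6, 6, 5))
  nodes <- paste0("V", sprintf("%02d", seq_along(blocks)))
  n_levels <- rep(2:4, length.out = length(nodes))
  lv <- stats::setNames(
    lapply(n_levels, function(k) letters[seq_len(k)]), nodes
  )

  # within-block spine plus chords; single bridges between consecutive blocks
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (b in 1:5) {
    idx <- which(blocks == b)
    for (k in seq_along(idx)[-1]) {
      p <- idx[k - 1]
      parents[[nodes[idx[k]]]] <- nodes[p]
      if (k >= 3) {
        parents[[nodes[idx[k]]]] <- c(
          parents[[nodes[idx[k]]]], nodes[idx[k - 2]]
        )
      }
    }
  }
  for (b in 1:4) {
    head_next <- nodes[which(blocks == b + 1)[1]]
    tail_this <- nodes[utils::tail(which(blocks == b), 1)]
    parents[[head_next]] <- c(parents[[head_next]], tail_this)
  }
  dag <- bn_dag(nodes, parents, lv)
  bn <- sample_cpts(
    dag, dirichlet_spec(alpha_with_parents = 0.5, alpha_root = 5),
    seed = derive_seed(seed, "survey-cpts")
  )
  complete <- forward_sample(bn, n_rows, seed = derive_seed(seed, "survey-rows"))

  # uneven missingness: V01 ~33%, V15/V16 ~10%, others ~1% (co-missing with
  # V01); total incomplete-row fraction 0.53 -> ~0.47 complete cases
  heavy <- "V01"
  mid <- c("V15", "V16")
  small <- setdiff(nodes, c(heavy, mid))
  total <- 0.53
  freq_small <- (0.01 / total)
  freq_mid <- 0.10 / total
  freq_heavy_alone <- 0.33 / total - length(small) * freq_small
  stopifnot(freq_heavy_alone > 0)
  pat <- matrix(0L, 3 + length(small), length(nodes),
    dimnames = list(NULL, nodes)
  )
  pat[1, heavy] <- 1L
  pat[2, mid[1]] <- 1L
  pat[3, mid[2]] <- 1L
  for (i in seq_along(small)) pat[3 + i, c(heavy, small[i])] <- 1L
  freq <- c(
    freq_heavy_alone, freq_mid, freq_mid, rep(freq_small, length(small))
  )
  freq <- freq / sum(freq)
  spec <- missingness_spec(
    "MAR",
    proportion = total, vars = nodes, patterns = pat, freq = freq
  )
  out <- ampute(complete, spec, seed = derive_seed(seed, "survey-ampute"))
  attr(out, "planted_network") <- bn
  attr(out, "planted_blocks") <- stats::setNames(blocks, nodes)
  out
}

#' Repeated-seed structural EM
#'
#' Runs structural EM `n_repeats` times with distinct derived seeds and
#' returns the CPDAG of every successful run. A sampling E-step is the
#' default here, since with the deterministic mode-imputation E-step every
#' repeat would learn the same network and the consensus would be trivial.
#'
#' @param data data.frame of factors with `NA`s.
#' @param n_repeats Number of runs.
#' @param cfg A [sem_config()]; defaults to `sem_config(estep = "sample")`.
#' @param base_seed Master seed; run `i` uses a seed derived from it.
#' @return List of `pdag`s; attribute `"n_failed"` counts excluded runs.
#' @export
repeated_sem <- function(data, n_repeats = 100,
                         cfg = sem_config(estep = "sample"),
                         base_seed = 1) {
  stopifnot(n_repeats >= 1)
  runs <- vector("list", n_repeats)
  failed <- 0L
  for (i in seq_len(n_repeats)) {
    res <- tryCatch(
      structural_em(data, cfg, seed = derive_seed(base_seed, "repeat", i)),
      error = function(e) NULL
    )
    runs[[i]] <- if (is.null(res)) NULL else to_cpdag(res$network)
    if (is.null(runs[[i]])) failed <- failed + 1L
  }
  runs <- Filter(Negate(is.null), runs)
  attr(runs, "n_failed") <- failed
  runs
}

#' Consensus network from repeated runs
#'
#' The strength of an unordered pair is the fraction of CPDAGs containing
#' the link in any orientation; pairs at or above the threshold are
#' retained.
#'
#' @param networks Nonempty list of `pdag`s (or `bn_dag`s) over one node
#'   set.
#' @param threshold Retention threshold in `[0, 1]`.
#' @return A `consensus_network`: `nodes`, `strengths` (named numeric over
#'   `"A--B"` keys, only pairs seen at least once), `threshold`,
#'   `retained` (character vector of keys).
#' @export
consensus <- function(networks, threshold = 0.87) {
  if (!length(networks)) stop("empty network list")
  skels <- lapply(networks, skeleton)
  all_links <- sort(unique(unlist(skels)))
  strengths <- vapply(
    all_links,
    function(l) mean(vapply(skels, function(s) l %in% s, logical(1))),
    numeric(1)
  )
  structure(
    list(
      nodes = if (inherits(networks[[1]], "pdag")) {
        networks[[1]]$nodes
      } else {
        networks[[1]]$nodes
      },
      strengths = strengths,
      threshold = threshold,
      retained = names(strengths)[strengths >= threshold]
    ),
    class = "consensus_network"
  )
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(
    "Consensus network:", length(x$nodes), "nodes;",
    length(x$strengths), "links seen,", length(x$retained),
    "retained at threshold", x$threshold, "\n"
  )
  invisible(x)
}

#' Detect a bimodal threshold over link strengths
#'
#' If the sorted strengths contain a gap of at least `min_gap` separating a
#' lower and an upper cluster, the minimum of the upper cluster is returned;
#' otherwise the configured default is returned with attribute
#' `"bimodal" = FALSE`.
#'
#' @param strengths Nonempty numeric vector in `[0, 1]`.
#' @param min_gap Minimum gap width qualifying as bimodal.
#' @param default Fallback threshold when no qualifying gap exists.
#' @return Threshold with attribute `"bimodal"`.
#' @export
detect_bimodal_threshold <- function(strengths, min_gap = 0.5,
                                     default = 0.87) {
  stopifnot(length(strengths) >= 1)
  s <- sort(unique(strengths))
  if (length(s) == 1) {
    return(structure(s, bimodal = TRUE))
  }
  gaps <- diff(s)
  best <- which.max(gaps)
  if (gaps[best] >= min_gap) {
    structure(s[best + 1], bimodal = TRUE)
  } else {
    structure(default, bimodal = FALSE)
  }
}

#' Community detection on an undirected skeleton
#'
#' Girvan-Newman divisive clustering: edges are removed in decreasing order
#' of edge betweenness and the partition with maximum modularity along the
#' dendrogram is returned. Isolated nodes become singleton communities.
#'
#' @param skeleton_links Character vector of `"A--B"` links, or a
#'   `consensus_network` (its retained links are used).
#' @param nodes Character vector of all nodes (needed to include isolated
#'   ones); taken from a `consensus_network` automatically.
#' @return A `community_partition`: `membership` (named integer),
#'   `modularity` (of the chosen cut).
#' @export
communities <- function(skeleton_links, nodes = NULL) {
  if (inherits(skeleton_links, "consensus_network")) {
    nodes <- skeleton_links$nodes
    skeleton_links <- skeleton_links$retained
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(unlist(strsplit(skeleton_links, "--", fixed = TRUE))))
  }
  if (!length(nodes)) stop("empty graph")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(skeleton_links)) {
    ends <- do.call(rbind, strsplit(skeleton_links, "--", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)))
  }
  cl <- igraph::cluster_edge_betweenness(
    g,
    weights = NULL, directed = FALSE
  )
  structure(
    list(
      membership = stats::setNames(
        as.integer(igraph::membership(cl)), nodes
      ),
      modularity = if (igraph::ecount(g)) {
        max(igraph::modularity(cl), na.rm = TRUE)
      } else {
        0 # edgeless graph: modularity undefined, singletons returned
      }
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(
    "Community partition:", k, "communities over",
    length(x$membership), "nodes; modularity",
    signif(x$modularity, 4), "\n"
  )
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes; used
#' to compare a recovered partition with planted blocks.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return Numeric ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Run the full survey analysis stage
#'
#' Repeated-seed structural EM, strength computation, bimodal threshold
#' detection, consensus network and community detection in one call.
#'
#' @param data Incomplete data.frame of factors.
#' @param n_repeats Number of SEM runs.
#' @param cfg A [sem_config()] (sampling E-step by default).
#' @param base_seed Master seed.
#' @param threshold Fixed threshold, or `NULL` to detect it from the
#'   strength distribution.
#' @return List with `networks`, `consensus`, `threshold`, `communities`.
#' @export
survey_pipeline <- function(data, n_repeats = 100,
                            cfg = sem_config(estep = "sample"),
                            base_seed = 1, threshold = NULL) {
  nets <- repeated_sem(data, n_repeats, cfg, base_seed)
  cons0 <- consensus(nets, threshold = 0)
  thr <- if (is.null(threshold)) {
    detect_bimodal_threshold(cons0$strengths)
  } else {
    threshold
  }
  cons <- consensus(nets, threshold = as.numeric(thr))
  comm <- communities(cons)
  list(
    networks = nets, consensus = cons, threshold = thr, communities = comm
  )
}

#' Write a consensus network as GraphML with strength attributes
#'
#' @param x A `consensus_network`.
#' @param file Output path.
#' @export
write_consensus_graphml <- function(x, file) {
  g <- igraph::make_empty_graph(n = length(x$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x$nodes)
  if (length(x$retained)) {
    ends <- do.call(rbind, strsplit(x$retained, "--", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)))
    g <- igraph::set_edge_attr(
      g, "strength",
      value = unname(x$strengths[x$retained])
    )
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
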