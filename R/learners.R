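# The three strategies for structure learning from incomplete data:
# complete-case analysis, chained-equation imputation followed by learning,
# and hard-assignment structural EM.

#' Structural EM configuration
#'
#' @param max_em_iterations Maximum E/M iterations (default 5).
#' @param estep `"mode"` fills each missing cell with the most probable
#'   category given its parents (deterministic); `"sample"` draws from the
#'   conditional distribution instead, which is what makes repeated-seed
#'   consensus runs differ.
#' @param score_cfg A [score_config()].
#' @param search_cfg A [search_config()].
#' @return A `sem_config` list.
#' @export
sem_config <- function(max_em_iterations = 5, estep = c("mode", "sample"),
                       score_cfg = score_config(),
                       search_cfg = search_config()) {
  stopifnot(max_em_iterations >= 1)
  structure(
    list(
      max_em_iterations = max_em_iterations, estep = match.arg(estep),
      impute_method = "parents",
      score_cfg = score_cfg, search_cfg = search_cfg
    ),
    class = "sem_config"
  )
}

#' Chained-equation imputation configuration
#'
#' @param n_cycles Number of full passes over the variables (default 5).
#' @param n_completed_datasets Number of completed tables to produce
#'   (structure learning uses one).
#' @param ridge Ridge penalty stabilising the polytomous logistic fits.
#' @return A `mice_config` list.
#' @export
mice_config <- function(n_cycles = 5, n_completed_datasets = 1,
                        ridge = 1e-3) {
  stopifnot(n_cycles >= 1, n_completed_datasets >= 1, ridge > 0)
  structure(
    list(
      n_cycles = n_cycles,
      predictor_model = "polytomous-logistic",
      n_completed_datasets = n_completed_datasets, ridge = ridge
    ),
    class = "mice_config"
  )
}

learn_output <- function(method, network, completed = NULL,
                         diagnostics = list()) {
  structure(
    list(
      method = method, network = network, completed = completed,
      diagnostics = diagnostics
    ),
    class = "learn_output"
  )
}

#' @export
print.learn_output <- function(x, ...) {
  cat("Learned network (method:", x$method, ")\n")
  if (is.null(x$network)) {
    cat("  no result:", x$diagnostics$error, "\n")
  } else {
    cat(
      "  ", length(x$network$nodes), "nodes,", n_edges(x$network),
      "edges;", if (is.null(x$completed)) {
        "no completed table"
      } else {
        "completed table attached"
      }, "\n"
    )
  }
  invisible(x)
}

#' Complete-case structure learning
#'
#' Listwise deletion followed by tabu search: only rows with no missing cell
#' are used.
#'
#' @param data data.frame of factors, possibly with `NA`s.
#' @param score_cfg,search_cfg Scoring and search configurations.
#' @return A `learn_output`; if no complete rows remain, the network is
#'   `NULL` and the diagnostics record the failure (so replicate batches can
#'   continue).
#' @export
learn_complete_cases <- function(data, score_cfg = score_config(),
                                 search_cfg = search_config()) {
  complete <- stats::complete.cases(data)
  if (!any(complete)) {
    return(learn_output(
      "none", NULL,
      diagnostics = list(error = "no complete cases", n_used = 0L)
    ))
  }
  used <- droplevels_keep(data[complete, , drop = FALSE])
  net <- tabu_search(used, score_cfg, search_cfg)
  learn_output("none", net, diagnostics = list(n_used = sum(complete)))
}

# subsetting keeps factor levels (they are part of the variable definition)
droplevels_keep <- function(df) {
  df
}

#' Maximum-likelihood CPT fit
#'
#' Counts family configurations on complete data; parent configurations
#' never observed get a uniform conditional (they carry no likelihood and a
#' proper distribution is needed for downstream imputation).
#'
#' @param dag A `bn_dag`.
#' @param data Complete data.frame of factors over the DAG's nodes.
#' @return A `bn_fit`.
#' @export
fit_mle <- function(dag, data) {
  stopifnot(!anyNA(data))
  codes <- table_to_codes(data)
  sizes <- vapply(data, nlevels, integer(1))
  cpts <- lapply(stats::setNames(dag$nodes, dag$nodes), function(nm) {
    counts <- t(family_counts(codes, nm, dag$parents[[nm]], sizes)) # q x r
    tot <- rowSums(counts)
    m <- counts / ifelse(tot > 0, tot, 1)
    m[tot == 0, ] <- 1 / ncol(m)
    dimnames(m) <- list(NULL, dag$levels[[nm]])
    m
  })
  structure(
    list(
      nodes = dag$nodes, parents = dag$parents, levels = dag$levels,
      cpts = cpts
    ),
    class = c("bn_fit", "bn_dag")
  )
}

# marginal-only fit from available (observed) cells; used to seed the EM
fit_marginals_available <- function(data) {
  nodes <- names(data)
  cpts <- lapply(stats::setNames(nodes, nodes), function(nm) {
    tab <- tabulate(as.integer(data[[nm]]), nbins = nlevels(data[[nm]]))
    if (sum(tab) == 0) stop("variable ", nm, " has no observed values")
    m <- matrix(tab / sum(tab), nrow = 1)
    colnames(m) <- levels(data[[nm]])
    m
  })
  structure(
    list(
      nodes = nodes,
      parents = stats::setNames(
        rep(list(character(0)), length(nodes)), nodes
      ),
      levels = table_levels(data), cpts = cpts
    ),
    class = c("bn_fit", "bn_dag")
  )
}

#' Impute missing cells from each node's parents
#'
#' Fills missing cells in topological order (so parents are completed before
#' their children) using the node's conditional distribution given the
#' parent values in the same row. `draw = FALSE` takes the most probable
#' category, ties broken by the lowest level index; `draw = TRUE` samples.
#'
#' @param table data.frame of factors with `NA`s.
#' @param bn A `bn_fit` whose parameters cover every node.
#' @param seed Integer seed (used only when `draw = TRUE`).
#' @param draw Sample instead of taking the mode.
#' @return Completed data.frame; observed cells are untouched.
#' @export
impute_from_parents <- function(table, bn, seed = 1, draw = FALSE) {
  stopifnot(inherits(bn, "bn_fit"))
  out <- table
  ord <- topo_sort(bn)
  runner <- function() {
    for (nm in ord) {
      miss <- which(is.na(out[[nm]]))
      if (!length(miss)) next
      pa <- bn$parents[[nm]]
      cpt <- bn$cpts[[nm]]
      if (length(pa)) {
        pa_codes <- vapply(
          out[miss, pa, drop = FALSE], as.integer, integer(length(miss))
        )
        if (is.null(dim(pa_codes))) {
          pa_codes <- matrix(pa_codes, nrow = length(miss))
        }
        rows <- cpt_row_index(
          pa_codes, vapply(bn$levels[pa], length, integer(1))
        )
      } else {
        rows <- rep(1L, length(miss))
      }
      probs <- cpt[rows, , drop = FALSE]
      pick <- if (draw) {
        r <- ncol(probs)
        cum <- probs %*% upper.tri(diag(r), diag = TRUE)
        u <- stats::runif(length(miss))
        pmin(1L + as.integer(rowSums(u > cum + 1e-15)), r)
      } else {
        max.col(probs, ties.method = "first")
      }
      out[[nm]][miss] <- factor(
        bn$levels[[nm]][pick], levels = bn$levels[[nm]]
      )
    }
    out
  }
  if (draw) with_seed(derive_seed(seed, "parents-impute"), runner()) else runner()
}

#' Structure learning by hard-assignment structural EM
#'
#' Starts from an empty network with marginals fitted on the available
#' (observed) cells, then alternates an E-step that completes the data from
#' the current network (parents-based imputation) with an M-step that runs
#' tabu search on the completed table and refits parameters by maximum
#' likelihood. Stops when the structure is unchanged between iterations or
#' after `max_em_iterations`.
#'
#' @param data data.frame of factors with `NA`s.
#' @param cfg A [sem_config()].
#' @param seed Integer seed (drives the E-step only when
#'   `cfg$estep == "sample"`).
#' @return A `learn_output` with the final network, the final completed
#'   table, and per-iteration score diagnostics.
#' @export
structural_em <- function(data, cfg = sem_config(), seed = 1) {
  never_observed <- vapply(
    data, function(v) all(is.na(v)), logical(1)
  )
  if (any(never_observed)) {
    stop(
      "variable(s) never observed: ",
      paste(names(data)[never_observed], collapse = ", ")
    )
  }
  params <- fit_marginals_available(data)
  prev_edges <- NULL
  net <- NULL
  completed <- NULL
  trace <- NULL
  draw <- cfg$estep == "sample"
  for (iter in seq_len(cfg$max_em_iterations)) {
    completed <- impute_from_parents(
      data, params,
      seed = derive_seed(seed, "sem-estep", iter), draw = draw
    )
    net <- tabu_search(completed, cfg$score_cfg, cfg$search_cfg)
    params <- fit_mle(net, completed)
    sc <- attr(net, "score")
    # hard assignment does not guarantee a monotone score; record, don't stop
    decreased <- !is.null(trace) && sc < trace$score[nrow(trace)]
    trace <- rbind(
      trace,
      data.frame(
        iteration = iter, score = sc, n_edges = n_edges(net),
        score_decreased = decreased
      )
    )
    edges <- skeleton_with_direction(net)
    if (identical(edges, prev_edges)) break
    prev_edges <- edges
  }
  if (any(trace$score_decreased)) {
    message(
      "structural_em: score decreased at iteration(s) ",
      paste(trace$iteration[trace$score_decreased], collapse = ", "),
      " (expected occasionally under hard assignment)"
    )
  }
  learn_output(
    "sem", net, completed,
    diagnostics = list(trace = trace, iterations = nrow(trace))
  )
}

skeleton_with_direction <- function(net) {
  e <- dag_edges(net)
  if (!nrow(e)) return(character(0))
  sort(paste(e[, 1], e[, 2], sep = ">"))
}

# one polytomous-logistic conditional fit + draw; falls back to the observed
# marginal when the fit is degenerate
draw_polytomous <- function(y_obs, x_obs, x_mis, ridge) {
  lev <- levels(y_obs)
  obs_lev <- levels(droplevels(y_obs))
  fallback <- function() {
    tab <- tabulate(as.integer(y_obs), nbins = length(lev))
    probs <- matrix(
      tab / sum(tab), nrow(x_mis), length(lev),
      byrow = TRUE
    )
    list(probs = probs, fallback = TRUE)
  }
  if (length(obs_lev) < 2 || nrow(x_obs) < 10) {
    return(fallback())
  }
  res <- tryCatch(
    suppressWarnings({
      y <- droplevels(y_obs)
      fit <- glmnet::glmnet(
        x_obs, y,
        family = "multinomial", alpha = 0,
        lambda = c(0.5, 0.1, ridge), standardize = TRUE
      )
      pr <- stats::predict(fit, newx = x_mis, s = ridge, type = "response")
      probs <- matrix(0, nrow(x_mis), length(lev))
      probs[, match(obs_lev, lev)] <- pr[, , 1]
      list(probs = probs, fallback = FALSE)
    }),
    error = function(e) NULL
  )
  if (is.null(res)) fallback() else res
}

#' Chained-equation imputation with polytomous logistic models
#'
#' Missing cells are first filled by draws from each variable's observed
#' empirical distribution; then, for a fixed number of cycles, each variable
#' in column order has its imputations unset, a ridge-stabilised polytomous
#' (multinomial) logistic regression of the variable on all other variables
#' is fitted on the rows where it is observed, and fresh imputations are
#' drawn from the fitted category probabilities. Degenerate fits (a single
#' observed level, separation, non-convergence) fall back to the observed
#' marginal for that cycle and are logged in the diagnostics.
#'
#' @param data data.frame of factors with `NA`s.
#' @param cfg A [mice_config()].
#' @param seed Integer seed.
#' @return Completed data.frame (attribute `"diagnostics"` lists fallback
#'   counts); observed cells are untouched.
#' @export
mice_impute <- function(data, cfg = mice_config(), seed = 1) {
  mask <- missing_mask(data)
  if (!any(mask)) {
    return(data)
  }
  vars <- names(data)
  n_fallback <- 0L
  completed <- data
  with_seed(derive_seed(seed, "mice"), {
    for (v in vars) {
      miss <- mask[, v]
      if (!any(miss)) next
      obs_vals <- completed[[v]][!miss]
      completed[[v]][miss] <- sample(
        obs_vals,
        sum(miss),
        replace = TRUE
      )
    }
    for (cycle in seq_len(cfg$n_cycles)) {
      for (v in vars) {
        miss <- mask[, v]
        if (!any(miss)) next
        others <- completed[setdiff(vars, v)]
        x <- stats::model.matrix(
          ~ . - 1,
          data = others,
          contrasts.arg = lapply(
            others, stats::contrasts,
            contrasts = FALSE
          )
        )
        res <- draw_polytomous(
          completed[[v]][!miss],
          x[!miss, , drop = FALSE],
          x[miss, , drop = FALSE],
          cfg$ridge
        )
        if (res$fallback) n_fallback <- n_fallback + 1L
        r <- ncol(res$probs)
        cum <- res$probs %*% upper.tri(diag(r), diag = TRUE)
        u <- stats::runif(sum(miss))
        pick <- pmin(1L + as.integer(rowSums(u > cum + 1e-15)), r)
        completed[[v]][miss] <- factor(
          levels(data[[v]])[pick],
          levels = levels(data[[v]])
        )
      }
    }
  })
  attr(completed, "diagnostics") <- list(n_fallback = n_fallback)
  attr(completed, "ground_truth") <- attr(data, "ground_truth")
  completed
}

#' Impute with chained equations, then learn the structure
#'
#' @param data data.frame of factors with `NA`s.
#' @param mice_cfg A [mice_config()].
#' @param score_cfg,search_cfg Scoring and search configurations.
#' @param seed Integer seed for the imputation stage.
#' @return A `learn_output` with the completed table attached.
#' @export
learn_with_mice <- function(data, mice_cfg = mice_config(),
                            score_cfg = score_config(),
                            search_cfg = search_config(), seed = 1) {
  completed <- mice_impute(data, mice_cfg, seed)
  net <- tabu_search(completed, score_cfg, search_cfg)
  learn_output(
    "mice", net, completed,
    diagnostics = attr(completed, "diagnostics")
  )
}
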