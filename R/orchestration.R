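# Factorial experiment runner: scenario grid enumeration, per-replicate
# execution (generate -> sample -> ampute -> learn x3 -> compare), and
# collation into a tidy results table.

#' Scenario grid for the simulation study
#'
#' Defaults reproduce the full factorial design: 19 variable counts x 6
#' missing proportions x 3 mechanisms x 3 sample sizes = 1026 scenarios,
#' each replicated 100 times (102,600 datasets).
#'
#' @param n_vars Integer vector of variable counts.
#' @param proportions Missing proportions.
#' @param mechanisms Subset of `c("MCAR", "MAR", "MNAR")`.
#' @param n_rows Sample sizes.
#' @param replicates Replicates per scenario.
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(n_vars = 2:20,
                          proportions = seq(0.1, 0.6, by = 0.1),
                          mechanisms = c("MCAR", "MAR", "MNAR"),
                          n_rows = c(1000, 5000, 10000),
                          replicates = 100, seed = 1) {
  stopifnot(
    length(n_vars) >= 1, length(proportions) >= 1,
    all(mechanisms %in% c("MCAR", "MAR", "MNAR")),
    length(n_rows) >= 1, replicates >= 1
  )
  structure(
    list(
      n_vars = n_vars, proportions = proportions,
      mechanisms = mechanisms, n_rows = n_rows,
      replicates = replicates, seed = seed
    ),
    class = "scenario_grid"
  )
}

#' A reduced grid small enough for routine testing
#'
#' @param replicates Replicates per scenario.
#' @param seed Master seed.
#' @return A `scenario_grid`.
#' @export
ci_grid <- function(replicates = 5, seed = 1) {
  scenario_grid(
    n_vars = c(5, 10), proportions = c(0.3, 0.5),
    mechanisms = c("MCAR", "MNAR"), n_rows = 1000,
    replicates = replicates, seed = seed
  )
}

#' Enumerate all scenarios of a grid
#'
#' Deterministic Cartesian product (variable count fastest, then
#' proportion, mechanism, sample size) with a derived base seed per
#' scenario.
#'
#' @param grid A [scenario_grid()].
#' @return data.frame with one row per scenario; attribute
#'   `"dataset_count"` gives scenarios x replicates.
#' @export
enumerate_scenarios <- function(grid) {
  sc <- expand.grid(
    n_vars = grid$n_vars, proportion = grid$proportions,
    mechanism = grid$mechanisms, n_rows = grid$n_rows,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sc$scenario_id <- seq_len(nrow(sc))
  sc$base_seed <- vapply(
    sc$scenario_id,
    function(i) derive_seed(grid$seed, "scenario", i),
    integer(1)
  )
  attr(sc, "dataset_count") <- nrow(sc) * grid$replicates
  attr(sc, "replicates") <- grid$replicates
  sc
}

#' Run one replicate of one scenario
#'
#' Executes the full simulation chain: generate a random DAG, attach random
#' CPTs, forward-sample the complete data, ampute it, then learn with all
#' three methods on the identical amputed table and compare each learned
#' skeleton with the generating structure. Hamming distances of the
#' completed tables are recorded for the two imputing methods.
#'
#' @param scenario One row of [enumerate_scenarios()] output (or a list
#'   with `n_vars`, `proportion`, `mechanism`, `n_rows`, `base_seed`).
#' @param replicate Replicate index.
#' @param score_cfg,search_cfg,sem_cfg,mice_cfg Method configurations.
#' @param methods Character subset of `c("none", "mice", "sem")`.
#' @return data.frame with one row per method (failed methods get `NA`
#'   metrics and an `error` string).
#' @export
run_replicate <- function(scenario, replicate,
                          score_cfg = score_config(),
                          search_cfg = search_config(),
                          sem_cfg = NULL, mice_cfg = mice_config(),
                          methods = c("none", "mice", "sem")) {
  if (is.null(sem_cfg)) {
    sem_cfg <- sem_config(score_cfg = score_cfg, search_cfg = search_cfg)
  }
  seed <- derive_seed(scenario$base_seed, "replicate", replicate)
  truth <- generate_random_dag(
    scenario$n_vars,
    max_in_degree = 3, n_levels = 3,
    seed = derive_seed(seed, "structure")
  )
  bn <- sample_cpts(truth, dirichlet_spec(), seed = derive_seed(seed, "cpts"))
  complete <- forward_sample(bn, scenario$n_rows, seed = derive_seed(seed, "rows"))
  spec <- missingness_spec(
    scenario$mechanism,
    proportion = scenario$proportion, vars = names(complete)
  )
  amputed <- ampute(complete, spec, seed = derive_seed(seed, "ampute"))
  mask <- missing_mask(amputed)

  one <- function(method) {
    res <- tryCatch(
      switch(method,
        none = learn_complete_cases(amputed, score_cfg, search_cfg),
        mice = learn_with_mice(
          amputed, mice_cfg, score_cfg, search_cfg,
          seed = derive_seed(seed, "mice")
        ),
        sem = structural_em(
          amputed, sem_cfg,
          seed = derive_seed(seed, "sem")
        )
      ),
      error = function(e) learn_output(
        method, NULL,
        diagnostics = list(error = conditionMessage(e))
      )
    )
    row <- data.frame(
      n_vars = scenario$n_vars, proportion = scenario$proportion,
      mechanism = scenario$mechanism, n_rows = scenario$n_rows,
      method = method, replicate = replicate, seed = seed,
      tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
      precision = NA_real_, recall = NA_real_, hamming = NA_integer_,
      error = NA_character_, stringsAsFactors = FALSE
    )
    if (is.null(res$network)) {
      row$error <- res$diagnostics$error
      return(row)
    }
    cmp <- compare_skeletons(res$network, truth)
    row$tp <- cmp$tp
    row$fp <- cmp$fp
    row$fn <- cmp$fn
    row$precision <- cmp$precision
    row$recall <- cmp$recall
    if (!is.null(res$completed)) {
      row$hamming <- hamming_distance(res$completed, complete, mask)
    }
    row
  }
  do.call(rbind, lapply(methods, one))
}

#' Run a whole scenario grid
#'
#' Loops over scenarios and replicates (seeds are pre-derived, so results
#' do not depend on execution order) and collates a tidy results table,
#' one row per method and replicate.
#'
#' @param grid A [scenario_grid()].
#' @param ... Passed to [run_replicate()].
#' @param progress Print a line per scenario.
#' @return Tidy data.frame of replicate results.
#' @export
run_grid <- function(grid, ..., progress = FALSE) {
  sc <- enumerate_scenarios(grid)
  out <- vector("list", nrow(sc) * grid$replicates)
  k <- 0L
  for (i in seq_len(nrow(sc))) {
    if (progress) {
      message(
        "scenario ", i, "/", nrow(sc), ": ",
        sc$n_vars[i], " vars, p=", sc$proportion[i], ", ",
        sc$mechanism[i], ", n=", sc$n_rows[i]
      )
    }
    for (r in seq_len(grid$replicates)) {
      k <- k + 1L
      out[[k]] <- run_replicate(sc[i, ], r, ...)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write replicate results as tidy CSV
#'
#' @param results data.frame from [run_grid()].
#' @param file Output path.
#' @export
write_results_csv <- function(results, file) {
  utils::write.csv(results, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Read and write categorical tables as CSV
#'
#' Missing cells are written as empty fields; the reader accepts both empty
#' fields and the literal `NA`.
#'
#' @param table data.frame of factors.
#' @param file Path.
#' @export
write_table_csv <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_table_csv
#' @param levels Optional named list fixing each column's level set (columns
#'   otherwise use the levels observed in the file, sorted).
#' @return `read_table_csv`: data.frame of factors.
#' @export
read_table_csv <- function(file, levels = NULL) {
  df <- utils::read.csv(
    file,
    stringsAsFactors = FALSE, na.strings = c("", "NA"),
    colClasses = "character"
  )
  for (nm in names(df)) {
    lv <- if (!is.null(levels) && nm %in% names(levels)) {
      levels[[nm]]
    } else {
      sort(unique(df[[nm]][!is.na(df[[nm]])]))
    }
    df[[nm]] <- factor(df[[nm]], levels = lv)
  }
  df
}
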