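# Evaluation of recovered structures and imputed values.
#
# Structures are compared as skeletons: a learned link counts as a true
# positive when the unordered pair exists in the reference network,
# regardless of orientation. Precision = TP / (TP + FP),
# recall = TP / (TP + FN). Imputation accuracy is the Hamming distance
# between the completed table and the pre-amputation original over the
# masked cells.

#' Compare two network skeletons
#'
#' @param learned,reference `bn_dag` objects over the same node set (or
#'   `pdag`s; orientations are discarded either way).
#' @return A `comparison_result` list: `tp`, `fp`, `fn`, `precision`,
#'   `recall`. Undefined ratios (zero denominator) are `NA`.
#' @export
compare_skeletons <- function(learned, reference) {
  nodes_of <- function(x) if (inherits(x, "pdag")) x$nodes else x$nodes
  if (!setequal(nodes_of(learned), nodes_of(reference))) {
    stop("node sets differ")
  }
  ls <- skeleton(learned)
  rs <- skeleton(reference)
  tp <- length(intersect(ls, rs))
  fp <- length(setdiff(ls, rs))
  fn <- length(setdiff(rs, ls))
  structure(
    list(
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(
    "Skeleton comparison: TP =", x$tp, " FP =", x$fp, " FN =", x$fn,
    "\n  precision =", signif(x$precision, 4),
    " recall =", signif(x$recall, 4), "\n"
  )
  invisible(x)
}

#' Hamming distance between completed and original tables
#'
#' Counts the masked cells whose imputed value differs from the original
#' value. Cells outside the mask are required to agree (imputation never
#' alters observed data), so they contribute zero.
#'
#' @param imputed Completed data.frame.
#' @param original Complete ground-truth data.frame of the same shape.
#' @param mask Logical matrix (`TRUE` = cell was missing). When `NULL`,
#'   every cell is compared — equivalent under the soundness invariant that
#'   imputation never alters observed cells.
#' @return Integer count.
#' @export
hamming_distance <- function(imputed, original, mask = NULL) {
  if (!all(dim(imputed) == dim(original))) stop("shape mismatch")
  if (anyNA(imputed)) stop("imputed table still has missing cells")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(imputed), ncol(imputed))
  }
  a <- as.matrix(as.data.frame(lapply(imputed, as.character)))
  b <- as.matrix(as.data.frame(lapply(original, as.character)))
  sum(a[mask] != b[mask])
}

#' Variable-count groups used for aggregation
#'
#' The six groups partition 2..20 variables.
#'
#' @param n_vars Integer vector of variable counts.
#' @return Factor with levels `2-5`, `6-8`, `9-11`, `12-14`, `15-17`,
#'   `18-20`.
#' @export
variable_group <- function(n_vars) {
  cut(
    n_vars,
    breaks = c(1, 5, 8, 11, 14, 17, 20),
    labels = c("2-5", "6-8", "9-11", "12-14", "15-17", "18-20")
  )
}

#' Aggregate replicate results and run the comparison tests
#'
#' For every (variable group x missing proportion x sample size x mechanism)
#' cell: per-method means and standard errors of precision and recall; a
#' one-way ANOVA across methods; Bonferroni correction of the ANOVA p-values
#' across all cells in the same (metric, sample size, mechanism) panel; and
#' Tukey HSD pairwise comparisons wherever the corrected p-value is below
#' `alpha`. Hamming distances, where present, are compared between SEM and
#' MICE by Student's t-test. Replicates with undefined precision are
#' excluded from that metric, with exclusion counts reported.
#'
#' @param results data.frame with columns `n_vars`, `proportion`,
#'   `mechanism`, `n_rows`, `method`, `replicate`, `precision`, `recall`
#'   and optionally `hamming`.
#' @param alpha Significance level for running post-hoc tests.
#' @return List with `cell_summary`, `anova`, `tukey`, `hamming_tests` and
#'   `exclusions` data.frames.
#' @export
aggregate_and_test <- function(results, alpha = 0.05) {
  stopifnot(all(c(
    "n_vars", "proportion", "mechanism", "n_rows", "method",
    "precision", "recall"
  ) %in% names(results)))
  results$group <- variable_group(results$n_vars)
  cell_key <- c("group", "proportion", "n_rows", "mechanism")

  summarise_metric <- function(metric) {
    ok <- !is.na(results[[metric]])
    d <- results[ok, , drop = FALSE]
    agg <- stats::aggregate(
      d[[metric]],
      by = d[c(cell_key, "method")],
      FUN = function(v) {
        c(
          mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
          n = length(v)
        )
      }
    )
    out <- cbind(agg[c(cell_key, "method")], as.data.frame(agg$x))
    out$metric <- metric
    out
  }
  cell_summary <- rbind(summarise_metric("precision"), summarise_metric("recall"))

  run_anova <- function(metric) {
    ok <- !is.na(results[[metric]])
    d <- results[ok, , drop = FALSE]
    cells <- unique(d[cell_key])
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- d$group == cells$group[i] &
        d$proportion == cells$proportion[i] &
        d$n_rows == cells$n_rows[i] &
        d$mechanism == cells$mechanism[i]
      sub <- d[sel, , drop = FALSE]
      if (length(unique(sub$method)) < 2) return(NULL)
      fit <- stats::aov(sub[[metric]] ~ factor(sub$method))
      sm <- summary(fit)[[1]]
      data.frame(
        cells[i, , drop = FALSE],
        metric = metric,
        f_value = sm$`F value`[1],
        p_raw = sm$`Pr(>F)`[1],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  }
  anova_tab <- rbind(run_anova("precision"), run_anova("recall"))
  if (!is.null(anova_tab) && nrow(anova_tab)) {
    # Bonferroni family: cells within one (metric, n_rows, mechanism) panel
    panel <- interaction(
      anova_tab$metric, anova_tab$n_rows, anova_tab$mechanism
    )
    anova_tab$p_bonferroni <- NA_real_
    for (pl in unique(panel)) {
      sel <- panel == pl
      anova_tab$p_bonferroni[sel] <- stats::p.adjust(
        anova_tab$p_raw[sel],
        method = "bonferroni"
      )
    }
  }

  tukey_rows <- list()
  if (!is.null(anova_tab) && nrow(anova_tab)) {
    sig <- which(!is.na(anova_tab$p_bonferroni) &
      anova_tab$p_bonferroni < alpha)
    for (i in sig) {
      metric <- anova_tab$metric[i]
      sel <- !is.na(results[[metric]]) &
        results$group == anova_tab$group[i] &
        results$proportion == anova_tab$proportion[i] &
        results$n_rows == anova_tab$n_rows[i] &
        results$mechanism == anova_tab$mechanism[i]
      sub <- results[sel, , drop = FALSE]
      fit <- stats::aov(sub[[metric]] ~ factor(sub$method))
      tk <- stats::TukeyHSD(fit)[[1]]
      tukey_rows[[length(tukey_rows) + 1]] <- data.frame(
        anova_tab[i, c(cell_key, "metric"), drop = FALSE],
        comparison = rownames(tk),
        diff = tk[, "diff"],
        p_adj = tk[, "p adj"],
        row.names = NULL
      )
    }
  }
  tukey_tab <- if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL

  hamming_tab <- NULL
  if ("hamming" %in% names(results) && any(!is.na(results$hamming))) {
    d <- results[!is.na(results$hamming), , drop = FALSE]
    cells <- unique(d[c("n_vars", "proportion", "n_rows", "mechanism")])
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sel <- d$n_vars == cells$n_vars[i] &
        d$proportion == cells$proportion[i] &
        d$n_rows == cells$n_rows[i] &
        d$mechanism == cells$mechanism[i]
      sub <- d[sel, , drop = FALSE]
      sem <- sub$hamming[sub$method == "sem"]
      mice <- sub$hamming[sub$method == "mice"]
      if (length(sem) < 2 || length(mice) < 2) return(NULL)
      tt <- stats::t.test(sem, mice)
      data.frame(
        cells[i, , drop = FALSE],
        mean_sem = mean(sem), mean_mice = mean(mice),
        t = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE
      )
    })
    hamming_tab <- do.call(rbind, Filter(Negate(is.null), rows))
  }

  exclusions <- data.frame(
    metric = c("precision", "recall"),
    n_excluded = c(
      sum(is.na(results$precision)), sum(is.na(results$recall))
    )
  )

  list(
    cell_summary = cell_summary, anova = anova_tab, tukey = tukey_tab,
    hamming_tests = hamming_tab, exclusions = exclusions
  )
}
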