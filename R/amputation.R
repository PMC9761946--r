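# Multivariate amputation of complete categorical tables.
#
# Rows are assigned to missingness patterns by a multinomial draw over the
# pattern frequency vector; within each pattern subset rows become incomplete
# with a probability that is constant under MCAR and a logistic function of a
# standardized weighted-sum score under MAR/MNAR, calibrated by bisection so
# the expected incomplete-row fraction equals the target proportion.

#' Missingness specification
#'
#' Defaults reproduce the canonical multivariate-amputation setup: one
#' pattern per variable (pattern i removes exactly variable i), uniform
#' pattern frequencies, and mechanism-specific weight matrices — under MAR
#' every variable except the missing one contributes to the weighted-sum
#' score; under MNAR only the to-be-removed variable's own value does.
#'
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param proportion Target fraction of incomplete rows, in `[0, 1]`.
#' @param vars Character vector of variable names the spec applies to.
#' @param patterns Optional binary matrix (`n_patterns x n_vars`, 1 =
#'   variable missing in that pattern). Default: identity.
#' @param freq Optional probability vector over patterns. Default: uniform.
#' @param weights Optional weight matrix (same shape as `patterns`).
#'   Defaults depend on the mechanism as described above.
#' @return A `missingness_spec` list.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             proportion = 0.3, vars,
                             patterns = NULL, freq = NULL, weights = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(proportion >= 0, proportion <= 1, is.character(vars))
  p <- length(vars)
  if (is.null(patterns)) {
    patterns <- diag(1L, p)
    colnames(patterns) <- vars
  }
  patterns <- as.matrix(patterns)
  if (is.null(colnames(patterns))) colnames(patterns) <- vars
  stopifnot(
    ncol(patterns) == p, all(patterns %in% c(0, 1)),
    all(rowSums(patterns) >= 1)
  )
  k <- nrow(patterns)
  if (is.null(freq)) freq <- rep(1 / k, k)
  stopifnot(length(freq) == k, all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-12) stop("freq must sum to 1")
  if (is.null(weights)) {
    weights <- switch(mechanism,
      MCAR = matrix(0, k, p, dimnames = list(NULL, vars)),
      MAR = 1 - patterns, # observed variables drive missingness
      MNAR = patterns # the removed value drives its own missingness
    )
  }
  weights <- as.matrix(weights)
  stopifnot(all(dim(weights) == dim(patterns)))
  colnames(weights) <- vars
  structure(
    list(
      mechanism = mechanism, proportion = proportion, vars = vars,
      patterns = patterns, freq = freq, weights = weights
    ),
    class = "missingness_spec"
  )
}

#' Weighted-sum scores of rows
#'
#' Categories are encoded as integer codes `0..k-1` in declared level order;
#' each column is standardized to zero mean, unit variance, and the score of
#' a row is the weighted sum of its standardized codes. Zero-variance columns
#' contribute 0.
#'
#' @param table Complete data.frame of factors.
#' @param weights_row Numeric weight per column (recycled names not used;
#'   positional).
#' @return Numeric vector, one score per row.
#' @export
weighted_sum_scores <- function(table, weights_row) {
  stopifnot(!anyNA(table), length(weights_row) == ncol(table))
  z <- vapply(seq_along(table), function(j) {
    v <- as.numeric(as.integer(table[[j]]) - 1L)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(nrow(table)))
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(table))
  as.numeric(z %*% weights_row)
}

#' Map scores to removal probabilities at a target mean
#'
#' Right-tailed logistic allocation: `p_r = plogis(shift + z(score_r))`
#' where `z` standardizes the scores and the shift is solved by bisection so
#' that `mean(p) = target_proportion` within `1e-6`. Rows with higher scores
#' therefore have higher removal probability. With constant scores the
#' probabilities are exactly the target proportion.
#'
#' @param scores Numeric score vector.
#' @param target_proportion Desired mean probability, in `[0, 1]`.
#' @param max_iter Bisection iteration cap.
#' @return Probability vector of the same length.
#' @export
score_to_probability <- function(scores, target_proportion, max_iter = 200) {
  stopifnot(target_proportion >= 0, target_proportion <= 1)
  n <- length(scores)
  if (target_proportion %in% c(0, 1)) {
    return(rep(target_proportion, n))
  }
  s <- stats::sd(scores)
  z <- if (!is.finite(s) || s < 1e-12) {
    rep(0, n)
  } else {
    (scores - mean(scores)) / s
  }
  f <- function(shift) mean(stats::plogis(shift + z)) - target_proportion
  lo <- -40
  hi <- 40
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  p <- stats::plogis((lo + hi) / 2 + z)
  if (abs(mean(p) - target_proportion) > 1e-6) {
    stop(
      "probability calibration did not converge: mean ", mean(p),
      " vs target ", target_proportion
    )
  }
  p
}

#' Introduce missing values into a complete table
#'
#' @param table Complete data.frame of factors (no `NA`s).
#' @param spec A [missingness_spec()].
#' @param seed Integer seed.
#' @return The table with `NA`s in the amputed cells. The complete original
#'   is retained in an attribute for ground-truth evaluation; use
#'   [ground_truth()] and [missing_mask()] to access it.
#' @export
ampute <- function(table, spec, seed = 1) {
  stopifnot(is.data.frame(table), inherits(spec, "missingness_spec"))
  if (anyNA(table)) stop("table already contains missing cells")
  if (!all(spec$vars %in% names(table))) stop("spec vars not in table")
  n <- nrow(table)
  k <- nrow(spec$patterns)
  out <- table
  with_seed(derive_seed(seed, "ampute"), {
    pattern_of <- sample.int(k, n, replace = TRUE, prob = spec$freq)
    for (pi in seq_len(k)) {
      rows <- which(pattern_of == pi)
      if (!length(rows)) next
      p <- if (spec$mechanism == "MCAR") {
        rep(spec$proportion, length(rows))
      } else {
        sc <- weighted_sum_scores(
          table[rows, spec$vars, drop = FALSE],
          spec$weights[pi, ]
        )
        score_to_probability(sc, spec$proportion)
      }
      hit <- stats::runif(length(rows)) < p
      miss_vars <- spec$vars[spec$patterns[pi, ] == 1]
      for (v in miss_vars) out[rows[hit], v] <- NA
    }
  })
  attr(out, "ground_truth") <- table
  out
}

#' Ground truth behind an amputed table
#'
#' Privileged accessor for evaluation code: returns the complete table that
#' [ampute()] started from.
#'
#' @param table An amputed data.frame.
#' @return The complete original data.frame.
#' @export
ground_truth <- function(table) {
  gt <- attr(table, "ground_truth")
  if (is.null(gt)) stop("table carries no ground truth")
  gt
}

#' Missingness mask of a table
#'
#' @param table A data.frame.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) {
  m <- is.na(as.matrix(table))
  dimnames(m) <- list(NULL, names(table))
  m
}

#' Serialise a missingness specification
#'
#' @param spec A [missingness_spec()].
#' @param file Output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @export
write_missingness_spec <- function(spec, file) {
  obj <- list(
    mechanism = spec$mechanism, proportion = spec$proportion,
    vars = spec$vars,
    patterns = apply(spec$patterns, 1, as.integer, simplify = FALSE),
    freq = spec$freq,
    weights = apply(spec$weights, 1, as.numeric, simplify = FALSE)
  )
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(obj, file)
  } else {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a missingness specification
#'
#' @param file Path written by [write_missingness_spec()].
#' @return A `missingness_spec`.
#' @export
read_missingness_spec <- function(file) {
  obj <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  to_mat <- function(x) {
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  # serialisation may round the frequencies; renormalise small drift
  freq <- as.numeric(obj$freq)
  if (abs(sum(freq) - 1) > 1e-12 && abs(sum(freq) - 1) < 1e-4) {
    freq <- freq / sum(freq)
  }
  obj$freq <- freq
  missingness_spec(
    mechanism = obj$mechanism, proportion = obj$proportion,
    vars = obj$vars,
    patterns = to_mat(obj$patterns), freq = obj$freq,
    weights = to_mat(obj$weights)
  )
}
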