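test_that("weighted sum scores match manual standardize-and-sum arithmetic", {
  tab <- data.frame(
    A = factor(c("a", "b", "b"), levels = c("a", "b")),
    B = factor(c("x", "x", "y"), levels = c("x", "y"))
  )
  # codes A: 0,1,1; B: 0,0,1; z-scores via sd()
  za <- (c(0, 1, 1) - 2 / 3) / sd(c(0, 1, 1))
  zb <- (c(0, 0, 1) - 1 / 3) / sd(c(0, 0, 1))
  expect_equal(weighted_sum_scores(tab, c(1, 1)), za + zb)
  expect_equal(weighted_sum_scores(tab, c(0, 0)), c(0, 0, 0))
  expect_equal(weighted_sum_scores(tab, c(0, 1)), zb)
  # zero-variance column contributes nothing
  tab$C <- factor(rep("u", 3))
  expect_equal(weighted_sum_scores(tab, c(0, 0, 1)), c(0, 0, 0))
})

test_that("score-to-probability calibration hits the target mean and is monotone", {
  set.seed(4)
  for (target in c(0.1, 0.3, 0.6)) {
    sc <- rnorm(500)
    p <- score_to_probability(sc, target)
    expect_lt(abs(mean(p) - target), 1e-6)
    expect_true(all(diff(p[order(sc)]) >= -1e-12))
  }
  expect_equal(score_to_probability(rep(2, 7), 0.25), rep(0.25, 7))
  expect_equal(score_to_probability(rnorm(5), 0), rep(0, 5))
})

test_that("amputation respects the proportion and never alters observed values", {
  rt <- random_table(5, 10000, seed = 21)
  tab <- rt$data
  for (mech in c("MCAR", "MAR", "MNAR")) {
    spec <- missingness_spec(mech, 0.3, vars = names(tab))
    am <- ampute(tab, spec, seed = 31)
    frac <- mean(!stats::complete.cases(am))
    se <- sqrt(0.3 * 0.7 / 10000)
    expect_lt(abs(frac - 0.3), 4 * se)
    mask <- missing_mask(am)
    expect_identical(
      as.character(unlist(am)[!as.vector(mask)]),
      as.character(unlist(tab)[!as.vector(mask)])
    )
    expect_identical(ground_truth(am), tab)
    # uniform pattern frequencies split missingness equally over variables
    percol <- colMeans(mask)
    expect_true(all(abs(percol - 0.3 / 5) < 4 * sqrt(0.06 * 0.94 / 10000) + 0.01))
  }
  expect_error(ampute(ampute(tab, spec, seed = 1), spec), "missing")
})

test_that("zero proportion is a no-op", {
  rt <- random_table(3, 200, seed = 5)
  spec <- missingness_spec("MNAR", 0, vars = names(rt$data))
  am <- ampute(rt$data, spec, seed = 9)
  expect_equal(sum(missing_mask(am)), 0)
  expect_identical(am$X1, rt$data$X1)
})

test_that("MCAR missingness is independent of values; MNAR is not", {
  rt <- random_table(4, 4000, seed = 8)
  tab <- rt$data
  p_mcar <- numeric(100)
  p_mnar <- numeric(100)
  for (s in 1:100) {
    for (mech in c("MCAR", "MNAR")) {
      spec <- missingness_spec(mech, 0.3, vars = names(tab))
      am <- ampute(tab, spec, seed = 1000 + s)
      mask <- missing_mask(am)
      # test the first column's missingness against its own true values
      pv <- suppressWarnings(
        stats::chisq.test(table(mask[, 1], tab[[1]]))$p.value
      )
      if (mech == "MCAR") p_mcar[s] <- pv else p_mnar[s] <- pv
    }
  }
  expect_gte(sum(p_mcar > 0.01), 95)
  expect_gt(sum(p_mnar < 0.01), 50)
})

test_that("MAR: missingness depends on other columns, not the hidden one", {
  # B's missingness is driven by A's (observed) value under MAR
  tab <- dependent_pair(20000, seed = 3, flip = 0.6)
  spec <- missingness_spec(
    "MAR", 0.4,
    vars = names(tab),
    patterns = matrix(c(0, 1), 1, 2), freq = 1
  )
  am <- ampute(tab, spec, seed = 77)
  mask <- missing_mask(am)
  p_other <- suppressWarnings(
    stats::chisq.test(table(mask[, "B"], tab$A))$p.value
  )
  expect_lt(p_other, 1e-4)
  # conditional on A, missingness of B carries no information about B
  fit <- stats::glm(
    mask[, "B"] ~ tab$A + tab$B,
    family = binomial()
  )
  fit0 <- stats::glm(mask[, "B"] ~ tab$A, family = binomial())
  lr_p <- stats::pchisq(
    fit0$deviance - fit$deviance,
    df = 2, lower.tail = FALSE
  )
  expect_gt(lr_p, 0.01)
})

test_that("missingness specs round-trip through YAML and JSON", {
  spec <- missingness_spec("MNAR", 0.25, vars = c("A", "B", "C"))
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_missingness_spec(spec, f)
    back <- read_missingness_spec(f)
    expect_equal(back$mechanism, spec$mechanism)
    expect_equal(back$proportion, spec$proportion)
    expect_equal(unname(back$patterns), unname(spec$patterns))
    expect_equal(back$freq, spec$freq)
    expect_equal(unname(back$weights), unname(spec$weights))
  }
})
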