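test_that("complete-case learning drops exactly the incomplete rows", {
  rt <- random_table(4, 10, seed = 61)
  tab <- rt$data
  tab$X1[1:2] <- NA
  tab$X3[c(2, 5, 7)] <- NA # 4 distinct incomplete rows
  out <- learn_complete_cases(tab)
  expect_equal(out$diagnostics$n_used, 6)
  # no missing cells: identical to a direct tabu run
  full <- random_table(4, 400, seed = 62)
  direct <- tabu_search(full$data)
  via_cc <- learn_complete_cases(full$data)
  expect_identical(dag_edges(via_cc$network), dag_edges(direct))
})

test_that("zero complete rows is a recorded failure, not a crash", {
  tab <- data.frame(
    A = factor(c("a", NA), levels = c("a", "b")),
    B = factor(c(NA, "b"), levels = c("a", "b"))
  )
  out <- learn_complete_cases(tab)
  expect_null(out$network)
  expect_match(out$diagnostics$error, "complete")
})

test_that("parents-based imputation takes the conditional mode in topological order", {
  fit <- chain_ab(
    p_a = c(0.5, 0.5),
    p_b_given_a = rbind(c(0.1, 0.9), c(0.7, 0.3))
  )
  tab <- forward_sample(fit, 6, seed = 2)
  tab$A[1:6] <- factor("a1", levels = c("a1", "a2"))
  tab$B[1:3] <- NA
  out <- impute_from_parents(tab, fit)
  expect_true(all(out$B[1:3] == "b2")) # argmax of (0.1, 0.9)
  expect_identical(out$B[4:6], tab$B[4:6])

  # tie on a parentless marginal resolves to the lowest level index
  tie <- fit
  tie$cpts$A <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a1", "a2")))
  tab2 <- tab
  tab2$A[1] <- NA
  out2 <- impute_from_parents(tab2, tie)
  expect_equal(as.character(out2$A[1]), "a1")

  # fully missing row in a chain: parent filled first, child follows it
  tab3 <- forward_sample(fit, 3, seed = 4)
  tab3$A[1] <- NA
  tab3$B[1] <- NA
  out3 <- impute_from_parents(tab3, fit)
  expect_false(anyNA(out3))
  mode_a <- c("a1", "a2")[which.max(fit$cpts$A[1, ])]
  expect_equal(as.character(out3$A[1]), mode_a)
  row_b <- fit$cpts$B[which(c("a1", "a2") == mode_a), ]
  expect_equal(as.character(out3$B[1]), names(which.max(row_b))[1])
})

test_that("chained-equation imputation is sound and learns strong dependence", {
  set.seed(9)
  n <- 1000
  lv <- c("a", "b")
  x <- factor(sample(lv, n, TRUE), levels = lv)
  df <- data.frame(x = x, y = x)
  spec <- missingness_spec(
    "MCAR", 0.3,
    vars = c("x", "y"),
    patterns = matrix(c(0, 1), 1, 2), freq = 1
  )
  am <- ampute(df, spec, seed = 3)
  mask <- missing_mask(am)
  comp <- mice_impute(am, seed = 4)
  expect_false(anyNA(comp))
  expect_identical(comp$x, df$x)
  expect_identical(comp$y[!mask[, "y"]], df$y[!mask[, "y"]])
  # deterministic dependence: imputations should almost always be right
  expect_gte(mean(comp$y[mask[, "y"]] == df$y[mask[, "y"]]), 0.9)
  # complete input returned unchanged
  expect_identical(mice_impute(df, seed = 5), df)
})

test_that("degenerate conditional fits fall back to the observed marginal", {
  # one observed level only: the model cannot be fitted
  tab <- data.frame(
    A = factor(rep("a", 50), levels = c("a", "b")),
    B = factor(sample(c("x", "y"), 50, TRUE), levels = c("x", "y"))
  )
  tab$A[1:10] <- NA
  comp <- mice_impute(tab, seed = 6)
  expect_false(anyNA(comp))
  expect_true(all(comp$A == "a"))
  expect_gte(attr(comp, "diagnostics")$n_fallback, 1)
})

test_that("structural EM on complete data equals a single tabu run", {
  rt <- random_table(5, 400, seed = 71)
  direct <- tabu_search(rt$data)
  sem <- structural_em(rt$data, sem_config(), seed = 1)
  expect_identical(dag_edges(sem$network), dag_edges(direct))
  expect_equal(sem$diagnostics$iterations, 2) # second pass confirms no change
})

test_that("structural EM completes the data without touching observed cells", {
  rt <- random_table(6, 600, seed = 72)
  spec <- missingness_spec("MCAR", 0.3, vars = names(rt$data))
  am <- ampute(rt$data, spec, seed = 5)
  mask <- missing_mask(am)
  sem <- structural_em(am, sem_config(), seed = 2)
  expect_false(anyNA(sem$completed))
  for (j in names(am)) {
    obs <- !mask[, j]
    expect_identical(sem$completed[[j]][obs], am[[j]][obs])
  }
  expect_true(all(diff(sem$diagnostics$trace$iteration) == 1))
})

test_that("structural EM rejects never-observed variables", {
  tab <- data.frame(
    A = factor(c(NA, NA), levels = c("a", "b")),
    B = factor(c("a", "b"), levels = c("a", "b"))
  )
  expect_error(structural_em(tab), "never observed")
})

test_that("learning through imputation equals direct search on complete input", {
  rt <- random_table(4, 300, seed = 73)
  direct <- tabu_search(rt$data)
  via <- learn_with_mice(rt$data, seed = 3)
  expect_identical(dag_edges(via$network), dag_edges(direct))
  expect_false(anyNA(via$completed))
})

test_that("all three learners agree at near-zero missingness", {
  rt <- random_table(5, 4000, seed = 74)
  spec <- missingness_spec("MCAR", 0.01, vars = names(rt$data))
  am <- ampute(rt$data, spec, seed = 7)
  none <- learn_complete_cases(am)
  mice <- learn_with_mice(am, seed = 8)
  sem <- structural_em(am, seed = 9)
  expect_identical(skeleton(none$network), skeleton(mice$network))
  expect_identical(skeleton(none$network), skeleton(sem$network))
})

test_that("imputation improves structure recovery on a planted network", {
  # scaled-down check of the headline ordering at a harsh missingness level
  wins <- 0L
  n_trials <- 12
  for (s in seq_len(n_trials)) {
    truth <- generate_random_dag(5, seed = 900 + s)
    bn <- sample_cpts(truth, seed = 901 + s)
    tab <- forward_sample(bn, 1000, seed = 902 + s)
    spec <- missingness_spec("MCAR", 0.3, vars = names(tab))
    am <- ampute(tab, spec, seed = 903 + s)
    cc <- learn_complete_cases(am)
    sem <- suppressMessages(structural_em(am, seed = 904 + s))
    r_cc <- compare_skeletons(cc$network, truth)$recall
    r_sem <- compare_skeletons(sem$network, truth)$recall
    if (!is.na(r_sem) && !is.na(r_cc) && r_sem >= r_cc) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.7 * n_trials))
})
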