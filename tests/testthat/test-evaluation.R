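test_that("skeleton comparison obeys the precision/recall definitions", {
  ref <- bn_dag(
    LETTERS[1:4],
    parents = list(B = "A", C = "B")
  )
  same <- compare_skeletons(ref, ref)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  expect_equal(same$fp + same$fn, 0)

  learned <- bn_dag(
    LETTERS[1:4],
    parents = list(B = "A", D = "C")
  )
  cmp <- compare_skeletons(learned, ref)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn), c(1, 1, 1))
  expect_equal(cmp$precision, 0.5)
  expect_equal(cmp$recall, 0.5)
  expect_equal(cmp$tp + cmp$fn, length(skeleton(ref)))

  empty <- bn_dag(LETTERS[1:4])
  cmp0 <- compare_skeletons(empty, ref)
  expect_equal(cmp0$recall, 0)
  expect_true(is.na(cmp0$precision))
  expect_error(
    compare_skeletons(bn_dag(c("A", "B")), ref),
    "node sets"
  )

  # direction never matters
  fwd <- bn_dag(c("A", "B"), parents = list(B = "A"))
  bwd <- bn_dag(c("A", "B"), parents = list(A = "B"))
  expect_equal(compare_skeletons(fwd, bwd)$precision, 1)
})

test_that("Hamming distance counts disagreeing masked cells", {
  orig <- data.frame(
    A = factor(c("a", "b", "a", "b")),
    B = factor(c("x", "x", "y", "y"))
  )
  mask <- matrix(FALSE, 4, 2)
  mask[1, 1] <- mask[2, 1] <- mask[3, 2] <- TRUE
  imput <- orig
  imput$A[1] <- "b" # one wrong cell
  expect_equal(hamming_distance(imput, orig, mask), 1)
  expect_equal(hamming_distance(orig, orig, mask), 0)
  all_wrong <- orig
  all_wrong$A[1:2] <- c("b", "a")
  all_wrong$B[3] <- "x"
  expect_equal(hamming_distance(all_wrong, orig, mask), 3)
  expect_equal(
    hamming_distance(all_wrong, orig, mask),
    hamming_distance(orig, all_wrong, mask)
  )
  expect_error(hamming_distance(orig[1:3, ], orig, mask), "shape")
})

test_that("variable groups partition 2..20", {
  g <- variable_group(2:20)
  expect_false(anyNA(g))
  expect_equal(
    as.vector(table(g)),
    c(4, 3, 3, 3, 3, 3)
  )
  expect_equal(as.character(variable_group(c(2, 5, 6, 20))),
    c("2-5", "2-5", "6-8", "18-20"))
})

fake_results <- function(mean_by_method, n = 100, sd = 0.02, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(mean_by_method), function(m) {
    data.frame(
      n_vars = 10, proportion = 0.3, mechanism = "MCAR", n_rows = 1000,
      method = m, replicate = seq_len(n),
      precision = pmin(1, pmax(0, rnorm(n, mean_by_method[[m]], sd))),
      recall = pmin(1, pmax(0, rnorm(n, mean_by_method[[m]], sd))),
      hamming = NA_real_
    )
  }))
}

test_that("identical methods yield a null ANOVA and no pairwise tests", {
  res <- fake_results(list(none = 0.7, mice = 0.7, sem = 0.7), sd = 1e-6)
  rep <- aggregate_and_test(res)
  expect_true(all(rep$anova$p_bonferroni > 0.05))
  expect_null(rep$tukey)
})

test_that("a planted method difference is detected by ANOVA and Tukey", {
  res <- fake_results(list(none = 0.5, mice = 0.5, sem = 0.9))
  rep <- aggregate_and_test(res)
  expect_true(all(rep$anova$p_bonferroni < 0.05))
  expect_false(is.null(rep$tukey))
  sig <- rep$tukey[rep$tukey$p_adj < 0.05, "comparison"]
  expect_true(all(grepl("sem", sig)))
  expect_false(any(grepl("^none-mice$|^mice-none$", sig)))
  # Bonferroni here multiplies by the number of cells in the panel (1)
  expect_equal(rep$anova$p_bonferroni, pmin(1, rep$anova$p_raw))
})

test_that("undefined precision is excluded and counted", {
  res <- fake_results(list(none = 0.6, mice = 0.6, sem = 0.6))
  res$precision[1:5] <- NA
  rep <- aggregate_and_test(res)
  excl <- rep$exclusions
  expect_equal(excl$n_excluded[excl$metric == "precision"], 5)
  cs <- rep$cell_summary
  n_prec <- cs$n[cs$metric == "precision" & cs$method == "none"]
  expect_equal(n_prec, 95)
})

test_that("Hamming t-tests compare the two imputing methods", {
  res <- fake_results(list(mice = 0.6, sem = 0.6), n = 30)
  set.seed(2)
  res$hamming <- ifelse(res$method == "sem", rnorm(60, 100, 5), rnorm(60, 150, 5))
  rep <- aggregate_and_test(res)
  expect_false(is.null(rep$hamming_tests))
  expect_lt(rep$hamming_tests$p_value[1], 1e-6)
  expect_lt(rep$hamming_tests$mean_sem[1], rep$hamming_tests$mean_mice[1])
})

test_that("aggregation is a pure function of its input", {
  res <- fake_results(list(none = 0.5, mice = 0.6, sem = 0.7))
  a <- aggregate_and_test(res)
  b <- aggregate_and_test(res)
  expect_identical(a$anova, b$anova)
  expect_identical(a$cell_summary, b$cell_summary)
})
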