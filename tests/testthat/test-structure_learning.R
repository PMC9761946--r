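test_that("BDe family score matches the closed-form Gamma expression", {
  tab <- data.frame(
    A = factor(rep(c("0", "1"), each = 5), levels = c("0", "1"))
  )
  got <- family_score("A", character(0), tab, score_config("BDe", 1))
  want <- lgamma(1) - lgamma(11) + lgamma(5.5) + lgamma(5.5) - 2 * lgamma(0.5)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("network scores decompose over families", {
  rt <- random_table(5, 300, seed = 31)
  for (sn in c("BDe", "BDs", "BIC")) {
    cfg <- score_config(sn)
    total <- network_score(rt$dag, rt$data, cfg)
    by_family <- sum(vapply(
      rt$dag$nodes,
      function(nm) family_score(nm, rt$dag$parents[[nm]], rt$data, cfg),
      numeric(1)
    ))
    expect_equal(total, by_family, tolerance = 1e-12)
  }
})

test_that("BDe is score-equivalent across Markov-equivalent DAGs", {
  tab <- dependent_pair(400, seed = 2)
  cfg <- score_config("BDe", 1)
  ab <- parse_modelstring("[A][B|A]", table_levels(tab))
  ba <- parse_modelstring("[B][A|B]", table_levels(tab))
  expect_equal(
    network_score(ab, tab, cfg), network_score(ba, tab, cfg),
    tolerance = 1e-9
  )
  # all three orientations of a chain on sampled 3-node data
  rt <- random_table(3, 500, seed = 6)
  chains <- c("[X1][X2|X1][X3|X2]", "[X2][X1|X2][X3|X2]", "[X3][X2|X3][X1|X2]")
  scores <- vapply(
    chains,
    function(s) {
      network_score(
        parse_modelstring(s, table_levels(rt$data)), rt$data, cfg
      )
    },
    numeric(1)
  )
  expect_lt(max(scores) - min(scores), 1e-9)
})

test_that("BIC uses log-likelihood minus log(n)/2 per free parameter", {
  tab <- dependent_pair(300, seed = 9)
  n <- nrow(tab)
  counts <- table(tab$A)
  ll <- sum(counts * log(counts / n))
  want <- ll - 0.5 * log(n) * 2 # 3 levels -> 2 free parameters
  expect_equal(
    family_score("A", character(0), tab, score_config("BIC")),
    want,
    tolerance = 1e-9
  )
})

test_that("BDs restricts the prior to observed parent configurations", {
  # parent level "c" never observed: BDs spreads iss over 2 configs, BDe over 3
  tab <- data.frame(
    P = factor(c("a", "a", "b", "b"), levels = c("a", "b", "c")),
    C = factor(c("x", "y", "x", "y"), levels = c("x", "y"))
  )
  bde <- family_score("C", "P", tab, score_config("BDe", 1))
  bds <- family_score("C", "P", tab, score_config("BDs", 1))
  manual_bds <- 2 * (lgamma(1 / 2) - lgamma(1 / 2 + 2)) +
    4 * (lgamma(1 / 4 + 1) - lgamma(1 / 4))
  expect_equal(bds, manual_bds, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(bde, bds)))
})

test_that("tabu search finds the exhaustive optimum on 3-variable problems", {
  for (s in 1:50) {
    rt <- random_table(3, 200, seed = 100 + s)
    net <- tabu_search(rt$data)
    oracle <- exhaustive_search(rt$data)
    expect_equal(attr(net, "score"), attr(oracle, "score"), tolerance = 1e-9)
  }
})

test_that("tabu search recovers a strong dependence and is no worse than empty", {
  tab <- dependent_pair(10000, seed = 12, flip = 0.05)
  net <- tabu_search(tab)
  expect_equal(skeleton(net), "A--B")
  empty_score <- network_score(
    bn_dag(names(tab), levels = table_levels(tab)), tab, score_config()
  )
  expect_gte(attr(net, "score"), empty_score)
})

test_that("independent variables yield the empty graph", {
  set.seed(33)
  n <- 5000
  lv <- c("a", "b", "c")
  tab <- data.frame(
    X = factor(sample(lv, n, TRUE), levels = lv),
    Y = factor(sample(lv, n, TRUE), levels = lv),
    Z = factor(sample(lv, n, TRUE), levels = lv)
  )
  net <- tabu_search(tab)
  oracle <- exhaustive_search(tab)
  expect_equal(n_edges(net), 0)
  expect_equal(n_edges(oracle), 0)
})

test_that("tabu search refuses missing cells and is deterministic", {
  rt <- random_table(4, 300, seed = 41)
  tab <- rt$data
  n1 <- tabu_search(tab)
  n2 <- tabu_search(tab)
  expect_identical(dag_edges(n1), dag_edges(n2))
  tab$X1[1] <- NA
  expect_error(tabu_search(tab), "missing")
})

test_that("memoised family scores agree with direct recomputation", {
  rt <- random_table(4, 250, seed = 51)
  cfg <- score_config("BDe", 1)
  scorer <- bnmiss:::make_scorer(rt$data, cfg)
  for (nm in names(rt$data)) {
    for (pa in list(character(0), setdiff(names(rt$data), nm)[1:2])) {
      a <- scorer(nm, pa)
      b <- scorer(nm, pa) # cached
      direct <- family_score(nm, pa, rt$data, cfg)
      expect_equal(a, direct, tolerance = 1e-12)
      expect_identical(a, b)
    }
  }
})

test_that("CPDAG conversion directs colliders, frees chains, and is idempotent", {
  lv <- list(A = letters[1:3], B = letters[1:3], C = letters[1:3])
  chain <- to_cpdag(parse_modelstring("[A][B|A][C|B]", lv))
  expect_equal(sort(pdag_edges(chain)$undirected), c("A--B", "B--C"))
  expect_equal(nrow(pdag_edges(chain)$directed), 0)
  collider <- to_cpdag(parse_modelstring("[A][B][C|A:B]", lv))
  expect_equal(length(pdag_edges(collider)$undirected), 0)
  expect_setequal(pdag_edges(collider)$directed[, "to"], c("C", "C"))
  single <- to_cpdag(parse_modelstring("[A][B|A]", lv[1:2]))
  expect_equal(pdag_edges(single)$undirected, "A--B")
  for (s in 1:20) {
    cp <- to_cpdag(generate_random_dag(7, seed = s))
    expect_identical(to_cpdag(cp)$amat, cp$amat)
  }
})

test_that("CPDAG matches the equivalence-class enumeration oracle", {
  for (s in 1:20) {
    d <- generate_random_dag(4, seed = 300 + s)
    expect_identical(
      to_cpdag(d)$amat,
      bnmiss:::compelled_by_enumeration(d)$amat
    )
  }
})

test_that("skeletons erase direction and intersect as sets", {
  lv <- list(A = letters[1:2], B = letters[1:2])
  expect_equal(
    skeleton(parse_modelstring("[A][B|A]", lv)),
    skeleton(parse_modelstring("[B][A|B]", lv))
  )
  expect_equal(length(skeleton(bn_dag(c("A", "B")))), 0)
  orig <- bn_dag(
    paste0("N", 1:4),
    parents = list(N2 = "N1", N3 = "N2", N4 = "N3")
  )
  learned <- bn_dag(
    paste0("N", 1:4),
    parents = list(N2 = "N1", N4 = "N2")
  )
  expect_equal(intersect(skeleton(orig), skeleton(learned)), "N1--N2")
})
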