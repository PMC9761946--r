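# Shared fixture builders (all generated in code; no stored data).

# two-node chain A -> B with explicit CPTs
chain_ab <- function(p_a = c(0.6, 0.4),
                     p_b_given_a = rbind(c(0.9, 0.1), c(0.2, 0.8))) {
  dag <- bn_dag(
    c("A", "B"),
    parents = list(B = "A"),
    levels = list(A = c("a1", "a2"), B = c("b1", "b2"))
  )
  fit <- sample_cpts(dag, seed = 1)
  fit$cpts$A <- matrix(p_a, 1, dimnames = list(NULL, c("a1", "a2")))
  fit$cpts$B <- `dimnames<-`(p_b_given_a, list(NULL, c("b1", "b2")))
  fit
}

# complete three-level table sampled from a random network
random_table <- function(n_vars, n_rows, seed) {
  dag <- generate_random_dag(n_vars, seed = seed)
  bn <- sample_cpts(dag, seed = seed + 1)
  list(dag = dag, bn = bn, data = forward_sample(bn, n_rows, seed = seed + 2))
}

# strongly dependent pair: y is a noisy copy of x (three levels)
dependent_pair <- function(n, seed, flip = 0.05) {
  with_seed <- function(s, e) {
    set.seed(s)
    e
  }
  set.seed(seed)
  lv <- c("a", "b", "c")
  x <- factor(sample(lv, n, TRUE), levels = lv)
  y <- as.character(x)
  sw <- runif(n) < flip
  y[sw] <- sample(lv, sum(sw), TRUE)
  data.frame(A = x, B = factor(y, levels = lv))
}
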