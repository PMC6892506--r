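test_that("directed_graph enforces its invariants", {
  g <- directed_graph(data.frame(source = c(0, 0, 1), target = c(1, 2, 2)),
                      n_nodes = 4)
  expect_equal(g$n_nodes, 4L)
  expect_equal(sum(out_degree(g)), nrow(g$edges))
  expect_equal(sum(in_degree(g)), nrow(g$edges))
  expect_warning(
    g2 <- directed_graph(data.frame(source = c(0, 0), target = c(1, 1))),
    "Duplicate"
  )
  expect_equal(nrow(g2$edges), 1L)
  expect_error(directed_graph(data.frame(source = 0, target = 2), n_nodes = 2),
               "reference")
  expect_error(directed_graph(data.frame(source = -1, target = 0)), "0-based")
})

test_that("stochastic operator matches the A/k_out rule with uniform dangling columns", {
  # single dangling node: S = [1]
  g1 <- directed_graph(data.frame(source = integer(), target = integer()),
                       n_nodes = 1)
  expect_equal(as.matrix(stochastic_operator(g1)), matrix(1, 1, 1))
  # 2-cycle: permutation matrix
  g2 <- directed_graph(data.frame(source = c(0, 1), target = c(1, 0)))
  expect_equal(as.matrix(stochastic_operator(g2)),
               matrix(c(0, 1, 1, 0), 2, 2))
  # hand-evaluated mixed case with a dangling node
  g4 <- directed_graph(data.frame(source = c(0, 0, 1), target = c(1, 2, 2)),
                       n_nodes = 4)
  S <- as.matrix(stochastic_operator(g4))
  expect_equal(S[, 1], c(0, 0.5, 0.5, 0))
  expect_equal(S[, 4], rep(0.25, 4))
  # an empty node set is rejected before any operator can be built
  expect_error(
    directed_graph(data.frame(source = integer(), target = integer()), n_nodes = 0),
    "at least one node"
  )
})

test_that("google operator is column-stochastic and has the correct limits", {
  g <- random_graph(30, seed = 5)
  S <- as.matrix(stochastic_operator(g))
  expect_lt(max(abs(colSums(S) - 1)), 1e-12)
  G <- as.matrix(google_operator(g, alpha = 0.85))
  expect_lt(max(abs(colSums(G) - 1)), 1e-12)
  # teleportation-only limit
  G0 <- as.matrix(google_operator(g, alpha = 1e-12))
  expect_lt(max(abs(G0 - 1 / 30)), 1e-11)
  # direct formula on the 2-cycle
  g2 <- directed_graph(data.frame(source = c(0, 1), target = c(1, 0)))
  expect_equal(as.matrix(google_operator(g2, alpha = 0.5)),
               matrix(c(0.25, 0.75, 0.75, 0.25), 2, 2))
  expect_error(google_operator(g, alpha = 1), "alpha")
  expect_error(google_operator(g, alpha = 0), "alpha")
  # matrix-free application agrees with the dense realization
  v <- runif(30); v <- v / sum(v)
  expect_equal(apply_operator(google_operator(g), v),
               drop(as.matrix(google_operator(g)) %*% v), tolerance = 1e-13)
  # stochasticity preserved by application
  expect_equal(sum(apply_operator(google_operator(g), v)), 1, tolerance = 1e-12)
})

test_that("pagerank finds the unique stationary vector", {
  # symmetric cases: uniform
  co <- expand.grid(s = 0:3, t = 0:3); co <- co[co$s != co$t, ]
  pr <- pagerank(directed_graph(data.frame(source = co$s, target = co$t)))
  expect_equal(pr$probs, rep(0.25, 4), tolerance = 1e-10)
  pr3 <- pagerank(directed_graph(data.frame(source = 0:2, target = c(1, 2, 0))))
  expect_equal(pr3$probs, rep(1 / 3, 3), tolerance = 1e-10)
  # star with dangling hub vs dense oracle; hub is ranked first
  star <- directed_graph(data.frame(source = c(1, 2), target = c(0, 0)))
  prs <- pagerank(star)
  expect_equal(prs$probs, oracle_stationary(oracle_google(star)),
               tolerance = 1e-10)
  expect_equal(prs$index[1], 1L)
  # fixed-point residual bound
  G <- oracle_google(star)
  expect_lt(sum(abs(G %*% prs$probs - prs$probs)), 10 * 1e-12)
  expect_error(pagerank(star, max_iter = 2), "converge")
})

test_that("power iteration agrees with the dense oracle and is start-independent", {
  for (seed in 1:3) {
    g <- random_graph(150, p = 0.04, seed = seed)
    pr <- pagerank(g)
    expect_lt(max(abs(pr$probs - oracle_stationary(oracle_google(g)))), 1e-8)
    set.seed(seed + 100)
    st <- runif(150)
    pr2 <- pagerank(g, start = st / sum(st))
    expect_lt(max(abs(pr$probs - pr2$probs)), 1e-10)
  }
})

test_that("pagerank is invariant under node relabeling", {
  g <- random_graph(40, seed = 9)
  set.seed(2)
  perm <- sample(40) - 1L  # perm[i+1] is the new id of node i
  g_perm <- directed_graph(data.frame(
    source = perm[g$edges$source + 1L],
    target = perm[g$edges$target + 1L]
  ), n_nodes = 40)
  p1 <- pagerank(g)$probs
  p2 <- pagerank(g_perm)$probs
  expect_lt(max(abs(p1 - p2[perm + 1L])), 1e-10)
})

test_that("top of the ranking is stable across damping factors", {
  g <- random_graph(100, p = 0.05, seed = 4)
  top5 <- lapply(c(0.5, 0.7, 0.85, 0.95), function(a) {
    order(-pagerank(g, alpha = a)$probs)[1:5]
  })
  # the set of top-5 nodes varies by at most one member across alpha
  base <- top5[[3]]
  for (t5 in top5) expect_gte(length(intersect(t5, base)), 4)
})

test_that("cheirank is pagerank of the reversed network", {
  # symmetric graph: P* equals P
  ed <- data.frame(source = c(0, 1, 1, 2, 0, 2), target = c(1, 0, 2, 1, 2, 0))
  g <- directed_graph(ed)
  expect_equal(cheirank(g)$probs, pagerank(g)$probs, tolerance = 1e-10)
  # chain: the source node is the most diffusive
  chain <- directed_graph(data.frame(source = c(0, 1), target = c(1, 2)))
  cr <- cheirank(chain)
  expect_equal(cr$index[1], 1L)
  expect_equal(cr$probs, oracle_stationary(oracle_google(reverse_graph(chain))),
               tolerance = 1e-10)
  # double reversal is the identity
  g2 <- random_graph(25, seed = 11)
  expect_equal(pagerank(reverse_graph(reverse_graph(g2)))$probs,
               pagerank(g2)$probs, tolerance = 1e-12)
})

test_that("rank_indices assigns K = 1 to the largest probability with stable ties", {
  expect_equal(rank_indices(c(0.5, 0.3, 0.2)), c(1L, 2L, 3L))
  expect_equal(rank_indices(c(0.2, 0.2, 0.6)), c(2L, 3L, 1L))
  set.seed(8)
  v <- runif(100)
  k <- rank_indices(v)
  expect_equal(sort(k), 1:100)
  expect_equal(order(-v), order(k))      # sort oracle
  expect_true(all(diff(v[order(k)]) <= 0))
  expect_error(rank_indices(c(-1, 0.5)), "nonnegative")
})
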