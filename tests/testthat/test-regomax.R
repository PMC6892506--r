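test_that("a full subset reduces trivially to the Google matrix itself", {
  g <- random_graph(12, seed = 1)
  r <- reduce_google_matrix(g, 0:11)
  expect_equal(unname(r$G_R), oracle_google(g), tolerance = 1e-12)
  expect_equal(max(abs(r$G_pr)), 0)
  expect_equal(max(abs(r$G_qr)), 0)
  expect_error(reduce_google_matrix(g, integer()), "at least one")
  expect_error(reduce_google_matrix(g, c(0, 0)), "duplicates")
})

test_that("the reduced fixed point reproduces the restricted global PageRank", {
  g <- random_graph(50, p = 0.08, seed = 2)
  sub <- c(0, 7, 13, 22, 31, 44)
  r <- suppressWarnings(reduce_google_matrix(g, sub))
  p_global <- pagerank(g)$probs[sub + 1]
  p_rel <- p_global / sum(p_global)
  expect_lt(max(abs(r$p_r - p_rel) / p_rel), 1e-8)
  expect_lt(max(abs(colSums(r$G_R) - 1)), 1e-10)
  # kappa is the ratio of sums between reduced and restricted global PageRank
  expect_equal(r$kappa, 1 / sum(pagerank(g)$probs[sub + 1]), tolerance = 1e-10)
})

test_that("dense and iterative backends agree with the dense eigen oracle", {
  g <- random_graph(30, p = 0.12, seed = 3)
  sub <- c(2, 8, 15, 21, 28)
  rd <- suppressWarnings(reduce_google_matrix(g, sub, backend = "dense"))
  ri <- suppressWarnings(reduce_google_matrix(g, sub, backend = "iterative"))
  expect_lt(max(abs(rd$G_R - ri$G_R)), 1e-10)
  expect_lt(max(abs(rd$G_pr - ri$G_pr)), 1e-10)
  expect_lt(max(abs(rd$G_qr - ri$G_qr)), 1e-10)
  orc <- oracle_reduce(g, sub)
  expect_lt(max(abs(unname(rd$G_R) - orc$G_R)), 1e-10)
  expect_lt(max(abs(unname(rd$G_rr) - orc$G_rr)), 1e-12)
  expect_lt(max(abs(unname(rd$G_pr) - orc$G_pr)), 1e-9)
  expect_lt(max(abs(unname(rd$G_qr) - orc$G_qr)), 1e-9)
  expect_equal(rd$lambda_c, orc$lambda_c, tolerance = 1e-10)
  # additive decomposition holds entrywise on both backends
  expect_lt(rd$decomp_err, 1e-10)
  expect_lt(ri$decomp_err, 1e-10)
})

test_that("permuting the subset order permutes the reduced matrices consistently", {
  g <- random_graph(40, seed = 4)
  sub <- c(1, 6, 12, 19, 25, 33)
  r1 <- suppressWarnings(reduce_google_matrix(g, sub))
  perm <- c(3, 1, 6, 2, 5, 4)
  r2 <- suppressWarnings(reduce_google_matrix(g, sub[perm]))
  for (cn in c("G_R", "G_rr", "G_pr", "G_qr")) {
    expect_lt(max(abs(r2[[cn]] - r1[[cn]][perm, perm])), 1e-10)
  }
})

test_that("G_pr is exactly rank one with columns shaped like the reduced PageRank", {
  net <- study_network(7)
  sel <- net$catalog[net$catalog$group %in% c("company", "rare_renal_disease"), ]
  r <- reduce_google_matrix(net$graph, sel$node_id, labels = sel$name)
  sv <- svd(r$G_pr)$d
  expect_lt(sv[2] / sv[1], 1e-12)
  # every normalized column approximates P_r (the study-scale, qualitative
  # version of the column-similarity property)
  coldist <- apply(r$G_pr, 2, function(cl) sum(abs(cl / sum(cl) - r$p_r)))
  expect_lt(max(coldist), 0.5)
  # self-interaction split is exact
  expect_equal(r$G_qrd + r$G_qrnd, r$G_qr)
  expect_true(all(diag(r$G_qrnd) == 0))
})

test_that("split_qr separates diagonal and off-diagonal parts exactly", {
  expect_equal(split_qr(diag(3)), list(G_qrd = diag(3), G_qrnd = matrix(0, 3, 3)))
  m0 <- matrix(1, 4, 4) - diag(4)
  expect_equal(split_qr(m0)$G_qrd, matrix(0, 4, 4))
  expect_equal(split_qr(m0)$G_qrnd, m0)
  set.seed(5)
  m <- matrix(rnorm(25), 5, 5)
  parts <- split_qr(m)
  expect_identical(parts$G_qrd + parts$G_qrnd, m)
  expect_error(split_qr(matrix(1, 2, 3)), "square")
})

test_that("top_hidden_links surfaces planted indirect paths and respects bounds", {
  net <- study_network(7)
  sel <- net$catalog[net$catalog$group %in% c("company", "rare_renal_disease"), ]
  r <- reduce_google_matrix(net$graph, sel$node_id, labels = sel$name)
  hl <- top_hidden_links(r, net$catalog, "company", "rare_renal_disease", k = 5)
  expect_equal(hl$source[1], "company_01")
  expect_equal(hl$target[1], "disease_01")
  expect_false(hl$is_direct[1])
  expect_gt(hl$weight[1], 10 * hl$weight[2])
  # k larger than available entries returns everything, sorted
  all_links <- top_hidden_links(r, net$catalog, "company", "rare_renal_disease",
                                k = 1e6)
  expect_equal(nrow(all_links), 100L)
  expect_true(all(diff(all_links$weight) <= 1e-15))
  # empty group gives an empty table
  expect_equal(nrow(top_hidden_links(r, net$catalog, "cancer", "country")), 0L)
})

test_that("no indirect pathways means a numerically empty G_qrnd block", {
  # diseases reachable only via background removed: companies and diseases
  # in separate components with no complement paths between them
  ed <- data.frame(
    source = c(0, 1, 2, 3, 4, 5),
    target = c(1, 0, 3, 2, 5, 4)
  )
  g <- directed_graph(ed)
  r <- suppressWarnings(reduce_google_matrix(g, c(0, 2, 4)))
  # remaining coupling is pure teleportation, identical for every pair:
  # off-diagonal indirect entries carry no link information
  expect_lt(max(abs(r$G_qrnd - mean(r$G_qrnd[row(r$G_qrnd) != col(r$G_qrnd)]) *
                      (1 - diag(3)))), 1e-10)
})
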