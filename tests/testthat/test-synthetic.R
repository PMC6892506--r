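test_that("generation is deterministic per seed and validates plantings", {
  cfg <- layered_config(n_background = 300, n_country = 5, n_company = 4,
                        n_disease = 3, seed = 123)
  n1 <- generate_layered_network(cfg)
  n2 <- generate_layered_network(cfg)
  expect_identical(n1$graph$edges, n2$graph$edges)
  expect_identical(n1$catalog, n2$catalog)
  n3 <- generate_layered_network(layered_config(n_background = 300, n_country = 5,
                                                n_company = 4, n_disease = 3,
                                                seed = 124))
  expect_false(identical(n1$graph$edges, n3$graph$edges))
  expect_error(
    layered_config(n_company = 2, planted_hidden = data.frame(
      source = 5, n_intermediaries = 2, target = 1)),
    "company"
  )
  expect_error(
    layered_config(n_disease = 2, planted_hidden = data.frame(
      source = 1, n_intermediaries = 2, target = 7)),
    "disease"
  )
})

test_that("generated degree sequences are heavy-tailed", {
  net <- generate_layered_network(layered_config(n_background = 2000, seed = 42))
  indeg <- in_degree(net$graph)
  expect_gt(max(indeg) / median(indeg), 10)
})

test_that("group centralities are ordered country > company > disease", {
  net <- generate_layered_network(layered_config(seed = 42))
  pr <- pagerank(net$graph)
  grp <- net$catalog$group
  means <- tapply(pr$probs, grp, mean)
  expect_gt(means[["country"]], means[["company"]])
  expect_gt(means[["company"]], means[["rare_renal_disease"]])
})

test_that("planted two-hop paths dominate the indirect company-disease block", {
  net <- study_network(11)
  sel <- net$catalog[net$catalog$group %in% c("company", "rare_renal_disease"), ]
  r <- reduce_google_matrix(net$graph, sel$node_id, labels = sel$name)
  hl <- top_hidden_links(r, net$catalog, "company", "rare_renal_disease", k = 2)
  expect_equal(hl$source[1], "company_01")
  expect_equal(hl$target[1], "disease_01")
  expect_false(hl$is_direct[1])
  # the planted coupling dwarfs the teleportation-level background couplings
  expect_gt(hl$weight[1], 20 * hl$weight[2])
  # without plantings the same entry sits at the background level
  cfg0 <- layered_config(seed = 11)
  net0 <- generate_layered_network(cfg0)
  sel0 <- net0$catalog[net0$catalog$group %in% c("company", "rare_renal_disease"), ]
  r0 <- reduce_google_matrix(net0$graph, sel0$node_id, labels = sel0$name)
  hl0 <- top_hidden_links(r0, net0$catalog, "company", "rare_renal_disease", k = 1)
  expect_lt(hl0$weight[1], hl$weight[1] / 20)
})

test_that("the generator never wires direct company-disease edges", {
  net <- study_network(11)
  comp <- net$catalog$node_id[net$catalog$group == "company"]
  dis <- net$catalog$node_id[net$catalog$group == "rare_renal_disease"]
  e <- net$graph$edges
  expect_equal(sum(e$source %in% comp & e$target %in% dis), 0L)
})

test_that("tiny fixtures carry dense-solve oracles the solver reproduces", {
  tf <- tiny_fixtures()
  expect_setequal(names(tf),
                  c("cycle3", "chain3", "star3", "complete4", "dangling4"))
  expect_equal(attr(tf$cycle3, "pagerank"), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(attr(tf$complete4, "pagerank"), rep(0.25, 4), tolerance = 1e-12)
  for (nm in names(tf)) {
    expect_lt(max(abs(pagerank(tf[[nm]])$probs - attr(tf[[nm]], "pagerank"))),
              1e-10)
    expect_lte(tf[[nm]]$n_nodes, 10L)
  }
  # the star oracle gives the dangling hub the top position
  expect_equal(which.max(attr(tf$star3, "pagerank")), 1L)
})

test_that("packaged study tables load, validate, and match printed rows", {
  tabs <- load_paper_tables()
  expect_equal(nrow(tabs$companies), 34L)
  expect_equal(nrow(tabs$diseases), 47L)
  pf <- tabs$companies[tabs$companies$K_r == 1, ]
  expect_equal(pf$name, "Pfizer")
  expect_equal(c(pf$K_r_star, pf$K_LMC, pf$K_MC), c(3L, 2L, 3L))
  al <- tabs$diseases[tabs$diseases$K_r == 1, ]
  expect_equal(al$name, "Alport syndrome")
  expect_equal(al$K_r_star, 6L)
  expect_equal(al$category, "glomerular")
  expect_equal(sort(unique(tabs$diseases$category)),
               c("ciliopathies", "congenital", "glomerular",
                 "nephrolithiasis", "tubular_metabolic"))
})

test_that("a corrupted rank column is rejected loudly", {
  d <- withr::local_tempdir()
  tabs <- load_paper_tables()
  bad <- tabs$companies
  bad$K_r[2] <- 1L  # duplicate rank: no longer a permutation
  readr::write_csv(bad, file.path(d, "companies.csv"))
  readr::write_csv(tabs$diseases, file.path(d, "renal_diseases.csv"))
  expect_error(load_paper_tables(dir = d), "not a permutation")
})

test_that("the nodes of interest bookkeeping sums to 313", {
  sizes <- interest_group_sizes()
  expect_equal(sum(sizes$n), 313L)
  expect_equal(sizes$n[sizes$group == "company"], 34L)
  expect_equal(sizes$n[sizes$group == "rare_renal_disease"], 47L)
})
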