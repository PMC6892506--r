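# A 12-node planted toy: 3 "companies" among 8 other subset members whose
# strongest couplings are known, plus background nodes so the reduction is
# well defined.
friend_toy <- function() {
  # subset: companies a,b,c (0,1,2) and partners p1..p4 (3,4,5,6)
  # direct links chosen so each company has unambiguous strongest couplings
  ed <- data.frame(
    source = c(0, 0, 0, 1, 1, 2, 2, 1,
               7, 8, 9, 10, 11, 7, 8, 9,
               3, 4, 5, 6),
    target = c(1, 3, 4, 2, 4, 0, 5, 6,
               0, 1, 2, 3, 4, 8, 9, 7,
               7, 8, 9, 10)
  )
  g <- directed_graph(ed, n_nodes = 12)
  catalog <- tibble::tibble(
    node_id = 0:11,
    name = c("a", "b", "c", "p1", "p2", "p3", "p4", paste0("bg", 1:5)),
    group = c(rep("company", 3), rep("country", 4), rep("other", 5)),
    category = ""
  )
  list(graph = g, catalog = catalog)
}

toy_reduced <- function() {
  toy <- friend_toy()
  sel <- toy$catalog[toy$catalog$group %in% c("company", "country"), ]
  r <- suppressWarnings(
    reduce_google_matrix(toy$graph, sel$node_id, labels = sel$name)
  )
  list(toy = toy, r = r)
}
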