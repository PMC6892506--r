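#' Directed graphs for Google-matrix analysis
#'
#' A `directed_graph` is a plain container for a node set `0..n_nodes-1` and a
#' set of directed edges. Node identifiers are 0-based everywhere (in memory
#' and in edge-list files); conversion to R's 1-based matrix indexing happens
#' only at the linear-algebra boundary.
#'
#' @param edges A data frame with integer columns `source` and `target`
#'   (0-based node ids), one row per directed edge `source -> target`.
#' @param n_nodes Number of nodes. Defaults to one more than the largest id
#'   seen in `edges`, so isolated trailing nodes must be declared explicitly.
#' @return An object of class `directed_graph` with fields `n_nodes`, `edges`
#'   (a tibble), and cached `out_degree` / `in_degree` integer vectors indexed
#'   by `node_id + 1`.
#' @examples
#' g <- directed_graph(data.frame(source = c(0L, 1L), target = c(1L, 0L)))
#' out_degree(g)
#' @export
directed_graph <- function(edges, n_nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    abort("`edges` must have columns `source` and `target`.")
  }
  edges <- tibble(
    source = as.integer(edges$source),
    target = as.integer(edges$target)
  )
  if (nrow(edges) > 0 && (anyNA(edges$source) || anyNA(edges$target))) {
    abort("Edge endpoints must be non-missing integers.")
  }
  if (nrow(edges) > 0 && min(edges$source, edges$target) < 0) {
    abort("Node ids must be >= 0 (ids are 0-based).")
  }
  n_min <- if (nrow(edges) > 0) max(edges$source, edges$target) + 1L else 0L
  n_nodes <- as.integer(n_nodes %||% n_min)
  if (n_nodes < n_min) {
    abort(sprintf("`n_nodes` = %d but edges reference node %d.", n_nodes, n_min - 1L))
  }
  if (n_nodes < 1L) {
    abort("A directed_graph needs at least one node.")
  }
  key <- edges$source * as.double(n_nodes) + edges$target
  if (anyDuplicated(key)) {
    warn("Duplicate edges collapsed.")
    edges <- edges[!duplicated(key), ]
  }
  structure(
    list(
      n_nodes = n_nodes,
      edges = edges,
      out_degree = tabulate(edges$source + 1L, nbins = n_nodes),
      in_degree = tabulate(edges$target + 1L, nbins = n_nodes)
    ),
    class = "directed_graph"
  )
}

#' @export
print.directed_graph <- function(x, ...) {
  cat(sprintf(
    "<directed_graph: %d nodes, %d edges, %d dangling>\n",
    x$n_nodes, nrow(x$edges), sum(x$out_degree == 0L)
  ))
  invisible(x)
}

#' @rdname directed_graph
#' @param graph A `directed_graph`.
#' @export
out_degree <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  graph$out_degree
}

#' @rdname directed_graph
#' @export
in_degree <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  graph$in_degree
}

#' Reverse every edge of a directed graph
#'
#' The CheiRank of a network is the PageRank of its edge-reversed counterpart;
#' this helper produces that counterpart.
#'
#' @param graph A `directed_graph`.
#' @return A `directed_graph` with all edges reversed.
#' @export
reverse_graph <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  directed_graph(
    tibble(source = graph$edges$target, target = graph$edges$source),
    n_nodes = graph$n_nodes
  )
}

#' Sparse adjacency matrix of a directed graph
#'
#' Returns the adjacency matrix with the column-to-row orientation used
#' throughout the package: `A[i, j] = 1` when node `j` points to node `i`,
#' so that column `j` lists the out-neighbourhood of `j`.
#'
#' @param graph A `directed_graph`.
#' @return A sparse `dgCMatrix` of dimension `n_nodes x n_nodes`.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  sparseMatrix(
    i = graph$edges$target + 1L,
    j = graph$edges$source + 1L,
    x = 1,
    dims = c(graph$n_nodes, graph$n_nodes)
  )
}

#' @export
tidy.directed_graph <- function(x, ...) {
  x$edges
}

#' @export
glance.directed_graph <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes,
    n_edges = nrow(x$edges),
    n_dangling = sum(x$out_degree == 0L),
    max_in_degree = if (x$n_nodes) max(x$in_degree) else 0L,
    max_out_degree = if (x$n_nodes) max(x$out_degree) else 0L
  )
}
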