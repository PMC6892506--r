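#' Column-stochastic link operator S of a directed graph
#'
#' Column `j` of `S` equals `A[, j] / k_out(j)` when node `j` has outgoing
#' links, and the uniform column `1/N` when `j` is dangling. The dangling
#' columns are never materialised: the operator stores the sparse link part
#' together with a dangling indicator, and the uniform dangling mass is
#' applied analytically on each product, so the construction stays
#' scale-agnostic.
#'
#' @param graph A `directed_graph`.
#' @return An object of class `stochastic_op` with fields `S0` (sparse link
#'   part; dangling columns all zero), `dangling` (logical vector), `n`.
#' @export
stochastic_operator <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  n <- graph$n_nodes
  if (n == 0L) abort("Cannot build a stochastic operator for an empty graph.")
  e <- graph$edges
  s0 <- sparseMatrix(
    i = e$target + 1L,
    j = e$source + 1L,
    x = 1 / graph$out_degree[e$source + 1L],
    dims = c(n, n)
  )
  structure(
    list(S0 = s0, dangling = graph$out_degree == 0L, n = n),
    class = "stochastic_op"
  )
}

#' Google matrix operator G = alpha * S + (1 - alpha)/N
#'
#' The teleportation term and the dangling-column mass are rank-one and are
#' applied analytically, never stored, so products with `G` cost one sparse
#' matrix-vector product.
#'
#' @param x A `directed_graph` or a `stochastic_op`.
#' @param alpha Damping factor in (0, 1); the standard value is 0.85.
#' @return An object of class `google_op`.
#' @export
google_operator <- function(x, alpha = 0.85) {
  if (inherits(x, "directed_graph")) x <- stochastic_operator(x)
  stopifnot(inherits(x, "stochastic_op"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1.")
  }
  structure(
    list(S0 = x$S0, dangling = x$dangling, n = x$n, alpha = alpha),
    class = "google_op"
  )
}

#' Apply a stochastic or Google operator to a vector (or matrix of columns)
#'
#' @param op A `stochastic_op` or `google_op`.
#' @param v Numeric vector of length `n`, or a matrix with `n` rows.
#' @return The product `S v` or `G v`, same shape as `v`.
#' @export
apply_operator <- function(op, v) {
  UseMethod("apply_operator")
}

#' @export
apply_operator.stochastic_op <- function(op, v) {
  v <- as.matrix(v)
  base <- as.matrix(op$S0 %*% v)
  dang <- colSums(v[op$dangling, , drop = FALSE]) / op$n
  drop(sweep(base, 2, dang, "+"))
}

#' @export
apply_operator.google_op <- function(op, v) {
  v <- as.matrix(v)
  base <- as.matrix(op$S0 %*% v)
  extra <- (op$alpha * colSums(v[op$dangling, , drop = FALSE]) +
              (1 - op$alpha) * colSums(v)) / op$n
  drop(sweep(op$alpha * base, 2, extra, "+"))
}

#' @export
as.matrix.stochastic_op <- function(x, dense_cap = 5000, ...) {
  if (x$n > dense_cap) {
    abort(sprintf("Refusing dense realization for n = %d > dense_cap = %d.",
                  x$n, dense_cap))
  }
  m <- as.matrix(x$S0)
  m[, x$dangling] <- 1 / x$n
  m
}

#' @export
as.matrix.google_op <- function(x, dense_cap = 5000, ...) {
  if (x$n > dense_cap) {
    abort(sprintf("Refusing dense realization for n = %d > dense_cap = %d.",
                  x$n, dense_cap))
  }
  s <- as.matrix(x$S0)
  s[, x$dangling] <- 1 / x$n
  x$alpha * s + (1 - x$alpha) / x$n
}

#' @export
print.stochastic_op <- function(x, ...) {
  cat(sprintf("<stochastic_op: n = %d, %d dangling columns>\n",
              x$n, sum(x$dangling)))
  invisible(x)
}

#' @export
print.google_op <- function(x, ...) {
  cat(sprintf("<google_op: n = %d, alpha = %g, %d dangling columns>\n",
              x$n, x$alpha, sum(x$dangling)))
  invisible(x)
}

#' PageRank of a directed network
#'
#' Computes the stationary probability vector `P = G P` of the Google matrix
#' by power iteration, stopping when the L1 distance between successive
#' iterates falls below `tol`. By the Perron-Frobenius theorem the fixed point
#' is unique for 0 < alpha < 1 and independent of the start vector.
#'
#' @param x A `directed_graph`, `stochastic_op`, `google_op`, or a dense
#'   column-stochastic matrix.
#' @param alpha Damping factor; ignored when `x` is already a `google_op` or a
#'   dense matrix.
#' @param tol Convergence threshold on the L1 change between iterates.
#' @param max_iter Iteration cap; exceeding it is an error that reports the
#'   residual reached.
#' @param start Optional start probability vector (defaults to uniform).
#' @return An object of class `rank_result` with fields `probs` (stationary
#'   probabilities, summing to 1), `index` (the rank permutation `K`: `K = 1`
#'   for the largest probability, ties broken by ascending node id),
#'   `n_iter`, and `residual`.
#' @seealso [cheirank()], [rank_indices()]
#' @export
pagerank <- function(x, alpha = 0.85, tol = 1e-12, max_iter = 1000, start = NULL) {
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive.")
  op <- if (is.matrix(x)) {
    n <- nrow(x)
    local({
      m <- x
      function(v) drop(m %*% v)
    })
  } else {
    if (inherits(x, "directed_graph") || inherits(x, "stochastic_op")) {
      x <- google_operator(x, alpha = alpha)
    }
    stopifnot(inherits(x, "google_op"))
    n <- x$n
    function(v) apply_operator(x, v)
  }
  p <- if (is.null(start)) rep(1 / n, n) else {
    stopifnot(length(start) == n, all(start >= 0))
    start / sum(start)
  }
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- op(p)
    p_new <- p_new / sum(p_new)
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) break
  }
  if (res >= tol) {
    abort(sprintf(
      "PageRank power iteration did not converge: residual %.3e after %d iterations (tol %.1e).",
      res, iter, tol
    ))
  }
  structure(
    list(probs = p, index = rank_indices(p), n_iter = iter, residual = res),
    class = "rank_result"
  )
}

#' CheiRank of a directed network
#'
#' The CheiRank vector `P*` is the PageRank of the network with every edge
#' reversed (adjacency transposed); it measures how strongly a node diffuses
#' towards the rest of the network through its outgoing links.
#'
#' @inheritParams pagerank
#' @param graph A `directed_graph`.
#' @return A `rank_result` holding `P*` and `K*`.
#' @export
cheirank <- function(graph, alpha = 0.85, tol = 1e-12, max_iter = 1000, start = NULL) {
  stopifnot(inherits(graph, "directed_graph"))
  pagerank(reverse_graph(graph), alpha = alpha, tol = tol,
           max_iter = max_iter, start = start)
}

#' Rank permutation of a probability vector
#'
#' Assigns `K = 1` to the largest probability down to `K = N` for the
#' smallest, with ties broken by ascending node position (stable), so the
#' result is always a permutation of `1..N`.
#'
#' @param probs Nonnegative numeric vector.
#' @return Integer vector `K` with `K[i]` the rank of element `i`.
#' @export
rank_indices <- function(probs) {
  if (any(probs < 0)) abort("`probs` must be nonnegative.")
  as.integer(rank(-probs, ties.method = "first"))
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("<rank_result: n = %d, %d iterations, residual %.2e>\n",
              length(x$probs), x$n_iter, x$residual))
  invisible(x)
}

#' @export
tidy.rank_result <- function(x, ...) {
  tibble(node_id = seq_along(x$probs) - 1L, p = x$probs, k = x$index)
}

#' @export
glance.rank_result <- function(x, ...) {
  tibble(n = length(x$probs), n_iter = x$n_iter, residual = x$residual)
}

#' Combined PageRank/CheiRank table for a network
#'
#' Convenience wrapper computing both centralities and joining node names
#' from a catalog, in the column layout used by the CSV writers.
#'
#' @param graph A `directed_graph`.
#' @param catalog Optional node catalog tibble (see [read_node_catalog()]).
#' @inheritParams pagerank
#' @return A tibble with columns `node_id,name,P,K,Pstar,Kstar`.
#' @export
rank_table <- function(graph, catalog = NULL, alpha = 0.85, tol = 1e-12,
                       max_iter = 1000) {
  pr <- pagerank(graph, alpha = alpha, tol = tol, max_iter = max_iter)
  cr <- cheirank(graph, alpha = alpha, tol = tol, max_iter = max_iter)
  out <- tibble(
    node_id = seq_len(graph$n_nodes) - 1L,
    name = as.character(seq_len(graph$n_nodes) - 1L),
    P = pr$probs, K = pr$index,
    Pstar = cr$probs, Kstar = cr$index
  )
  if (!is.null(catalog)) {
    out$name <- catalog$name[match(out$node_id, catalog$node_id)]
  }
  out
}
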