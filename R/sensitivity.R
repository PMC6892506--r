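#' Column-renormalised perturbation of one link of a stochastic matrix
#'
#' Boosts the transition `j -> k` of a column-stochastic matrix by a signed
#' strength `delta` while keeping column `j` exactly normalised:
#' `G[l, j] -> G[l, j] / (1 + delta * G[k, j])` for `l != k` and
#' `G[k, j] -> G[k, j] (1 + delta) / (1 + delta * G[k, j])`. All other
#' columns are untouched. At `delta = 0`, or when `G[k, j] = 1`, the map is
#' the identity.
#'
#' @param G A column-stochastic matrix.
#' @param j Source column index (1-based position within the matrix).
#' @param k Boosted row index (1-based).
#' @param delta Signed perturbation strength; `1 + delta * G[k, j]` must be
#'   positive.
#' @return The perturbed matrix.
#' @export
perturb_column <- function(G, j, k, delta) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  n <- nrow(G)
  if (j < 1 || j > n || k < 1 || k > n) abort("`j` and `k` must index the matrix.")
  denom <- 1 + delta * G[k, j]
  if (denom <= 0) {
    abort(sprintf("Inadmissible perturbation: 1 + delta * G[k, j] = %.3g <= 0.", denom))
  }
  gkj <- G[k, j]
  G[, j] <- G[, j] / denom
  G[k, j] <- gkj * (1 + delta) / denom
  G
}

#' PageRank sensitivity of reduced-PageRank components to one link
#'
#' The sensitivity `D(j -> k, i)` is the logarithmic derivative
#' `(1/P_i) dP_i/d delta` of the `i`-th component of the stationary vector of
#' the reduced Google matrix under the column-renormalised boost of the link
#' `j -> k` (see [perturb_column()]), evaluated in the limit `delta -> 0`.
#'
#' Two evaluation methods are provided. `"fd"` (default) approximates the
#' limit by the symmetric finite difference
#' `[P_i(+delta) - P_i(-delta)] / (2 delta P_i(0))`, accurate to second order
#' in `delta`. `"exact"` differentiates the fixed-point equation
#' `P(delta) = G(delta) P(delta)` analytically: with
#' `dG[, j] = G[k, j] (e_k - G[, j])` the derivative `x = dP/d delta` solves
#' the singular system `(I - G) x = dG P` under the constraint `sum(x) = 0`,
#' handled by an augmented least-squares solve.
#'
#' @param reduced A `reduced_google` object, or a column-stochastic matrix.
#' @param j,k Source column and boosted row, given as 1-based positions or as
#'   subset labels when `reduced` is a `reduced_google`.
#' @param targets Components `i` to report (positions or labels); defaults to
#'   all.
#' @param delta Finite-difference step (ignored for `method = "exact"`).
#' @param method `"fd"` or `"exact"`.
#' @return A tibble `target,label,d` with attributes `delta` and `method`.
#' @export
pagerank_sensitivity <- function(reduced, j, k, targets = NULL, delta = 1e-4,
                                 method = c("fd", "exact")) {
  method <- match.arg(method)
  G <- if (inherits(reduced, "reduced_google")) reduced$G_R else reduced
  stopifnot(is.matrix(G))
  n <- nrow(G)
  lab <- if (inherits(reduced, "reduced_google")) reduced$subset$label else
    (colnames(G) %||% as.character(seq_len(n)))
  resolve <- function(x) {
    if (is.character(x)) {
      pos <- match(x, lab)
      if (anyNA(pos)) abort(sprintf("Unknown label(s): %s",
                                    paste(x[is.na(pos)], collapse = ", ")))
      pos
    } else as.integer(x)
  }
  j <- resolve(j); k <- resolve(k)
  targets <- if (is.null(targets)) seq_len(n) else resolve(targets)
  p0 <- stationary_dense(G)
  if (method == "fd") {
    pp <- stationary_dense(perturb_column(G, j, k, +delta))
    pm <- stationary_dense(perturb_column(G, j, k, -delta))
    d_all <- (pp - pm) / (2 * delta * p0)
  } else {
    dg_col <- G[k, j] * ((seq_len(n) == k) - G[, j])
    b <- dg_col * p0[j]
    aug <- rbind(diag(n) - G, rep(1, n))
    x <- qr.solve(aug, c(b, 0))
    d_all <- x / p0
  }
  out <- tibble(target = targets, label = lab[targets], d = d_all[targets])
  attr(out, "delta") <- if (method == "fd") delta else 0
  attr(out, "method") <- method
  out
}

# Stationary vector of a small column-stochastic matrix, to machine
# precision: least-squares solve of (I - G) p = 0 augmented with sum(p) = 1.
stationary_dense <- function(G) {
  n <- nrow(G)
  drop(qr.solve(rbind(diag(n) - G, rep(1, n)), c(rep(0, n), 1)))
}

#' Diagonal sensitivity profile of a set of targets to one source node
#'
#' For a source node `s` (say a pharmaceutical company) and a set of target
#' nodes `c` (say countries), computes the diagonal PageRank sensitivities
#' `D(s -> c, c)`: how much the influence of each target grows when the
#' effective transition from the source to that target is boosted. This is
#' the quantity mapped per country in the study's sensitivity maps.
#'
#' @param reduced A `reduced_google` object.
#' @param source Source node (label or 1-based subset position).
#' @param targets Target nodes (labels or positions); empty input gives an
#'   empty table.
#' @param delta,method Passed to [pagerank_sensitivity()].
#' @return A tibble `target,label,d` sorted by decreasing sensitivity.
#' @export
sensitivity_profile <- function(reduced, source, targets, delta = 1e-4,
                                method = c("fd", "exact")) {
  method <- match.arg(method)
  if (length(targets) == 0) {
    return(tibble(target = integer(), label = character(), d = double()))
  }
  rows <- purrr::map_dfr(targets, function(tg) {
    pagerank_sensitivity(reduced, j = source, k = tg, targets = tg,
                         delta = delta, method = method)
  })
  rows[order(-rows$d), ]
}
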