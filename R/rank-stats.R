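#' Relative PageRank/CheiRank ranks within a node group
#'
#' Ranks the members of a group (e.g. the 34 pharmaceutical companies or the
#' 47 rare renal diseases) among themselves by descending probability,
#' producing the relative indexes `K_r` and `K_r*`. Ties are broken by
#' ascending label so both columns are always permutations of `1..n`.
#'
#' @param labels Character vector of member names.
#' @param p PageRank probabilities aligned with `labels`.
#' @param p_star Optional CheiRank probabilities.
#' @return A tibble `label,K_r[,K_r_star]`, in `labels` order.
#' @export
relative_ranks <- function(labels, p, p_star = NULL) {
  stopifnot(length(labels) == length(p))
  rk <- function(v) {
    o <- order(-v, labels)
    r <- integer(length(v))
    r[o] <- seq_along(v)
    r
  }
  out <- tibble(label = labels, K_r = rk(p))
  if (!is.null(p_star)) {
    stopifnot(length(p_star) == length(p))
    out$K_r_star <- rk(p_star)
  }
  out
}

#' Spearman rank correlation of two tie-free rank columns
#'
#' Uses the classical formula `rho = 1 - 6 sum(d^2) / (n (n^2 - 1))`, valid
#' because rank columns are permutations by construction (no tie
#' correction is needed or applied).
#'
#' @param x,y Equal-length permutations of `1..n`.
#' @return The correlation coefficient at full precision.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (!setequal(x, seq_len(n)) || !setequal(y, seq_len(n))) {
    abort("`x` and `y` must each be a permutation of 1..n.")
  }
  1 - 6 * sum((x - y)^2) / (n * (n^2 - 1))
}

#' Pairwise Spearman correlations between rank columns
#'
#' @param ranks A data frame whose columns are rank permutations (e.g. the
#'   `K_r`, `K_r_star`, `K_LMC`, `K_MC` columns of the company table).
#' @return A tibble `col_x,col_y,rho` over all ordered pairs, including the
#'   unit diagonal, suitable for reproducing a correlation table.
#' @export
spearman_matrix <- function(ranks) {
  cols <- names(ranks)
  purrr::map_dfr(cols, function(cx) {
    purrr::map_dfr(cols, function(cy) {
      tibble(col_x = cx, col_y = cy,
             rho = spearman_rho(ranks[[cx]], ranks[[cy]]))
    })
  })
}

#' Top-j overlap between two ranked lists
#'
#' `eta(j)` is the fraction of items present in the top `j` of both lists:
#' `eta(j) = |top_j(a) intersect top_j(b)| / j`. When the two lists contain
#' the same items, `eta(n) = 1` at the full length.
#'
#' @param list_a,list_b Character vectors, best-ranked first.
#' @param j Prefix length(s), each between 1 and the shorter list length.
#' @return Numeric vector of overlaps, one per value of `j`.
#' @export
rank_overlap <- function(list_a, list_b, j) {
  jmax <- min(length(list_a), length(list_b))
  if (any(j < 1 | j > jmax)) {
    abort(sprintf("`j` must lie in 1..%d.", jmax))
  }
  vapply(j, function(jj) {
    length(intersect(list_a[seq_len(jj)], list_b[seq_len(jj)])) / jj
  }, numeric(1))
}

#' Overlap curve over all prefix lengths
#'
#' @inheritParams rank_overlap
#' @return A tibble `j,eta` for `j = 1..min(length)`.
#' @export
overlap_curve <- function(list_a, list_b) {
  jmax <- min(length(list_a), length(list_b))
  tibble(j = seq_len(jmax), eta = rank_overlap(list_a, list_b, seq_len(jmax)))
}

#' Density of nodes on the logarithmic rank-rank plane
#'
#' Bins the joint distribution of `(log10 K, log10 K*)` over an
#' `n_bins x n_bins` grid spanning `[0, log10 N]^2`. Bins are half-open
#' `[lo, hi)` with the final bin closed, so the worst rank `K = N` lands in
#' the last tile and the tile counts always sum to `N`.
#'
#' @param K,K_star Rank permutations of `1..N`.
#' @param n_bins Grid resolution per axis.
#' @return A tibble `bin_k,bin_kstar,log10_k,log10_kstar,count` containing
#'   the occupied tiles (`log10_*` are tile centers).
#' @export
rank_plane_density <- function(K, K_star, n_bins = 100) {
  n <- length(K)
  stopifnot(length(K_star) == n)
  if (!setequal(K, seq_len(n)) || !setequal(K_star, seq_len(n))) {
    abort("`K` and `K_star` must be permutations of 1..N.")
  }
  hi <- log10(max(n, 2))
  bin_of <- function(v) pmin(floor(log10(v) / hi * n_bins) + 1L, n_bins)
  bk <- bin_of(K)
  bks <- bin_of(K_star)
  df <- dplyr::count(tibble(bin_k = bk, bin_kstar = bks),
                     .data$bin_k, .data$bin_kstar, name = "count")
  df$log10_k <- (df$bin_k - 0.5) * hi / n_bins
  df$log10_kstar <- (df$bin_kstar - 0.5) * hi / n_bins
  df[c("bin_k", "bin_kstar", "log10_k", "log10_kstar", "count")]
}

#' Heatmap of a rank-plane density grid
#'
#' @param object A tibble from [rank_plane_density()].
#' @param overlay Optional tibble `K,K_star[,group]` of nodes to mark on top
#'   of the density (e.g. the positions of a node group of interest).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rank_plane <- function(object, overlay = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$log10_k,
                                            y = .data$log10_kstar,
                                            fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = expression(log[10] ~ K), y = expression(log[10] ~ K^"*"),
                  fill = "count") +
    ggplot2::theme_minimal()
  if (!is.null(overlay)) {
    overlay <- as_tibble(overlay)
    overlay$log10_k <- log10(overlay$K)
    overlay$log10_kstar <- log10(overlay$K_star)
    mapping <- if ("group" %in% names(overlay)) {
      ggplot2::aes(x = .data$log10_k, y = .data$log10_kstar, color = .data$group)
    } else {
      ggplot2::aes(x = .data$log10_k, y = .data$log10_kstar)
    }
    p <- p + ggplot2::geom_point(data = overlay, mapping = mapping,
                                 inherit.aes = FALSE, size = 1.5)
  }
  p
}
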