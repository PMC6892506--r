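#' Reduced Google matrix of a subset of nodes of interest
#'
#' For a subset `r` of `N_r` nodes embedded in a network of `N >> N_r` nodes,
#' the reduced Google matrix is the `N_r x N_r` column-stochastic matrix
#'
#'   `G_R = G_rr + G_rs (I - G_ss)^-1 G_sr`
#'
#' where `G` is partitioned into blocks over the subset (`r`) and its
#' complement (`s`). `G_R` sums the direct transitions between subset nodes
#' and every indirect pathway through the rest of the network, and its
#' stationary vector reproduces (up to normalisation) the restriction of the
#' global PageRank to the subset. `G_R` is further decomposed as
#' `G_R = G_rr + G_pr + G_qr`: `G_rr` is the literal sub-block of `G`
#' (direct links), `G_pr` the contribution of the leading spectral projector
#' of `G_ss` (a near rank-one matrix whose columns all approximate the
#' reduced PageRank), and `G_qr` the remainder carrying the indirect
#' "hidden link" information. `G_qr = G_qrd + G_qrnd` splits off the
#' self-interaction diagonal.
#'
#' Two backends are available. The dense backend materialises `G_ss` and uses
#' direct LAPACK solves; it is only allowed when the complement is small. The
#' iterative backend is matrix-free: the teleportation + dangling part of
#' `G_ss` is a rank-one matrix, so `(I - G_ss)^-1` is evaluated with a
#' Sherman-Morrison update around the sparse part `I - alpha S0_ss`, whose
#' geometric series contracts at rate `alpha` regardless of network size.
#' The leading eigenpair of `G_ss` (eigenvalue `lambda_c` and left/right
#' eigenvectors defining the projector) is obtained by power iteration.
#'
#' @param graph A `directed_graph`.
#' @param subset Integer vector of 0-based node ids (order is preserved in
#'   every reduced matrix), or a data frame with columns `node_id` and
#'   optionally `label`.
#' @param labels Optional display names aligned with `subset`.
#' @param alpha Damping factor in (0, 1).
#' @param tol Convergence threshold (L1 for fixed points, relative residual
#'   for the series solves).
#' @param max_iter Iteration cap for the global PageRank.
#' @param backend `"auto"` (dense when the complement has at most
#'   `dense_cap` nodes, iterative otherwise), `"dense"`, or `"iterative"`.
#' @param dense_cap Largest complement size for which the dense backend is
#'   allowed.
#' @param series_max Iteration cap for the series solves and eigen iterations.
#' @return An object of class `reduced_google` with matrices `G_R`, `G_rr`,
#'   `G_pr`, `G_qr`, `G_qrd`, `G_qrnd` (rows/columns in subset order), the
#'   reduced PageRank `p_r` (fixed point of `G_R`), the normalised
#'   restriction `p_global_r` of the global PageRank, the proportionality
#'   constant `kappa = 1 / sum(P[subset])`, the complement leading eigenvalue
#'   `lambda_c`, the logical direct-edge matrix `direct`, and diagnostics.
#' @examples
#' g <- directed_graph(data.frame(source = c(0, 1, 2, 3), target = c(1, 2, 0, 0)))
#' r <- reduce_google_matrix(g, subset = c(0, 1))
#' r$G_R
#' @export
reduce_google_matrix <- function(graph, subset, labels = NULL, alpha = 0.85,
                                 tol = 1e-12, max_iter = 1000,
                                 backend = c("auto", "iterative", "dense"),
                                 dense_cap = 2000, series_max = 100000) {
  stopifnot(inherits(graph, "directed_graph"))
  backend <- match.arg(backend)
  if (is.data.frame(subset)) {
    labels <- labels %||% subset$label
    subset <- subset$node_id
  }
  subset <- as.integer(subset)
  n <- graph$n_nodes
  n_r <- length(subset)
  if (n_r < 1L) abort("`subset` must contain at least one node.")
  if (anyDuplicated(subset)) abort("`subset` must not contain duplicates.")
  if (any(subset < 0L | subset >= n)) abort("`subset` ids out of range.")
  labels <- as.character(labels %||% subset)
  if (length(labels) != n_r) abort("`labels` must align with `subset`.")

  op <- google_operator(graph, alpha = alpha)
  pr_global <- pagerank(op, tol = tol, max_iter = max_iter)
  r <- subset + 1L
  s <- setdiff(seq_len(n), r)
  n_s <- length(s)

  # additive column constant of G: every entry of column j carries
  # (alpha * dangling_j + (1 - alpha)) / n on top of alpha * S0[, j]
  tcol <- (alpha * as.numeric(op$dangling) + (1 - alpha)) / n

  dn <- list(labels, labels)
  g_rr <- sweep(alpha * as.matrix(op$S0[r, r, drop = FALSE]), 2, tcol[r], "+")
  dimnames(g_rr) <- dn

  a <- adjacency_matrix(graph)
  direct <- as.matrix(a[r, r, drop = FALSE]) > 0
  dimnames(direct) <- dn

  if (n_s == 0L) {
    g_R <- g_rr
    zero <- matrix(0, n_r, n_r, dimnames = dn)
    p_r <- pagerank(g_R, tol = min(tol, 1e-13), max_iter = 50000)$probs
    res <- new_reduced_google(
      G_R = g_R, G_rr = g_rr, G_pr = zero, G_qr = zero,
      p_r = p_r, p_global_r = pr_global$probs[r] / sum(pr_global$probs[r]),
      kappa = 1 / sum(pr_global$probs[r]), lambda_c = NA_real_,
      subset = tibble(node_id = subset, label = labels),
      alpha = alpha, backend = "trivial", direct = direct
    )
    return(res)
  }

  s0_ss <- op$S0[s, s, drop = FALSE]
  s0_sr <- op$S0[s, r, drop = FALSE]
  s0_rs <- op$S0[r, s, drop = FALSE]
  t_s <- tcol[s]
  t_r <- tcol[r]

  g_sr <- sweep(alpha * as.matrix(s0_sr), 2, t_r, "+")

  # G_rs applied to an n_s x k dense matrix
  g_rs_mult <- function(x) {
    x <- as.matrix(x)
    sweep(alpha * as.matrix(s0_rs %*% x), 2, colSums(x * t_s), "+")
  }
  # G_ss and its transpose, matrix-free (rank-one teleport part analytic)
  g_ss_mult <- function(x) {
    x <- as.matrix(x)
    sweep(alpha * as.matrix(s0_ss %*% x), 2, colSums(x * t_s), "+")
  }
  g_ss_tmult <- function(x) {
    x <- as.matrix(x)
    alpha * as.matrix(Matrix::crossprod(s0_ss, x)) + outer(t_s, colSums(x))
  }

  use_dense <- backend == "dense" || (backend == "auto" && n_s <= dense_cap)
  if (backend == "dense" && n_s > dense_cap) {
    abort(sprintf("Dense backend refused: complement has %d > dense_cap = %d nodes.",
                  n_s, dense_cap))
  }

  eig <- power_eigenpair(g_ss_mult, g_ss_tmult, n_s, tol = tol,
                         max_iter = series_max)
  lambda_c <- eig$lambda
  psi_r <- eig$right
  psi_l <- eig$left
  plr <- sum(psi_l * psi_r)

  q_apply <- function(x) {
    x <- as.matrix(x)
    x - psi_r %*% (crossprod(psi_l, x) / plr)
  }

  if (use_dense) {
    g_ss <- sweep(alpha * as.matrix(s0_ss), 2, t_s, "+")
    x_sum <- solve(diag(n_s) - g_ss, g_sr)
    qb <- q_apply(g_sr)
    qgq <- q_apply(g_ss %*% q_apply(diag(n_s)))
    x_q <- solve(diag(n_s) - qgq, qb)
  } else {
    # (I - G_ss)^-1 via Sherman-Morrison around M = I - alpha S0_ss:
    # G_ss = alpha S0_ss + 1_s t_s^T, so
    # (I - G_ss)^-1 b = M^-1 b + M^-1 1 (t^T M^-1 b) / (1 - t^T M^-1 1)
    minv <- function(b) {
      x <- b
      term <- b
      for (i in seq_len(series_max)) {
        term <- alpha * as.matrix(s0_ss %*% term)
        x <- x + term
        if (max(abs(term)) < 0.01 * tol * max(1, max(abs(x)))) break
      }
      x
    }
    y <- minv(g_sr)
    z <- minv(matrix(1, n_s, 1))
    denom <- 1 - sum(t_s * z)
    x_sum <- y + z %*% (crossprod(t_s, y) / denom)
    # series for (I - Q G_ss Q)^-1 Q G_sr, contraction rate |lambda_2| < 1
    b <- q_apply(g_sr)
    x_q <- b
    term <- b
    for (i in seq_len(series_max)) {
      term <- q_apply(g_ss_mult(q_apply(term)))
      x_q <- x_q + term
      if (max(abs(term)) < 0.01 * tol * max(1, max(abs(x_q)))) break
    }
  }

  g_R <- g_rr + g_rs_mult(x_sum)
  u <- g_rs_mult(psi_r)                     # G_rs psi_R
  w <- drop(crossprod(psi_l, g_sr))         # psi_L^T G_sr
  g_pr <- (u %*% t(w)) / (plr * (1 - lambda_c))
  g_qr <- g_rs_mult(q_apply(x_q))
  dimnames(g_R) <- dimnames(g_pr) <- dimnames(g_qr) <- dn

  p_r <- pagerank(g_R, tol = min(tol, 1e-13), max_iter = 50000)$probs

  new_reduced_google(
    G_R = g_R, G_rr = g_rr, G_pr = g_pr, G_qr = g_qr,
    p_r = p_r,
    p_global_r = pr_global$probs[r] / sum(pr_global$probs[r]),
    kappa = 1 / sum(pr_global$probs[r]),
    lambda_c = lambda_c,
    subset = tibble(node_id = subset, label = labels),
    alpha = alpha,
    backend = if (use_dense) "dense" else "iterative",
    direct = direct
  )
}

new_reduced_google <- function(G_R, G_rr, G_pr, G_qr, p_r, p_global_r, kappa,
                               lambda_c, subset, alpha, backend, direct) {
  qr_parts <- split_qr(G_qr)
  # Negative G_qr entries are retained, never clipped (clipping would break
  # the additive decomposition). On PageRank-dominated networks they stay at
  # cancellation level; sizeable negatives signal a weakly separated leading
  # eigenvalue of the complement block, worth a look but not an error.
  neg <- min(G_qr, 0)
  if (neg < -1e-2) {
    warn(sprintf(
      "G_qr has negative entries down to %.3e; the indirect component is not PageRank-dominated here.",
      neg))
  }
  names(p_r) <- names(p_global_r) <- subset$label
  structure(
    list(
      G_R = G_R, G_rr = G_rr, G_pr = G_pr, G_qr = G_qr,
      G_qrd = qr_parts$G_qrd, G_qrnd = qr_parts$G_qrnd,
      p_r = p_r, p_global_r = p_global_r, kappa = kappa,
      lambda_c = lambda_c, subset = subset, alpha = alpha,
      backend = backend, direct = direct,
      colsum_err = max(abs(colSums(G_R) - 1)),
      decomp_err = max(abs(G_rr + G_pr + G_qr - G_R)),
      qr_min = min(G_qr)
    ),
    class = "reduced_google"
  )
}

# Leading eigenvalue and left/right eigenvectors of a nonnegative operator by
# power iteration with L1 normalisation (Perron vector, so entries stay >= 0).
power_eigenpair <- function(mult, tmult, n, tol = 1e-12, max_iter = 100000) {
  one_side <- function(f) {
    v <- rep(1 / n, n)
    lambda <- NA_real_
    for (i in seq_len(max_iter)) {
      w <- drop(f(v))
      lambda <- sum(abs(w))
      w <- w / lambda
      if (sum(abs(w - v)) < tol) {
        return(list(vec = w, lambda = lambda, iter = i))
      }
      v <- w
    }
    abort(sprintf("Power iteration for the complement eigenvector did not converge in %d iterations.",
                  max_iter))
  }
  rgt <- one_side(mult)
  lft <- one_side(tmult)
  list(right = rgt$vec, left = lft$vec, lambda = rgt$lambda,
       iter = c(rgt$iter, lft$iter))
}

#' Split an indirect-component matrix into diagonal and off-diagonal parts
#'
#' The diagonal of `G_qr` carries self-interactions of the subset nodes,
#' which are not informative for link inference; `G_qrnd` is the part used
#' for hidden-link screening. The two parts sum to the input exactly.
#'
#' @param G_qr A square matrix.
#' @return A list with `G_qrd` (diagonal part) and `G_qrnd` (off-diagonal).
#' @export
split_qr <- function(G_qr) {
  if (!is.matrix(G_qr) || nrow(G_qr) != ncol(G_qr)) {
    abort("`G_qr` must be a square matrix.")
  }
  d <- diag(diag(G_qr), nrow = nrow(G_qr))
  dimnames(d) <- dimnames(G_qr)
  list(G_qrd = d, G_qrnd = G_qr - d)
}

#' @export
print.reduced_google <- function(x, ...) {
  cat(sprintf(
    "<reduced_google: N_r = %d, alpha = %g, backend = %s>\n  lambda_c = %s, kappa = %.4g\n  max |colSums(G_R) - 1| = %.2e, max |G_rr+G_pr+G_qr - G_R| = %.2e\n",
    nrow(x$G_R), x$alpha, x$backend,
    format(x$lambda_c, digits = 6), x$kappa, x$colsum_err, x$decomp_err
  ))
  invisible(x)
}

#' @export
tidy.reduced_google <- function(x, ...) {
  comps <- c("G_R", "G_rr", "G_pr", "G_qr", "G_qrd", "G_qrnd")
  purrr::map_dfr(comps, function(cn) {
    m <- x[[cn]]
    tibble(
      component = cn,
      source = rep(colnames(m), each = nrow(m)),
      target = rep(rownames(m), times = ncol(m)),
      weight = as.vector(m)
    )
  })
}

#' @export
glance.reduced_google <- function(x, ...) {
  tibble(
    n_r = nrow(x$G_R),
    alpha = x$alpha,
    backend = x$backend,
    kappa = x$kappa,
    lambda_c = x$lambda_c,
    colsum_err = x$colsum_err,
    decomp_err = x$decomp_err,
    pagerank_consistency = max(abs(x$p_r - x$p_global_r) / pmax(x$p_global_r, .Machine$double.xmin))
  )
}

#' Strongest indirect (hidden) links between two node groups
#'
#' Screens the off-diagonal indirect component `G_qrnd` for the `k` largest
#' entries with source column in `from_group` and target row in `to_group`.
#' Each link is flagged `is_direct` according to whether the underlying
#' adjacency has the edge `source -> target`; a large `G_qrnd` weight with
#' `is_direct = FALSE` is a purely hidden link, carried only by multi-hop
#' pathways through the rest of the network.
#'
#' @param reduced A `reduced_google` object.
#' @param catalog Node catalog tibble with `node_id`, `name`, `group`.
#' @param from_group,to_group Group names resolved against the catalog.
#' @param k Number of links to return (all available if fewer).
#' @return A tibble `source,target,weight,is_direct` sorted by decreasing
#'   weight; empty when either group has no subset member.
#' @export
top_hidden_links <- function(reduced, catalog, from_group, to_group, k = 10) {
  stopifnot(inherits(reduced, "reduced_google"))
  pos <- function(grp) {
    ids <- catalog$node_id[catalog$group == grp]
    which(reduced$subset$node_id %in% ids)
  }
  from <- pos(from_group)
  to <- pos(to_group)
  empty <- tibble(source = character(), target = character(),
                  weight = double(), is_direct = logical())
  if (length(from) == 0 || length(to) == 0) return(empty)
  m <- reduced$G_qrnd[to, from, drop = FALSE]
  d <- reduced$direct[to, from, drop = FALSE]
  out <- tibble(
    source = rep(reduced$subset$label[from], each = length(to)),
    target = rep(reduced$subset$label[to], times = length(from)),
    weight = as.vector(m),
    is_direct = as.vector(d)
  )
  out <- out[out$source != out$target, ]
  out <- out[order(-out$weight, out$source, out$target), ]
  head(out, k)
}

#' Heatmap panels of a reduced Google matrix
#'
#' Renders the four matrices the analysis inspects (`G_R`, `G_rr`, `G_pr`,
#' `G_qrnd`) as color-mapped tiles in subset order, optionally drawing group
#' boundary squares from a catalog.
#'
#' @param object A `reduced_google` object.
#' @param catalog Optional catalog used to draw group boundaries.
#' @param components Which components to draw.
#' @param ... Unused.
#' @return A ggplot object faceted by component.
#' @export
autoplot.reduced_google <- function(object, catalog = NULL,
                                    components = c("G_R", "G_rr", "G_pr", "G_qrnd"),
                                    ...) {
  lv <- object$subset$label
  df <- tidy(object)
  df <- df[df$component %in% components, ]
  df$component <- factor(df$component, levels = components)
  df$source <- factor(df$source, levels = lv)
  df$target <- factor(df$target, levels = rev(lv))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                        fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "source (column)", y = "target (row)", fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  if (!is.null(catalog)) {
    grp <- catalog$group[match(object$subset$node_id, catalog$node_id)]
    bounds <- cumsum(rle(grp)$lengths)
    starts <- c(0, head(bounds, -1))
    n_r <- length(lv)
    sq <- tibble(
      xmin = starts + 0.5, xmax = bounds + 0.5,
      ymin = n_r - bounds + 0.5, ymax = n_r - starts + 0.5
    )
    p <- p + ggplot2::geom_rect(
      data = sq,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, color = "white", linewidth = 0.3
    )
  }
  p
}

#' Write and read a reduced matrix set as plain-text artifacts
#'
#' Each component is written as a labeled CSV and a MatrixMarket file; the
#' subset, scalars and the direct-edge matrix go into a JSON sidecar so a
#' set can be reloaded losslessly for downstream stages.
#'
#' @param reduced A `reduced_google` object.
#' @param dir Output directory (created if needed).
#' @return `write_reduced_set()` returns `dir` invisibly;
#'   `read_reduced_set()` returns a `reduced_google`.
#' @export
write_reduced_set <- function(reduced, dir) {
  stopifnot(inherits(reduced, "reduced_google"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in c("G_R", "G_rr", "G_pr", "G_qr")) {
    write_matrix_csv(reduced[[cn]], file.path(dir, paste0(cn, ".csv")))
    writeMM(methods::as(reduced[[cn]], "CsparseMatrix"),
            file.path(dir, paste0(cn, ".mtx")))
  }
  meta <- list(
    subset = reduced$subset,
    p_r = unname(reduced$p_r),
    p_global_r = unname(reduced$p_global_r),
    kappa = reduced$kappa,
    lambda_c = reduced$lambda_c,
    alpha = reduced$alpha,
    backend = reduced$backend,
    direct = unname(apply(reduced$direct, 2, as.logical))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_reduced_set
#' @export
read_reduced_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  subset <- as_tibble(meta$subset)
  mats <- lapply(c("G_R", "G_rr", "G_pr", "G_qr"), function(cn) {
    read_matrix_csv(file.path(dir, paste0(cn, ".csv")))
  })
  names(mats) <- c("G_R", "G_rr", "G_pr", "G_qr")
  direct <- matrix(as.logical(meta$direct), nrow = nrow(subset))
  dimnames(direct) <- dimnames(mats$G_R)
  new_reduced_google(
    G_R = mats$G_R, G_rr = mats$G_rr, G_pr = mats$G_pr, G_qr = mats$G_qr,
    p_r = meta$p_r, p_global_r = meta$p_global_r, kappa = meta$kappa,
    lambda_c = meta$lambda_c %||% NA_real_,
    subset = subset, alpha = meta$alpha, backend = meta$backend,
    direct = direct
  )
}
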