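#' Friendship-network extraction from a reduced Google matrix
#'
#' Starting from the top-PageRank nodes of a seed group (e.g. pharmaceutical
#' companies), the network is grown iteratively: every newly added seed-group
#' node contributes its `n_friends` strongest same-group couplings and its
#' `n_partners` strongest partner-group couplings, where the coupling
#' strength of candidate `t` for source `s` is the `(t, s)` entry of
#' `G_rr + G_qr` with the self-interaction diagonal excluded (i.e.
#' `G_rr + G_qrnd`). Newly added same-group nodes are processed in the next
#' iteration; the process stops when an iteration adds no new same-group
#' node, which bounds the iteration count by the group size. Each traced
#' edge is flagged direct when the underlying adjacency contains
#' `source -> target`, and hidden otherwise.
#'
#' Ties in coupling strength are broken by the better (smaller) relative
#' PageRank position of the candidate, then by ascending label, so the
#' extraction is fully deterministic.
#'
#' @param reduced A `reduced_google` object.
#' @param catalog Node catalog tibble with `node_id`, `name`, `group`.
#' @param seed_group Group whose top-ranked members seed the expansion.
#' @param partner_group Group contributing partner links at each step.
#' @param n_seeds Number of seeds (clamped to the group size with a warning).
#' @param n_friends Same-group links traced per processed node.
#' @param n_partners Partner-group links traced per processed node.
#' @return An object of class `friend_network` with tibbles `nodes`
#'   (`label,group,iteration_added,seed`; seeds carry `iteration_added = 0`)
#'   and `edges` (`source,target,weight,is_direct,iteration`).
#' @export
build_friend_network <- function(reduced, catalog, seed_group, partner_group,
                                 n_seeds = 5, n_friends = 2, n_partners = 2) {
  stopifnot(inherits(reduced, "reduced_google"))
  sub <- reduced$subset
  grp <- catalog$group[match(sub$node_id, catalog$node_id)]
  seed_pos <- which(grp == seed_group)
  partner_pos <- which(grp == partner_group)
  if (length(seed_pos) == 0 || length(partner_pos) == 0) {
    abort("Both `seed_group` and `partner_group` must be present in the subset.")
  }
  if (n_seeds > length(seed_pos)) {
    warn(sprintf("n_seeds = %d exceeds the %d members of '%s'; clamped.",
                 n_seeds, length(seed_pos), seed_group))
    n_seeds <- length(seed_pos)
  }

  w <- reduced$G_rr + reduced$G_qrnd
  # relative PageRank position within each group (1 = best), used both for
  # seed selection and for deterministic tie-breaking
  rel_rank <- rep(NA_integer_, nrow(sub))
  for (g in unique(grp[!is.na(grp)])) {
    pos <- which(grp == g)
    rel_rank[pos[order(-reduced$p_r[pos], sub$label[pos])]] <- seq_along(pos)
  }
  seeds <- seed_pos[order(rel_rank[seed_pos])][seq_len(n_seeds)]

  pick_top <- function(cands, s, n_pick) {
    cands <- setdiff(cands, s)
    if (length(cands) == 0) return(integer())
    str <- w[cands, s]
    tie_rank <- rel_rank[cands]
    tie_rank[is.na(tie_rank)] <- .Machine$integer.max
    o <- order(-str, tie_rank, sub$label[cands])
    cands[o[seq_len(min(n_pick, length(cands)))]]
  }

  node_lab <- sub$label
  added <- seeds
  iter_added <- setNames(rep(0L, length(seeds)), node_lab[seeds])
  edges <- list()
  queue <- seeds
  iteration <- 0L
  while (length(queue) > 0) {
    iteration <- iteration + 1L
    next_queue <- integer()
    for (s in queue) {
      for (spec in list(list(cands = seed_pos, n = n_friends, same = TRUE),
                        list(cands = partner_pos, n = n_partners, same = FALSE))) {
        chosen <- pick_top(spec$cands, s, spec$n)
        for (t in chosen) {
          edges[[length(edges) + 1L]] <- tibble(
            source = node_lab[s], target = node_lab[t],
            weight = w[t, s], is_direct = reduced$direct[t, s],
            iteration = iteration
          )
          if (!(t %in% added)) {
            added <- c(added, t)
            iter_added[node_lab[t]] <- iteration
            if (spec$same) next_queue <- c(next_queue, t)
          }
        }
      }
    }
    queue <- next_queue
  }

  nodes <- tibble(
    label = node_lab[added],
    group = grp[added],
    iteration_added = unname(iter_added[node_lab[added]]),
    seed = added %in% seeds
  )
  structure(
    list(
      nodes = nodes,
      edges = dplyr::bind_rows(edges),
      n_iterations = iteration,
      params = list(seed_group = seed_group, partner_group = partner_group,
                    n_seeds = n_seeds, n_friends = n_friends,
                    n_partners = n_partners)
    ),
    class = "friend_network"
  )
}

#' @export
print.friend_network <- function(x, ...) {
  cat(sprintf(
    "<friend_network: %d nodes (%d seeds), %d edges (%d hidden), %d iterations>\n",
    nrow(x$nodes), sum(x$nodes$seed), nrow(x$edges),
    sum(!x$edges$is_direct), x$n_iterations
  ))
  invisible(x)
}

#' @export
tidy.friend_network <- function(x, ...) {
  x$edges
}

#' @export
glance.friend_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_seed_group = sum(x$nodes$group == x$params$seed_group),
    n_partner_group = sum(x$nodes$group == x$params$partner_group),
    n_edges = nrow(x$edges),
    n_hidden = sum(!x$edges$is_direct),
    n_iterations = x$n_iterations
  )
}

as_igraph_friend <- function(fn) {
  ed <- fn$edges
  ed$color <- ifelse(ed$is_direct, "black", "red")
  igraph::graph_from_data_frame(
    d = ed[c("source", "target", "weight", "is_direct", "iteration", "color")],
    directed = TRUE,
    vertices = fn$nodes[c("label", "group", "iteration_added", "seed")]
  )
}

#' Export a friendship network to GraphML, DOT, or CSV
#'
#' Node attributes carry `group`, `iteration_added` and the seed flag; edge
#' attributes carry the coupling weight, the direct/hidden flag and the
#' iteration at which the edge was traced. Hidden edges are color-attributed
#' red, direct ones black.
#'
#' @param fn A `friend_network`.
#' @param path Output file.
#' @param format `"graphml"`, `"dot"`, or `"csv"` (edge list).
#' @export
export_friend_network <- function(fn, path, format = c("graphml", "dot", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(fn$edges, path)
  } else {
    igraph::write_graph(as_igraph_friend(fn), path, format = format)
  }
  invisible(path)
}
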