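#' Read and write edge lists
#'
#' Edge lists are two-column tab-separated files, `source<TAB>target`, one
#' directed edge per line, 0-based integer node ids. Lines starting with `#`
#' are comments. Duplicate edges are collapsed with a warning when the graph
#' is built.
#'
#' @param path File path.
#' @param n_nodes Optional node count override (see [directed_graph()]).
#' @return `read_edge_list()` returns a `directed_graph`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(directed_graph(tibble(source = integer(), target = integer()),
                          n_nodes = n_nodes))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge list %s: line %d has %d fields (expected 2): '%s'",
      path, bad[1], lengths(parts)[bad[1]], lines[bad[1]]
    ))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf("Malformed edge list %s: non-integer node id on line %d.",
                  path, which(is.na(m[, 1]) | is.na(m[, 2]))[1]))
  }
  directed_graph(tibble(source = m[, 1], target = m[, 2]), n_nodes = n_nodes)
}

#' @rdname read_edge_list
#' @param graph A `directed_graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "directed_graph"))
  readr::write_tsv(graph$edges, path, col_names = FALSE)
  invisible(path)
}

#' Read and write graphs in MatrixMarket coordinate format
#'
#' The adjacency matrix is stored with 1-based indices as mandated by the
#' MatrixMarket standard; node ids are shifted back to 0-based on read.
#'
#' @param path File path (`.mtx`).
#' @return `read_mm_graph()` returns a `directed_graph`; `write_mm_graph()`
#'   returns `path` invisibly.
#' @export
read_mm_graph <- function(path) {
  a <- methods::as(readMM(path), "TsparseMatrix")
  if (nrow(a) != ncol(a)) {
    abort("MatrixMarket adjacency must be square.")
  }
  # stored as A[i, j] != 0 <=> edge j -> i
  directed_graph(tibble(source = a@j, target = a@i), n_nodes = nrow(a))
}

#' @rdname read_mm_graph
#' @param graph A `directed_graph`.
#' @export
write_mm_graph <- function(graph, path) {
  writeMM(adjacency_matrix(graph), path)
  invisible(path)
}

#' Read and write node catalogs
#'
#' A node catalog assigns each node a display name and a group. Groups follow
#' the study design: `country`, `company`, `cancer`, `rare_renal_disease`, or
#' `other`; the `category` column is nonempty only for rare renal diseases
#' (their five clinical classes).
#'
#' @param path CSV file with header `node_id,name,group,category`.
#' @return A tibble with columns `node_id` (0-based integer), `name`,
#'   `group`, `category`.
#' @export
read_node_catalog <- function(path) {
  cat_groups <- c("country", "company", "cancer", "rare_renal_disease", "other")
  x <- readr::read_csv(path, col_types = readr::cols(
    node_id = readr::col_integer(),
    name = readr::col_character(),
    group = readr::col_character(),
    category = readr::col_character()
  ))
  x$category[is.na(x$category)] <- ""
  bad <- setdiff(unique(x$group), cat_groups)
  if (length(bad) > 0) {
    abort(sprintf("Unknown group(s) in catalog: %s", paste(bad, collapse = ", ")))
  }
  if (any(x$category != "" & x$group != "rare_renal_disease")) {
    abort("`category` must be empty except for rare_renal_disease nodes.")
  }
  if (anyDuplicated(x$node_id)) {
    abort("Duplicate node_id in catalog.")
  }
  x
}

#' @rdname read_node_catalog
#' @param catalog A catalog tibble.
#' @export
write_node_catalog <- function(catalog, path) {
  readr::write_csv(catalog[c("node_id", "name", "group", "category")], path)
  invisible(path)
}

#' Write a PageRank/CheiRank table to CSV
#'
#' @param ranks A tibble with columns `node_id,name,P,K,Pstar,Kstar`, as
#'   produced by [rank_table()].
#' @param path Output CSV path.
#' @export
write_rank_table <- function(ranks, path) {
  readr::write_csv(ranks[c("node_id", "name", "P", "K", "Pstar", "Kstar")], path)
  invisible(path)
}

#' Write a labeled dense matrix as CSV
#'
#' Rows and columns keep the subset order of the reduced matrices; the first
#' column holds row labels.
#'
#' @param m A matrix with dimnames.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(row = rownames(m) %||% as.character(seq_len(nrow(m))), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    row = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[-1])
  rownames(m) <- df$row
  m
}
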