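#' Run the full analysis pipeline from a configuration
#'
#' Executes, per configuration: input loading (or synthetic generation),
#' global ranking, reduced-matrix computation, and any of the stats,
#' sensitivity and friendship-network stages, writing plain-text artifacts
#' (CSV / MatrixMarket / GraphML) plus a machine-readable run manifest with
#' versions, seed, parameters and input digests. Any stage failure raises an
#' error tagged with the stage name.
#'
#' The configuration is a nested list (or a YAML file with the same shape):
#'
#' * `input`: `edges` (TSV edge list) or `mm` (MatrixMarket), plus `catalog`
#'   (CSV); alternatively `simulate`: arguments for [layered_config()].
#' * `params`: `alpha`, `tol`, `max_iter`.
#' * `stages`: subset of `rank`, `reduce`, `stats`, `sensitivity`, `friends`.
#' * `subset_groups`: catalog groups forming the nodes of interest.
#' * `stats`: `table` (CSV path, or `"companies"` / `"diseases"` for the
#'   packaged tables), `pairs` (e.g. `"K_r:K_LMC"`), `overlap` (prefix sizes).
#' * `sensitivity`: `source` (label), `targets_group`, `delta`, `method`.
#' * `friends`: `seed_group`, `partner_group`, `n_seeds`, `n_friends`,
#'   `n_partners`.
#' * `out_dir`, `seed`, `verbose`.
#'
#' @param config A list or a YAML file path.
#' @return Invisibly, a list with the artifact paths and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- config$verbose %||% TRUE
  log_msg <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)), parent = e)
    })
  }
  params <- modifyList(list(alpha = 0.85, tol = 1e-12, max_iter = 1000),
                       config$params %||% list())
  stages <- config$stages %||% c("rank", "reduce")
  artifacts <- list()
  digests <- list()

  # ---- input ----------------------------------------------------------
  graph <- catalog <- NULL
  if (!is.null(config$simulate)) {
    stage("simulate", {
      sim_args <- config$simulate
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      if (!is.null(sim_args$planted_hidden)) {
        sim_args$planted_hidden <- dplyr::bind_rows(sim_args$planted_hidden)
      }
      net <- generate_layered_network(do.call(layered_config, sim_args))
      graph <- net$graph
      catalog <- net$catalog
      artifacts$edges <- write_edge_list(graph, file.path(out_dir, "edges.tsv"))
      artifacts$catalog <- write_node_catalog(catalog, file.path(out_dir, "catalog.csv"))
      log_msg("simulate", "generated %d nodes / %d edges (seed %s)",
              graph$n_nodes, nrow(graph$edges), format(net$config$seed))
    })
  } else if (!is.null(config$input)) {
    stage("input", {
      inp <- config$input
      graph <- if (!is.null(inp$mm)) read_mm_graph(inp$mm) else read_edge_list(inp$edges)
      for (f in c(inp$edges, inp$mm, inp$catalog)) {
        digests[[basename(f)]] <- unname(tools::md5sum(f))
      }
      if (!is.null(inp$catalog)) catalog <- read_node_catalog(inp$catalog)
      log_msg("input", "loaded %d nodes / %d edges", graph$n_nodes, nrow(graph$edges))
    })
  }

  # ---- rank -----------------------------------------------------------
  if ("rank" %in% stages && !is.null(graph)) {
    stage("rank", {
      rt <- rank_table(graph, catalog, alpha = params$alpha, tol = params$tol,
                       max_iter = params$max_iter)
      artifacts$ranks <- write_rank_table(rt, file.path(out_dir, "ranks.csv"))
      log_msg("rank", "wrote ranks.csv (top node: %s)", rt$name[which.min(rt$K)])
    })
  }

  # ---- reduce ---------------------------------------------------------
  reduced <- NULL
  if ("reduce" %in% stages && !is.null(graph)) {
    stage("reduce", {
      groups <- config$subset_groups %||% unique(catalog$group[catalog$group != "other"])
      sel <- catalog[catalog$group %in% groups, ]
      sel <- sel[order(match(sel$group, groups), sel$node_id), ]
      reduced <- reduce_google_matrix(
        graph, subset = sel$node_id, labels = sel$name,
        alpha = params$alpha, tol = params$tol, max_iter = params$max_iter
      )
      artifacts$reduced <- write_reduced_set(reduced, file.path(out_dir, "reduced"))
      log_msg("reduce", "N_r = %d, lambda_c = %.6f, colsum err %.1e",
              nrow(reduced$G_R), reduced$lambda_c, reduced$colsum_err)
    })
  } else if (!is.null(config$reduced_dir)) {
    reduced <- stage("reduce", read_reduced_set(config$reduced_dir))
  }

  # ---- stats ----------------------------------------------------------
  if ("stats" %in% stages) {
    stage("stats", {
      sc <- config$stats %||% list()
      tab <- sc$table %||% "companies"
      ranks <- if (identical(tab, "companies")) {
        load_paper_tables()$companies
      } else if (identical(tab, "diseases")) {
        load_paper_tables()$diseases
      } else {
        readr::read_csv(tab, col_types = readr::cols())
      }
      pairs <- sc$pairs %||% {
        rc <- setdiff(names(ranks)[vapply(ranks, is.numeric, logical(1))], "node_id")
        utils::combn(rc, 2, paste, collapse = ":")
      }
      rows <- purrr::map_dfr(pairs, function(pp) {
        cols <- strsplit(pp, ":", fixed = TRUE)[[1]]
        tibble(pair = pp, rho = spearman_rho(ranks[[cols[1]]], ranks[[cols[2]]]))
      })
      artifacts$stats <- file.path(out_dir, "stats.csv")
      readr::write_csv(rows, artifacts$stats)
      if (!is.null(sc$overlap)) {
        ov <- purrr::map_dfr(pairs, function(pp) {
          cols <- strsplit(pp, ":", fixed = TRUE)[[1]]
          la <- ranks$name[order(ranks[[cols[1]]])]
          lb <- ranks$name[order(ranks[[cols[2]]])]
          tibble(pair = pp, j = as.integer(sc$overlap),
                 eta = rank_overlap(la, lb, as.integer(sc$overlap)))
        })
        artifacts$overlap <- file.path(out_dir, "overlap.csv")
        readr::write_csv(ov, artifacts$overlap)
      }
      log_msg("stats", "wrote %d correlation pair(s)", nrow(rows))
    })
  }

  # ---- sensitivity ----------------------------------------------------
  if ("sensitivity" %in% stages) {
    stage("sensitivity", {
      if (is.null(reduced)) abort("sensitivity stage needs a reduced matrix set.")
      sc <- config$sensitivity
      if (is.null(sc$source)) abort("sensitivity stage needs `source`.")
      grp_lab <- if (!is.null(sc$targets_group) && !is.null(catalog)) {
        ids <- catalog$node_id[catalog$group == sc$targets_group]
        reduced$subset$label[reduced$subset$node_id %in% ids]
      } else sc$targets
      prof <- sensitivity_profile(reduced, source = sc$source, targets = grp_lab,
                                  delta = sc$delta %||% 1e-4,
                                  method = sc$method %||% "fd")
      artifacts$sensitivity <- file.path(out_dir, "sensitivity.csv")
      readr::write_csv(prof, artifacts$sensitivity)
      log_msg("sensitivity", "profile of %s over %d target(s)",
              sc$source, nrow(prof))
    })
  }

  # ---- friends --------------------------------------------------------
  if ("friends" %in% stages) {
    stage("friends", {
      if (is.null(reduced)) abort("friends stage needs a reduced matrix set.")
      if (is.null(catalog)) abort("friends stage needs a catalog.")
      fc <- config$friends %||% list()
      fn <- build_friend_network(
        reduced, catalog,
        seed_group = fc$seed_group %||% "company",
        partner_group = fc$partner_group %||% "country",
        n_seeds = fc$n_seeds %||% 5, n_friends = fc$n_friends %||% 2,
        n_partners = fc$n_partners %||% 2
      )
      artifacts$friends_csv <- export_friend_network(
        fn, file.path(out_dir, "friends.csv"), "csv")
      artifacts$friends_graphml <- export_friend_network(
        fn, file.path(out_dir, "friends.graphml"), "graphml")
      log_msg("friends", "%d nodes, %d edges, %d iterations",
              nrow(fn$nodes), nrow(fn$edges), fn$n_iterations)
    })
  }

  manifest <- list(
    package = "regomax",
    version = as.character(utils::packageVersion("regomax")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    params = params,
    stages = stages,
    input_digests = digests,
    artifacts = lapply(artifacts, as.character)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(artifacts = artifacts, manifest = manifest))
}
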