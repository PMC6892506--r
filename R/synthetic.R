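#' Configuration for the layered synthetic network generator
#'
#' The generator emulates, at desk scale, the statistical structure the
#' analysis assumes of an encyclopedia hyperlink network: a large
#' heavy-tailed background wired by directed preferential attachment, a
#' high-centrality "country-like" group drawing many background in-links, a
#' mid-centrality, densely inter-linked "company-like" group, a
#' low-centrality "disease-like" group with only a handful of links, and
#' optional planted two-hop indirect paths (company -> fresh intermediaries
#' -> disease) with no direct company -> disease edge, so that hidden-link
#' recovery can be tested against known ground truth.
#'
#' @param n_background Background node count.
#' @param n_country,n_company,n_disease Group sizes.
#' @param m_out,m_in Preferential-attachment out/in stubs per new background
#'   node.
#' @param attachment_exponent Preferential-attachment strength (1 = linear).
#' @param intra_company_density Probability of each ordered company-company
#'   direct edge.
#' @param country_in_frac Fraction of background nodes linking in to each
#'   country-like node.
#' @param company_in_frac Fraction of background nodes linking in to each
#'   company-like node.
#' @param disease_in_links Background in-links per disease-like node.
#' @param planted_hidden Data frame `source,n_intermediaries,target` with
#'   1-based indices into the company and disease groups; each row plants
#'   `n_intermediaries` fresh nodes between that company and disease.
#' @param seed RNG seed; identical configurations generate identical graphs.
#' @return A `generator_config` list.
#' @export
layered_config <- function(n_background = 5000, n_country = 20, n_company = 10,
                           n_disease = 10, m_out = 5, m_in = 2,
                           attachment_exponent = 1,
                           intra_company_density = 0.3,
                           country_in_frac = 0.05, company_in_frac = 0.005,
                           disease_in_links = 3,
                           planted_hidden = NULL, seed = 42) {
  cfg <- list(
    n_background = as.integer(n_background), n_country = as.integer(n_country),
    n_company = as.integer(n_company), n_disease = as.integer(n_disease),
    m_out = as.integer(m_out), m_in = as.integer(m_in),
    attachment_exponent = attachment_exponent,
    intra_company_density = intra_company_density,
    country_in_frac = country_in_frac, company_in_frac = company_in_frac,
    disease_in_links = as.integer(disease_in_links),
    planted_hidden = if (is.null(planted_hidden)) NULL else as_tibble(planted_hidden),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_background >= 2, n_country >= 0, n_company >= 0, n_disease >= 0,
              m_out >= 1, m_in >= 0,
              intra_company_density >= 0, intra_company_density <= 1,
              country_in_frac >= 0, country_in_frac <= 1,
              company_in_frac >= 0, company_in_frac <= 1)
  })
  ph <- cfg$planted_hidden
  if (!is.null(ph) && nrow(ph) > 0) {
    if (any(ph$source < 1 | ph$source > cfg$n_company)) {
      abort("Planted path sources must index the company-like group.")
    }
    if (any(ph$target < 1 | ph$target > cfg$n_disease)) {
      abort("Planted path targets must index the disease-like group.")
    }
  }
  structure(cfg, class = "generator_config")
}

#' Generate a layered synthetic network with a node catalog
#'
#' See [layered_config()] for the structure being emulated. The generator is
#' deterministic for a given configuration (including the seed) and never
#' creates a direct company -> disease edge, so any strong company -> disease
#' entry of the indirect component is attributable to pathways through the
#' background or the planted intermediaries.
#'
#' @param config A `generator_config`.
#' @return A list with `graph` (a `directed_graph`) and `catalog` (a node
#'   catalog tibble; background and intermediary nodes carry group `other`,
#'   disease-like nodes group `rare_renal_disease` with one of the five
#'   disease categories cycled through).
#' @export
generate_layered_network <- function(config = layered_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nb <- config$n_background
  chunk_cap <- 4L * nb + 4096L
  src <- vector("list", chunk_cap)
  dst <- vector("list", chunk_cap)
  n_chunks <- 0L
  push <- function(s, t) {
    n_chunks <<- n_chunks + 1L
    src[[n_chunks]] <<- as.integer(s)
    dst[[n_chunks]] <<- as.integer(t)
  }

  # --- background: directed preferential attachment (1-based ids for now)
  in_deg <- numeric(nb)
  out_deg <- numeric(nb)
  push(1L, 2L); push(2L, 1L)
  in_deg[1:2] <- 1; out_deg[1:2] <- 1
  expo <- config$attachment_exponent
  for (t in 3:nb) {
    prev <- seq_len(t - 1L)
    k_out <- min(config$m_out, t - 1L)
    w_in <- (in_deg[prev] + 1)^expo
    tgt <- sample(prev, k_out, prob = w_in)
    push(rep(t, k_out), tgt)
    out_deg[t] <- out_deg[t] + k_out
    in_deg[tgt] <- in_deg[tgt] + 1
    if (config$m_in > 0) {
      k_in <- min(config$m_in, t - 1L)
      w_out <- (out_deg[prev] + 1)^expo
      srcs <- sample(prev, k_in, prob = w_out)
      push(srcs, rep(t, k_in))
      in_deg[t] <- in_deg[t] + k_in
      out_deg[srcs] <- out_deg[srcs] + 1
    }
  }

  id0 <- nb
  country <- id0 + seq_len(config$n_country)
  id0 <- id0 + config$n_country
  company <- id0 + seq_len(config$n_company)
  id0 <- id0 + config$n_company
  disease <- id0 + seq_len(config$n_disease)
  id0 <- id0 + config$n_disease

  # --- country-like: many background in-links, a few out-links
  n_cin <- max(1L, round(config$country_in_frac * nb))
  for (c in country) {
    push(sample(nb, n_cin), rep(c, n_cin))
    out_bg <- sample(nb, min(5L, nb))
    push(rep(c, length(out_bg)), out_bg)
  }

  # --- company-like: moderate background in-links, dense intra-group links,
  #     out-links to countries and background (never to diseases)
  n_phin <- max(1L, round(config$company_in_frac * nb))
  for (p in company) {
    push(sample(nb, n_phin), rep(p, n_phin))
    if (config$n_country > 0) {
      cts <- sample(country, min(2L, config$n_country))
      push(rep(p, length(cts)), cts)
    }
    push(p, sample(nb, 1L))
  }
  if (config$n_company > 1 && config$intra_company_density > 0) {
    pairs <- expand.grid(s = company, t = company)
    pairs <- pairs[pairs$s != pairs$t, ]
    keep <- stats::runif(nrow(pairs)) < config$intra_company_density
    if (any(keep)) push(pairs$s[keep], pairs$t[keep])
  }

  # --- disease-like: few links of either kind
  for (d in disease) {
    push(sample(nb, min(config$disease_in_links, nb)), rep(d, min(config$disease_in_links, nb)))
    push(d, sample(nb, 1L))
  }

  # --- planted 2-hop hidden paths through fresh intermediaries
  inter <- integer(0)
  ph <- config$planted_hidden
  if (!is.null(ph) && nrow(ph) > 0) {
    for (i in seq_len(nrow(ph))) {
      ims <- id0 + seq_len(ph$n_intermediaries[i])
      id0 <- id0 + ph$n_intermediaries[i]
      inter <- c(inter, ims)
      push(rep(company[ph$source[i]], length(ims)), ims)
      push(ims, rep(disease[ph$target[i]], length(ims)))
    }
  }

  edges <- dplyr::distinct(tibble(
    source = unlist(src[seq_len(n_chunks)]) - 1L,
    target = unlist(dst[seq_len(n_chunks)]) - 1L
  ))
  graph <- suppressWarnings(directed_graph(edges, n_nodes = id0))

  categories <- c("congenital", "glomerular", "tubular_metabolic",
                  "nephrolithiasis", "ciliopathies")
  catalog <- tibble(
    node_id = seq_len(id0) - 1L,
    name = c(
      sprintf("bg_%04d", seq_len(nb)),
      sprintf("country_%02d", seq_len(config$n_country)),
      sprintf("company_%02d", seq_len(config$n_company)),
      sprintf("disease_%02d", seq_len(config$n_disease)),
      sprintf("im_%04d", seq_along(inter))
    ),
    group = c(
      rep("other", nb),
      rep("country", config$n_country),
      rep("company", config$n_company),
      rep("rare_renal_disease", config$n_disease),
      rep("other", length(inter))
    ),
    category = c(
      rep("", nb + config$n_country + config$n_company),
      rep(categories, length.out = config$n_disease),
      rep("", length(inter))
    )
  )
  list(graph = graph, catalog = catalog, config = config)
}

#' Tiny closed-form test networks with attached PageRank oracles
#'
#' Returns a named list of graphs of at most ten nodes (cycle, chain, star,
#' complete, and a graph with a dangling node), each carrying a `pagerank`
#' attribute computed at build time by a dense least-squares solve of the
#' stationary equation, independent of the package's power iteration.
#'
#' @param alpha Damping factor used for the attached oracles.
#' @return Named list; each element is a `directed_graph` with attributes
#'   `pagerank` (oracle stationary vector) and `alpha`.
#' @export
tiny_fixtures <- function(alpha = 0.85) {
  make <- function(s, t, n) {
    g <- directed_graph(tibble(source = s, target = t), n_nodes = n)
    gm <- as.matrix(google_operator(g, alpha = alpha))
    attr(g, "pagerank") <- drop(qr.solve(rbind(diag(n) - gm, rep(1, n)),
                                         c(rep(0, n), 1)))
    attr(g, "alpha") <- alpha
    g
  }
  co <- expand.grid(s = 0:3, t = 0:3)
  co <- co[co$s != co$t, ]
  list(
    cycle3 = make(c(0L, 1L, 2L), c(1L, 2L, 0L), 3L),
    chain3 = make(c(0L, 1L), c(1L, 2L), 3L),
    star3 = make(c(1L, 2L), c(0L, 0L), 3L),
    complete4 = make(as.integer(co$s), as.integer(co$t), 4L),
    dangling4 = make(c(0L, 0L, 1L), c(1L, 2L, 2L), 4L)
  )
}

#' Load the packaged study rank tables
#'
#' Returns the two printed rank tables shipped with the package: the 34
#' largest pharmaceutical companies with their relative PageRank (`K_r`),
#' relative CheiRank (`K_r_star`), largest-market-capitalization (`K_LMC`)
#' and 2017 market-capitalization (`K_MC`) ranks, and the 47 rare renal
#' diseases with `K_r`, `K_r_star` and a clinical category. Every rank
#' column is validated as a permutation; a corrupted fixture is rejected.
#'
#' The company rank columns are transcribed from the printed table; the
#' disease category column is a reconstruction from the standard clinical
#' classification of these diseases (the printed table encodes it only as
#' row colors).
#'
#' @param dir Directory holding the two CSVs; defaults to the copies shipped
#'   in the package.
#' @return A list with tibbles `companies` (34 rows) and `diseases` (47 rows).
#' @export
load_paper_tables <- function(dir = NULL) {
  path <- function(f) {
    if (is.null(dir)) system.file("extdata", f, package = "regomax", mustWork = TRUE)
    else file.path(dir, f)
  }
  companies <- readr::read_csv(path("companies.csv"), col_types = readr::cols(
    name = readr::col_character(), .default = readr::col_integer()
  ))
  diseases <- readr::read_csv(path("renal_diseases.csv"), col_types = readr::cols(
    name = readr::col_character(), short_name = readr::col_character(),
    category = readr::col_character(), .default = readr::col_integer()
  ))
  check_perm <- function(df, cols, what) {
    for (cc in cols) {
      if (!setequal(df[[cc]], seq_len(nrow(df)))) {
        abort(sprintf("Corrupted fixture: column %s of the %s table is not a permutation of 1..%d.",
                      cc, what, nrow(df)))
      }
    }
  }
  if (nrow(companies) != 34) abort("Corrupted fixture: expected 34 companies.")
  if (nrow(diseases) != 47) abort("Corrupted fixture: expected 47 diseases.")
  check_perm(companies, c("K_r", "K_r_star", "K_LMC", "K_MC"), "company")
  check_perm(diseases, c("K_r", "K_r_star"), "disease")
  list(companies = companies, diseases = diseases)
}

#' Sizes of the study's groups of nodes of interest
#'
#' The analysis selects 195 countries, 34 pharmaceutical companies, 47 rare
#' renal diseases and 37 cancer types among the encyclopedia articles,
#' 313 nodes of interest in total.
#'
#' @return A tibble `group,n`.
#' @export
interest_group_sizes <- function() {
  tibble(
    group = c("country", "company", "rare_renal_disease", "cancer"),
    n = c(195L, 34L, 47L, 37L)
  )
}
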