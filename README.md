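# regomax

Reduced Google matrix (REGOMAX) analysis of directed knowledge networks in
R: who interacts with whom — directly or through hidden, multi-hop
pathways — inside a small set of nodes of interest embedded in a much
larger network.

The motivating application is the hyperlink network of encyclopedia
articles about pharmaceutical companies, world countries, cancers, and
rare renal diseases: companies almost never cite an orphan disease
directly, yet their articles are connected through biographies,
subsidiaries, and drug pages. The reduced Google matrix makes those
indirect couplings quantitative. The same machinery applies to any
directed network with a distinguished subset: protein–protein interaction
neighbourhoods, citation subfields, trade partners.

## The method

For a network with Google matrix `G = α S + (1 − α)/N` (column-stochastic
link matrix `S`, uniform teleportation, damping `α = 0.85`), the package
computes for a subset `r` of `N_r` nodes:

* **PageRank `P` / CheiRank `P*`** — stationary vectors of `G` and of the
  edge-reversed network, with rank indices `K`, `K*`;
* **the reduced Google matrix**
  `G_R = G_rr + G_rs (1 − G_ss)⁻¹ G_sr`,
  the unique `N_r × N_r` stochastic matrix whose fixed point reproduces the
  subset's relative global PageRank, decomposed as
  `G_R = G_rr + G_pr + G_qr` into direct links, the PageRank-dominated
  rank-one part, and the indirect component whose large off-diagonal
  entries with no underlying edge are *hidden links*;
* **PageRank sensitivity** `D(j→k, i) = (1/P_i) dP_i/dδ` of any component
  to a column-renormalised boost of one effective link;
* **friendship networks** — iterative expansion from top-ranked seeds along
  the strongest `G_rr + G_qr` couplings, edges labelled direct or hidden;
* **rank statistics** — relative ranks within groups, Spearman rank
  correlations, top-j overlap `η(j)`, and log-scale rank-plane densities.

Everything is sparse and matrix-free (Sherman–Morrison around the
teleportation rank-one term), so it scales in the number of links, with a
dense backend as a cross-check at small sizes. A generator of layered
synthetic networks — heavy-tailed background, country/company/disease-like
strata, planted two-hop hidden paths — makes every stage testable without
any download.

## Worked example

```r
library(regomax)

# printed study tables: 34 companies, 47 rare renal diseases
co <- load_paper_tables()$companies
spearman_rho(co$K_r, co$K_r_star)
#> [1] 0.8041253
rank_overlap(co$name[order(co$K_r)], co$name[order(co$K_LMC)], 3)
#> [1] 0.3333333

# synthetic network with one planted hidden path company_01 -> ... -> disease_01
net <- generate_layered_network(layered_config(
  planted_hidden = data.frame(source = 1, n_intermediaries = 3, target = 1),
  seed = 42))
sel <- subset(net$catalog, group %in% c("company", "rare_renal_disease"))
r <- reduce_google_matrix(net$graph, sel$node_id, labels = sel$name)
r
#> <reduced_google: N_r = 20, alpha = 0.85, backend = iterative>
#>   lambda_c = 0.995455, kappa = 140.1
#>   max |colSums(G_R) - 1| = 1.69e-12, max |G_rr+G_pr+G_qr - G_R| = 2.30e-13

top_hidden_links(r, net$catalog, "company", "rare_renal_disease", k = 3)
#> # A tibble: 3 x 4
#>   source     target       weight is_direct
#> 1 company_01 disease_01 0.241    FALSE
#> 2 company_03 disease_04 0.000169 FALSE
#> 3 company_07 disease_04 0.000106 FALSE

sensitivity_profile(r, "company_01", c("disease_01", "disease_02", "disease_03"))
#> # A tibble: 3 x 3
#>   target label           d
#> 1     11 disease_01 0.469
#> 2     12 disease_02 0.0861
#> 3     13 disease_03 0.0858
```

Reading the output: the Spearman correlation 0.80 says influence in the
network and influence by market capitalization rank companies similarly but
far from identically (the top-3 overlap is only 1/3). On the synthetic
network, the planted company→disease path surfaces as the top hidden link
(`is_direct = FALSE`) three orders of magnitude above the
teleportation-level background couplings, and the sensitivity profile shows
`disease_01`'s PageRank responding five times more strongly than any other
disease to a boost from `company_01`. The vanishing column-sum and
decomposition errors are the numerical health checks of the reduction.

Result objects are tibble-friendly: `tidy()` returns long tables,
`glance()` one-row summaries, and `autoplot()` / `plot_rank_plane()` give
ggplot heatmaps of the reduced matrices and of the `(log K, log K*)` plane.
A command-line wrapper is installed as `exec/regomax` with subcommands
`simulate`, `rank`, `reduce`, `stats`, `sensitivity`, `friends`, and
`pipeline`; `run_pipeline()` is the equivalent R entry point and writes
CSV/MatrixMarket/GraphML artifacts plus a reproducibility manifest.

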