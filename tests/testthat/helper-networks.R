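# Study-scale synthetic networks shared between the heavier test blocks.
# Generation is deterministic per seed; the cache avoids regenerating the
# same network for every block that needs it.

.network_cache <- new.env(parent = emptyenv())

study_network <- function(seed) {
  key <- as.character(seed)
  if (is.null(.network_cache[[key]])) {
    cfg <- layered_config(
      planted_hidden = data.frame(source = 1, n_intermediaries = 3, target = 1),
      seed = seed
    )
    .network_cache[[key]] <- generate_layered_network(cfg)
  }
  .network_cache[[key]]
}

# subset of k nodes of interest that always contains the planted company and
# disease, then fills up with the remaining companies, diseases and countries
study_subset <- function(net, k) {
  cat_ <- net$catalog
  comp <- cat_[cat_$group == "company", ]
  dis <- cat_[cat_$group == "rare_renal_disease", ]
  ctry <- cat_[cat_$group == "country", ]
  pool <- rbind(comp[1, ], dis[1, ], comp[-1, ], dis[-1, ], ctry)
  pool[seq_len(k), ]
}
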