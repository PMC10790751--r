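# Shared fixtures: built once per test run, memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small gapped species (3 units x 4 genomes, 40 kb) with its ANI pair table
small_gapped <- function() memo("small_gapped", {
  sim <- simulate_species(sim_config(seed = 21, n_genomovars = 3,
                                     genomes_per_genomovar = 4,
                                     genome_length = 40000, n_core_genes = 15,
                                     n_accessory_pool = 15, gene_length = 500))
  sim$pairs <- pair_table(sim$genomes)
  sim
})

# indel-free pair at a given planted divergence (percent)
divergent_pair <- function(d_percent, seed) {
  simulate_species(sim_config(seed = seed, n_genomovars = 2,
                              genomes_per_genomovar = 1, scenario = "custom",
                              inter_unit_ani = c(100 - d_percent, 100 - d_percent),
                              intra_unit_ani = c(100, 100),
                              n_accessory_pool = 0, n_core_genes = 20,
                              gene_length = 700))$genomes
}

# random sample generators for dip testing (uniform / clustered / skewed)
random_dip_sample <- function(n) {
  x <- switch(sample(3L, 1L),
              runif(n),
              c(runif(ceiling(n / 2)) * 0.02, 0.6 + runif(floor(n / 2)) * 0.02),
              cumsum(rexp(n)))
  x[!duplicated(x)]
}

# brute-force connected components by depth-first search (units oracle)
dfs_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cid <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      stack <- c(stack, adj[[v]])
    }
  }
  # canonical labels: smallest member id
  labs <- vapply(split(names(comp), comp), min, character(1))
  setNames(unname(labs[as.character(comp)]), names(comp))
}

# truth-derived planted gap midpoint of a gapped simulation
planted_gap_midpoint <- function(truth) {
  same <- outer(truth$genomovar, truth$genomovar, "==")
  ut <- upper.tri(truth$identity)
  (max(truth$identity[ut & !same]) + min(truth$identity[ut & same])) / 2
}
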