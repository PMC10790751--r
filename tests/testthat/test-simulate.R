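test_that("planted identities honour the configured bands", {
  sim <- simulate_species(sim_config(seed = 2, n_genomovars = 2,
                                     genomes_per_genomovar = 3,
                                     scenario = "custom",
                                     inter_unit_ani = c(98.5, 98.5),
                                     intra_unit_ani = c(99.95, 99.95),
                                     genome_length = 50000, n_core_genes = 10,
                                     n_accessory_pool = 10, gene_length = 500))
  tr <- sim$truth
  same <- outer(tr$genomovar, tr$genomovar, "==")
  ut <- upper.tri(tr$identity)
  expect_true(all(tr$identity[ut & !same] >= 98.4 &
                  tr$identity[ut & !same] <= 98.6))
  expect_true(all(tr$identity[ut & same] >= 99.9))
  expect_equal(sum(ut & !same), 9)
  expect_equal(sum(ut & same), 6)
})

test_that("a single-genome species gives an empty pair table, no error", {
  sim <- simulate_species(sim_config(seed = 3, n_genomovars = 1,
                                     genomes_per_genomovar = 1,
                                     genome_length = 30000, n_core_genes = 10,
                                     n_accessory_pool = 5, gene_length = 400))
  expect_length(sim$genomes, 1)
  pt <- pair_table(sim$genomes)
  expect_s3_class(pt, "ani_pair_table")
  expect_equal(nrow(pt), 0)
})

test_that("gapped scenario leaves the 99.2-99.8 window empty with occupied flanks", {
  sim <- simulate_species(sim_config(seed = 4))
  iv <- sim$truth$identity[upper.tri(sim$truth$identity)]
  expect_equal(sum(iv > 99.2 & iv < 99.8), 0)
  expect_gt(sum(iv <= 99.2), 0)
  expect_gt(sum(iv >= 99.8), 0)
})

test_that("realized Hamming identity matches the planted matrix", {
  sim <- simulate_species(sim_config(seed = 5, n_genomovars = 2,
                                     genomes_per_genomovar = 2,
                                     genome_length = 30000, n_core_genes = 10,
                                     n_accessory_pool = 0, gene_length = 500))
  ids <- names(sim$genomes)
  L <- sim$truth$frame_length
  for (i in 1:3) for (j in (i + 1):4) {
    h <- sequence_identity(sim$genomes[[i]]$contigs[[1]],
                           sim$genomes[[j]]$contigs[[1]])
    planted <- sim$truth$identity[ids[i], ids[j]]
    p <- 1 - planted / 100
    tol <- 3 * sqrt(max(p * (1 - p), 1e-12) / L) * 100
    expect_lte(abs(h - planted), max(tol, 1e-9))
  }
})

test_that("strain partition refines the genomovar partition in truth", {
  for (s in 1:5) {
    sim <- simulate_species(sim_config(seed = s, n_genomovars = 3,
                                       genomes_per_genomovar = 3,
                                       genome_length = 40000, n_core_genes = 10,
                                       n_accessory_pool = 10, gene_length = 400,
                                       intra_unit_ani = c(99.85, 100)))
    tr <- sim$truth
    split_by_strain <- split(tr$genomovar[names(tr$strain)], tr$strain)
    expect_true(all(vapply(split_by_strain,
                           function(g) length(unique(g)) == 1L, logical(1))))
  }
})

test_that("same seed gives byte-identical FASTA output", {
  cfg <- sim_config(seed = 9, n_genomovars = 2, genomes_per_genomovar = 2,
                    genome_length = 30000, n_core_genes = 10,
                    n_accessory_pool = 5, gene_length = 400)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_species(cfg)
  write_species(s1$genomes, s1$truth, d1)
  s2 <- simulate_species(cfg)
  write_species(s2$genomes, s2$truth, d2)
  for (f in list.files(d1, pattern = "fasta$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("write_species round-trips genomes, truth tables and tree", {
  sim <- simulate_species(sim_config(seed = 10, n_genomovars = 2,
                                     genomes_per_genomovar = 2,
                                     genome_length = 30000, n_core_genes = 10,
                                     n_accessory_pool = 5, gene_length = 400))
  d <- tempfile()
  write_species(sim$genomes, sim$truth, d)
  back <- read_species(d)
  for (id in names(sim$genomes))
    expect_identical(back$genomes[[id]]$contigs, sim$genomes[[id]]$contigs)
  n <- length(sim$genomes)
  expect_equal(nrow(back$truth_labels), n)
  expect_equal(nrow(back$truth_pairs), n * (n - 1) / 2)
  expect_setequal(back$tree$tip.label, names(sim$genomes))
  # annotations and locus tags survive the round trip
  expect_equal(back$genomes[[1]]$genes$gene_id, sim$genomes[[1]]$genes$gene_id)
  expect_identical(back$genomes[[1]]$locus_tags, sim$genomes[[1]]$locus_tags)
  unlink(d, recursive = TRUE)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = 1, scenario = "custom",
                          inter_unit_ani = c(99, 99.9),
                          intra_unit_ani = c(97, 98)),
               "infeasible")
  expect_error(sim_config(seed = 1, scenario = "gapped",
                          intra_unit_ani = c(99.5, 99.9)),
               "gapped")
  expect_error(sim_config(seed = 1, mobile_fraction = 1.5), "mobile_fraction")
  expect_error(sim_config(seed = 1, mlst_loci = paste0("l", 1:6)), "7")
})

test_that("gapless scenario covers the range without exclusion", {
  sim <- simulate_species(sim_config(seed = 12, scenario = "gapless"))
  iv <- sim$truth$identity[upper.tri(sim$truth$identity)]
  expect_gt(sum(iv > 99.2 & iv < 99.8), 0)   # the window is populated
  h <- hist(iv, breaks = seq(96, 100, by = 0.5), plot = FALSE)
  expect_true(all(h$counts > 0))             # every half-unit bin occupied
})
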