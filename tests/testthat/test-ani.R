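test_that("self-comparison yields ANI 100 and shared fraction 1", {
  set.seed(101)
  s <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE), collapse = "")
  a <- compute_ani(s, s)
  expect_equal(a$ani, 100)
  expect_equal(a$shared_fraction, 1)
  expect_equal(a$n_fragments, 10)
})

test_that("30 substitutions inside one fragment give the forced identity set", {
  set.seed(102)
  base <- sample(c("A", "C", "G", "T"), 30000, replace = TRUE)
  mut <- base
  pos <- sample(6001:9000, 30)               # all inside fragment 3
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), base[p])[1]
  a <- compute_ani(paste(mut, collapse = ""), paste(base, collapse = ""))
  ids <- sort(a$fragments$identity)
  expect_equal(ids, c(99, rep(100, 9)))
  expect_equal(a$ani, 99.9)
  expect_equal(a$shared_fraction, 1)
})

test_that("fragment ANI matches exact Hamming identity on indel-free pairs", {
  g <- divergent_pair(2, seed = 31)
  h <- sequence_identity(g[[1]]$contigs[[1]], g[[2]]$contigs[[1]])
  a <- compute_ani(g[[1]], g[[2]])
  expect_lte(abs(a$ani - h), 0.05)
  expect_lte(abs(a$ani - 98), 0.1)
})

test_that("ANI decreases with planted divergence", {
  anis <- vapply(c(0.2, 1, 2, 3), function(d) {
    g <- divergent_pair(d, seed = 77)
    compute_ani(g[[1]], g[[2]])$ani
  }, numeric(1))
  expect_true(all(diff(anis) < 0))
})

test_that("pair_table keeps one row per unordered pair with the longer reference", {
  sim <- small_gapped()
  pt <- sim$pairs
  n <- length(sim$genomes)
  expect_equal(nrow(pt), n * (n - 1) / 2)
  lens <- vapply(sim$genomes, function(g) sum(nchar(g$contigs)), numeric(1))
  for (k in seq_len(nrow(pt))) {
    lq <- lens[pt$query_id[k]]; lr <- lens[pt$ref_id[k]]
    expect_true(lr > lq || (lr == lq && pt$ref_id[k] < pt$query_id[k]))
  }
  expect_error(pair_table(c(sim$genomes, sim$genomes[1])), "duplicate")
})

test_that("equal-length pair takes the lexicographically smaller id as reference", {
  set.seed(103)
  s <- paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")
  ga <- genome_record("b_genome", c(c1 = s))
  gb <- genome_record("a_genome", c(c1 = s))
  pt <- pair_table(list(ga, gb))
  expect_equal(pt$ref_id, "a_genome")
  expect_equal(pt$query_id, "b_genome")
})

test_that("swapping roles changes ANI by less than 0.05 on indel-free pairs", {
  for (s in 1:3) {
    g <- divergent_pair(1.5, seed = 200 + s)
    a1 <- compute_ani(g[[1]], g[[2]])$ani
    a2 <- compute_ani(g[[2]], g[[1]])$ani
    expect_lte(abs(a1 - a2), 0.05)
  }
})

test_that("too-short genomes raise the no-fragments error", {
  expect_error(compute_ani(strrep("ACGT", 100), strrep("ACGT", 2000)),
               "no fragments")
})

test_that("undefined ANI is NA, not zero", {
  set.seed(104)
  s1 <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  a <- compute_ani(s1, s2)   # unrelated random sequences: nothing maps
  expect_true(is.na(a$ani))
  expect_equal(a$n_bidirectional, 0)
})

test_that("multi-contig fragments never span contig junctions", {
  set.seed(105)
  c1 <- paste(sample(c("A", "C", "G", "T"), 7000, replace = TRUE), collapse = "")
  c2 <- paste(sample(c("A", "C", "G", "T"), 4500, replace = TRUE), collapse = "")
  g <- genome_record("mc", c(c1 = c1, c2 = c2))
  a <- compute_ani(g, g)
  # 2 fragments in contig 1 (7000), 1 in contig 2 (4500); remainders dropped
  expect_equal(a$n_fragments, 3)
  expect_equal(a$ani, 100)
})

test_that("shared_gene_fraction follows its definition and matches truth", {
  sim <- small_gapped()
  ga <- sim$genomes[[1]]
  # identical genomes
  expect_equal(shared_gene_fraction(ga, ga)$shared_gene_fraction, 1)
  # deletion example: removing k genes gives orthologs/(mean counts)
  gb <- ga
  drop <- tail(seq_len(nrow(ga$genes)), 3)
  gb$genes <- ga$genes[-drop, ]
  gs <- shared_gene_fraction(ga, gb)
  n <- nrow(ga$genes)
  expect_equal(gs$shared_gene_fraction, (n - 3) / mean(c(n, n - 3)))
  # counts add up per side
  expect_equal(nrow(gs$orthologs) + nrow(gs$nonshared_a), n)
  expect_equal(nrow(gs$orthologs) + nrow(gs$nonshared_b), n - 3)
  # agreement with the planted presence/absence matrix
  pres <- sim$truth$presence
  for (k in c(1, 5)) {
    a <- sim$genomes[[k]]; b <- sim$genomes[[k + 1]]
    gs <- shared_gene_fraction(a, b)
    n_core <- sum(a$genes$is_core)
    expected <- (n_core + sum(pres[, a$genome_id] & pres[, b$genome_id])) /
      mean(c(nrow(a$genes), nrow(b$genes)))
    expect_equal(gs$shared_gene_fraction, expected)
  }
  # zero-gene genome is an error
  g0 <- genome_record("empty", c(c1 = strrep("ACGT", 1000)))
  expect_error(shared_gene_fraction(ga, g0), "annotations")
})

test_that("pair tables round-trip through TSV, including undefined ANI", {
  sim <- small_gapped()
  pt <- sim$pairs
  pt$ani[1] <- NA
  f <- tempfile(fileext = ".tsv")
  write_pair_table(pt, f)
  back <- read_pair_table(f)
  expect_equal(back$ani, pt$ani)
  expect_equal(back$query_id, pt$query_id)
  # truncated table: schema error names the missing column
  bad <- pt[, setdiff(names(pt), "shared_fraction")]
  f2 <- tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pair_table(f2), "shared_fraction")
  unlink(c(f, f2))
})
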