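#' Configuration for the synthetic species generator
#'
#' Defines a simulated bacterial species: a set of genomes organised into
#' genomovars (intra-species units), with pairwise nucleotide identities
#' planted in two bands. In the default `"gapped"` scenario within-unit pairs
#' fall above 99.8% identity and between-unit pairs below 99.2%, leaving the
#' 99.2--99.8% interval empty -- the discontinuity the downstream gap
#' statistics are designed to detect. A `"gapless"` control covers 96--100%
#' without exclusion and a `"clonal"` scenario keeps all pairs above 99.5%.
#'
#' Genomes carry core genes (always present), accessory genes gained and lost
#' along the lineage tree, and seven designated core loci for MLST-style
#' sequence typing. Accessory genes labelled `hypothetical/mobile` turn over
#' `mobile_turnover` times faster than `annotated` ones, planting the category
#' bias that very close genome pairs differ mostly by mobile genes.
#'
#' @param seed integer seed driving all randomness of the generator.
#' @param genome_length target pangenome frame length in bp.
#' @param n_genomovars,genomes_per_genomovar planted unit structure.
#' @param inter_unit_ani,intra_unit_ani percent identity bands (length-2) for
#'   between-unit and within-unit genome pairs. Defaults depend on `scenario`.
#' @param strain_ani percent identity above which a planted pair is marked the
#'   same strain.
#' @param scenario one of `"gapped"`, `"gapless"`, `"clonal"`, or
#'   `"custom"` (two-level planting with caller-supplied bands, no gap
#'   constraint).
#' @param n_core_genes,n_accessory_pool,gene_length gene complement sizes (bp
#'   for `gene_length`).
#' @param gain_loss_prob per-branch probability that an accessory gene flips
#'   presence/absence.
#' @param mobile_fraction fraction of the accessory pool labelled
#'   `hypothetical/mobile`.
#' @param mobile_turnover multiplier on `gain_loss_prob` for mobile genes
#'   (capped so that the flip probability stays at or below 0.5); set to 1 for
#'   category-neutral (null) turnover.
#' @param acc_root_presence probability that an accessory gene is present in
#'   the species ancestor.
#' @param mlst_loci names of the 7 MLST loci.
#' @param mlst_locus_rate relative substitution rate inside MLST locus genes
#'   on terminal (genome) branches, as a fraction of the genome-average rate.
#'   Housekeeping core genes are under purifying selection, so alleles are
#'   stable within recently diverged lineages; 0 makes within-unit allele
#'   variants impossible.
#' @param mlst_locus_rate_unit same, on genomovar-ancestor branches; the
#'   higher default lets units accumulate distinct allele profiles while
#'   within-unit profiles stay mostly identical, the situation sequence
#'   typing was designed for.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_genomovars = 5L,
                       genomes_per_genomovar = 8L,
                       inter_unit_ani = NULL,
                       intra_unit_ani = NULL,
                       strain_ani = 99.99,
                       scenario = c("gapped", "gapless", "clonal", "custom"),
                       n_core_genes = 50L,
                       n_accessory_pool = 50L,
                       gene_length = 700L,
                       gain_loss_prob = 0.02,
                       mobile_fraction = 0.3,
                       mobile_turnover = 15,
                       acc_root_presence = 0.6,
                       mlst_loci = paste0("mlst", 1:7),
                       mlst_locus_rate = 0.05,
                       mlst_locus_rate_unit = 0.5) {
  scenario <- match.arg(scenario)
  if (is.null(inter_unit_ani)) {
    inter_unit_ani <- switch(scenario,
      gapped  = c(96.0, 99.2),
      gapless = c(96.0, 100.0),
      clonal  = c(99.6, 99.9),
      custom  = stop("scenario 'custom' requires explicit identity bands"))
  }
  if (is.null(intra_unit_ani)) {
    intra_unit_ani <- switch(scenario,
      gapped  = c(99.85, 99.99),
      gapless = c(96.0, 100.0),
      clonal  = c(99.85, 99.995),
      custom  = stop("scenario 'custom' requires explicit identity bands"))
  }
  cfg <- structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genomovars = as.integer(n_genomovars),
    genomes_per_genomovar = as.integer(genomes_per_genomovar),
    inter_unit_ani = as.numeric(inter_unit_ani),
    intra_unit_ani = as.numeric(intra_unit_ani),
    strain_ani = strain_ani, scenario = scenario,
    n_core_genes = as.integer(n_core_genes),
    n_accessory_pool = as.integer(n_accessory_pool),
    gene_length = as.integer(gene_length),
    gain_loss_prob = gain_loss_prob, mobile_fraction = mobile_fraction,
    mobile_turnover = mobile_turnover, acc_root_presence = acc_root_presence,
    mlst_loci = mlst_loci, mlst_locus_rate = mlst_locus_rate,
    mlst_locus_rate_unit = mlst_locus_rate_unit), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(mlst_loci) != 7L || anyDuplicated(mlst_loci))
      stop("exactly 7 distinct MLST locus names are required")
    if (n_core_genes < 7L) stop("need at least 7 core genes to host the MLST loci")
    if (n_accessory_pool < 0L) stop("n_accessory_pool must be >= 0")
    if (mobile_fraction < 0 || mobile_fraction > 1)
      stop("mobile_fraction must be in [0, 1]")
    if (mlst_locus_rate < 0 || mlst_locus_rate > 1 ||
        mlst_locus_rate_unit < 0 || mlst_locus_rate_unit > 1)
      stop("MLST locus rates must be in [0, 1]")
    if (length(inter_unit_ani) != 2L || length(intra_unit_ani) != 2L ||
        diff(inter_unit_ani) < 0 || diff(intra_unit_ani) < 0)
      stop("identity bands must be nondecreasing length-2 vectors")
    if (n_genomovars > 1L &&
        (intra_unit_ani[1] < inter_unit_ani[1] || intra_unit_ani[2] < inter_unit_ani[2]))
      stop("infeasible config: intra-unit identities fall below inter-unit identities")
    if (scenario == "gapped" &&
        (intra_unit_ani[1] < 99.8 || inter_unit_ani[2] > 99.2))
      stop("gapped scenario requires intra-unit ANI >= 99.8 and inter-unit ANI <= 99.2")
    if (scenario == "clonal" && inter_unit_ani[1] <= 99.5)
      stop("clonal scenario requires all planted identities > 99.5")
    # feasibility of unit-depth sampling: between-unit band must be at least as
    # wide as the within-unit band (tree-consistent planting)
    if (n_genomovars > 1L &&
        diff(inter_unit_ani) < diff(intra_unit_ani) - 1e-12)
      stop("infeasible config: inter-unit band narrower than intra-unit band")
    invisible(NULL)
  })
}

# Pangenome layout: alternating core/accessory gene blocks with spacers.
# Returns a data.frame of blocks with frame coordinates (0-based half-open).
.pan_layout <- function(cfg) {
  ng <- cfg$n_core_genes + cfg$n_accessory_pool
  gl <- cfg$gene_length
  total_gene <- ng * gl
  n_spacer <- ng + 1L
  spacer_len <- (cfg$genome_length - total_gene) %/% n_spacer
  if (spacer_len < 50L)
    stop("genes do not fit in genome_length: increase genome_length or reduce genes")
  ids <- character(ng); core <- logical(ng)
  ic <- ia <- 0L
  for (i in seq_len(ng)) {
    # interleave core and accessory genes along the genome
    take_core <- (ia >= cfg$n_accessory_pool) ||
      (ic < cfg$n_core_genes && (i %% 2L == 1L || ia >= cfg$n_accessory_pool))
    if (take_core && ic < cfg$n_core_genes) {
      ic <- ic + 1L; ids[i] <- sprintf("core_%03d", ic); core[i] <- TRUE
    } else {
      ia <- ia + 1L; ids[i] <- sprintf("acc_%03d", ia); core[i] <- FALSE
    }
  }
  starts <- spacer_len + (seq_len(ng) - 1L) * (gl + spacer_len)
  data.frame(gene_id = ids, is_core = core, start = starts,
             end = starts + gl, stringsAsFactors = FALSE)
}

#' Simulate a synthetic species with planted unit structure
#'
#' Generates genome assemblies whose pairwise identities follow the bands in
#' the configuration, together with machine-readable truth tables. Divergence
#' is planted on a two-level lineage tree (genomovar ancestors off the species
#' root, genomes off genomovar ancestors) so that pairwise identities are
#' tree-consistent; substitution sites are drawn uniformly at random and
#' disjointly across branches, which makes the realized pairwise Hamming
#' divergence on the pangenome frame exactly additive along the tree. The
#' returned truth matrix is therefore exact, not an expectation.
#'
#' @param config a [sim_config()].
#' @return a list with `genomes` (list of `genome_record`) and `truth` (a
#'   `species_truth`: planted identity matrix, genomovar/strain labels, gene
#'   presence matrix, categories, and the lineage tree as an [ape::phylo]).
#' @export
#' @examples
#' sim <- simulate_species(sim_config(seed = 7, n_genomovars = 2,
#'                                    genomes_per_genomovar = 2,
#'                                    genome_length = 30000, n_core_genes = 10,
#'                                    n_accessory_pool = 10, gene_length = 400))
#' sim$truth$identity
simulate_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  layout <- .pan_layout(cfg)
  L <- max(layout$end) + (layout$start[1])     # frame length incl. trailing spacer
  n_units <- cfg$n_genomovars
  per <- cfg$genomes_per_genomovar
  n <- n_units * per
  unit_of <- rep(seq_len(n_units), each = per)
  ids <- sprintf("g%02d_%02d", unit_of, sequence(rep(per, n_units)))

  # branch divergences (expected substitutions / site on the frame)
  idiv <- rev(1 - cfg$intra_unit_ani / 100)    # c(lo, hi) in divergence units
  ediv <- rev(1 - cfg$inter_unit_ani / 100)
  if (cfg$scenario == "gapless") {
    # diversity continuum: every genome on its own branch off the root, so
    # pairwise divergences (v_i + v_j) fill [0, ediv_hi] without exclusion
    u <- rep(0, n_units)
    v <- runif(n, 0, ediv[2] / 2)
  } else {
    v <- runif(n, idiv[1] / 2, idiv[2] / 2)    # genome depth below unit ancestor
    u_lo <- max(0, (ediv[1] - idiv[1]) / 2)
    u_hi <- (ediv[2] - idiv[2]) / 2
    if (u_hi < u_lo - 1e-12)
      stop("infeasible config: inter-unit band narrower than intra-unit band")
    u <- runif(n_units, u_lo, max(u_lo, u_hi)) # unit ancestor depth below root
    # anchor the two shallowest units at the band edge so that between-unit
    # pairs actually reach the top of the inter-unit identity band
    if (n_units >= 2L) u[order(u)[1:2]] <- u_lo
  }

  su <- as.integer(round(u * L))               # substitutions per unit branch
  sv <- as.integer(round(v * L))               # substitutions per genome branch

  # strands fixed on the ancestral frame; MLST loci = 7 core genes spread out
  strand <- setNames(sample(c("+", "-"), nrow(layout), replace = TRUE), layout$gene_id)
  core_ids <- layout$gene_id[layout$is_core]
  loci_genes <- core_ids[unique(round(seq(1, length(core_ids), length.out = 7)))]
  if (length(loci_genes) < 7L) loci_genes <- core_ids[1:7]
  locus_map <- setNames(loci_genes, cfg$mlst_loci)

  # disjoint substitution sites, uniform within each stratum; MLST locus
  # genes mutate at a reduced relative rate (purifying selection), with the
  # per-branch substitution *count* unchanged so planted identities stay exact
  loci_pos <- unlist(lapply(match(loci_genes, layout$gene_id), function(b)
    (layout$start[b] + 1L):layout$end[b]))
  P <- length(loci_pos)
  scount <- c(su, sv)
  rate_of <- c(rep(cfg$mlst_locus_rate_unit, n_units), rep(cfg$mlst_locus_rate, n))
  w <- (rate_of * P) / (rate_of * P + (L - P))
  nloc <- rbinom(length(scount), scount, w)
  nnon <- scount - nloc
  if (sum(nloc) > P || sum(nnon) > L - P)
    stop("requested divergence exceeds genome length")
  loc_pool <- sample(loci_pos)
  non_pool <- sample(setdiff(seq_len(L), loci_pos))
  loc_off <- cumsum(c(0L, nloc)); non_off <- cumsum(c(0L, nnon))
  site_of <- function(k) c(
    if (nloc[k] > 0L) loc_pool[(loc_off[k] + 1L):loc_off[k + 1L]] else integer(0),
    if (nnon[k] > 0L) non_pool[(non_off[k] + 1L):non_off[k + 1L]] else integer(0))
  unit_sites <- lapply(seq_len(n_units), site_of)
  genome_sites <- lapply(n_units + seq_len(n), site_of)

  root <- sample.int(4L, L, replace = TRUE) - 1L  # codes 0..3
  sites <- c(unlist(unit_sites), unlist(genome_sites))
  shift <- sample.int(3L, length(sites), replace = TRUE)  # base change, never identity

  # gene categories & presence
  acc_ids <- layout$gene_id[!layout$is_core]
  n_acc <- length(acc_ids)
  mobile <- setNames(rbinom(n_acc, 1L, cfg$mobile_fraction) == 1L, acc_ids)
  flip_p <- pmin(0.5, cfg$gain_loss_prob * ifelse(mobile, cfg$mobile_turnover, 1))
  pres_root <- rbinom(n_acc, 1L, cfg$acc_root_presence) == 1L
  presence <- matrix(FALSE, nrow = n_acc, ncol = n, dimnames = list(acc_ids, ids))
  if (n_acc > 0L) {
    unit_pres <- matrix(FALSE, nrow = n_acc, ncol = n_units)
    for (g in seq_len(n_units))
      unit_pres[, g] <- xor(pres_root, rbinom(n_acc, 1L, flip_p) == 1L)
    for (i in seq_len(n))
      presence[, i] <- xor(unit_pres[, unit_of[i]], rbinom(n_acc, 1L, flip_p) == 1L)
  }

  genomes <- vector("list", n)
  frames_sub <- vector("list", n_units)
  for (g in seq_len(n_units)) {
    fr <- root
    s <- unit_sites[[g]]
    if (length(s)) fr[s] <- (fr[s] + shift[match(s, sites)]) %% 4L
    frames_sub[[g]] <- fr
  }
  for (i in seq_len(n)) {
    fr <- frames_sub[[unit_of[i]]]
    s <- genome_sites[[i]]
    if (length(s)) fr[s] <- (fr[s] + shift[match(s, sites)]) %% 4L
    keep_gene <- layout$is_core | presence[match(layout$gene_id, acc_ids), i] %in% TRUE
    # positions kept: everything except absent accessory blocks
    drop_mask <- rep(FALSE, L)
    for (b in which(!keep_gene)) drop_mask[(layout$start[b] + 1L):layout$end[b]] <- TRUE
    kept <- which(!drop_mask)
    contig <- codes_to_seq(fr[kept])
    # recompute gene coordinates in contig space
    cum_drop <- cumsum(drop_mask)
    gsel <- which(keep_gene)
    genes <- data.frame(
      gene_id = layout$gene_id[gsel],
      contig = "c1",
      start = layout$start[gsel] - cum_drop[layout$start[gsel] + 1L],
      end = layout$end[gsel] - cum_drop[layout$end[gsel]],
      strand = unname(strand[layout$gene_id[gsel]]),
      category = ifelse(layout$is_core[gsel], "annotated",
                        ifelse(mobile[layout$gene_id[gsel]], "hypothetical/mobile",
                               "annotated")),
      is_core = layout$is_core[gsel],
      stringsAsFactors = FALSE)
    genomes[[i]] <- genome_record(ids[i], setNames(contig, "c1"), genes, locus_map)
  }
  names(genomes) <- ids

  # exact planted identity matrix (divergence additive along the tree)
  depth_u <- su / L; depth_v <- sv / L
  div <- outer(depth_v, depth_v, "+") +
    (outer(unit_of, unit_of, "!=") * outer(depth_u[unit_of], depth_u[unit_of], "+"))
  identity <- 100 * (1 - div)
  diag(identity) <- 100
  dimnames(identity) <- list(ids, ids)

  strain <- .threshold_components(identity, cfg$strain_ani, strict = TRUE)
  genomovar <- if (cfg$scenario == "gapless")
    .threshold_components(identity, 99.5, prefix = "gv")  # continuum: no planted units
  else setNames(paste0("gv", unit_of), ids)

  tree <- .two_level_tree(ids, unit_of, depth_u, depth_v)
  truth <- structure(list(
    identity = identity, genomovar = genomovar, strain = strain,
    presence = presence, mobile = mobile, tree = tree,
    frame_length = L, unit_depth = depth_u, genome_depth = setNames(depth_v, ids),
    config = cfg), class = "species_truth")
  list(genomes = genomes, truth = truth)
}

# single-linkage components of a planted identity matrix
.threshold_components <- function(identity, threshold, strict = FALSE, prefix = "s") {
  ids <- rownames(identity)
  n <- length(ids)
  adj <- if (strict) identity > threshold else identity >= threshold
  diag(adj) <- TRUE
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(comp[adj[i, ]])
      if (m < comp[i]) { comp[adj[i, ] & comp > m] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  setNames(paste0(prefix, match(comp, sort(unique(comp)))), ids)
}

.two_level_tree <- function(ids, unit_of, depth_u, depth_v) {
  units <- sort(unique(unit_of))
  sub <- vapply(units, function(g) {
    tips <- which(unit_of == g)
    inner <- paste(sprintf("%s:%.10f", ids[tips], depth_v[tips]), collapse = ",")
    if (length(tips) == 1L) sprintf("%s:%.10f", ids[tips], depth_v[tips] + depth_u[g])
    else sprintf("(%s):%.10f", inner, depth_u[g])
  }, character(1))
  txt <- if (length(sub) == 1L && !startsWith(sub, "(")) sprintf("(%s);", sub)
         else sprintf("(%s);", paste(sub, collapse = ","))
  ape::read.tree(text = txt)
}

#' Genome record
#'
#' A genome assembly with its contigs, gene annotations and MLST locus tags.
#' Gene intervals are 0-based half-open in contig coordinates.
#'
#' @param genome_id scalar id.
#' @param contigs named character vector of contig sequences.
#' @param genes data.frame with columns gene_id, contig, start, end, strand,
#'   category, is_core.
#' @param locus_tags named character vector mapping MLST locus name to gene_id.
#' @export
genome_record <- function(genome_id, contigs, genes = NULL, locus_tags = character(0)) {
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0), strand = character(0),
                        category = character(0), is_core = logical(0),
                        stringsAsFactors = FALSE)
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  bad <- genes$start < 0 | genes$end > nchar(contigs)[match(genes$contig, names(contigs))] |
    genes$start >= genes$end
  if (any(bad)) stop("gene intervals out of contig bounds")
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes,
                 locus_tags = locus_tags), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp, %d genes\n",
              x$genome_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' @export
print.species_truth <- function(x, ...) {
  cat(sprintf("<species_truth> %d genomes, %d genomovars, %d strains, scenario '%s'\n",
              nrow(x$identity), length(unique(x$genomovar)),
              length(unique(x$strain)), x$config$scenario))
  invisible(x)
}

# extract the (strand-normalised) sequence of one gene
gene_seq <- function(genome, gene_row) {
  s <- substr(genome$contigs[[gene_row$contig]], gene_row$start + 1L, gene_row$end)
  if (gene_row$strand == "-") revcomp(s) else s
}

gene_seqs <- function(genome) {
  g <- genome$genes
  vapply(seq_len(nrow(g)), function(i) gene_seq(genome, g[i, ]), character(1))
}

#' Write a simulated species to disk
#'
#' One FASTA per genome (80-column wrap), gene annotations, truth tables as
#' TSV, and the lineage tree as Newick. [read_species()] round-trips the
#' files losslessly.
#'
#' @param genomes list of `genome_record`.
#' @param truth optional `species_truth`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_species <- function(genomes, truth = NULL, outdir) {
  if (length(genomes) == 0L) stop("empty genome list")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in genomes) {
    f <- file.path(outdir, paste0(g$genome_id, ".fasta"))
    ss <- Biostrings::DNAStringSet(g$contigs)
    names(ss) <- names(g$contigs)
    Biostrings::writeXStringSet(ss, f, width = 80L)
    files <- c(files, f)
  }
  genes <- do.call(rbind, lapply(genomes, function(g)
    if (nrow(g$genes)) cbind(genome_id = g$genome_id, g$genes) else NULL))
  f <- file.path(outdir, "genes.tsv")
  write.table(genes, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  loci <- do.call(rbind, lapply(genomes, function(g)
    if (length(g$locus_tags)) data.frame(genome_id = g$genome_id,
                                         locus = names(g$locus_tags),
                                         gene_id = unname(g$locus_tags)) else NULL))
  if (!is.null(loci)) {
    f <- file.path(outdir, "loci.tsv")
    write.table(loci, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(truth)) {
    ids <- rownames(truth$identity)
    lab <- data.frame(genome_id = ids, genomovar = truth$genomovar[ids],
                      strain = truth$strain[ids])
    f <- file.path(outdir, "truth_labels.tsv")
    write.table(lab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    cmb <- t(combn(ids, 2))
    pairs <- data.frame(genome_a = cmb[, 1], genome_b = cmb[, 2],
                        identity = truth$identity[cmb])
    f <- file.path(outdir, "truth_pairs.tsv")
    write.table(pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(outdir, "truth_presence.tsv")
    write.table(data.frame(gene_id = rownames(truth$presence), truth$presence,
                           check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(outdir, "lineage.nwk")
    ape::write.tree(truth$tree, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read genomes (and truth tables, if present) written by [write_species()]
#'
#' @param dir directory containing the files.
#' @return list with `genomes` and (when available) `truth_labels`,
#'   `truth_pairs`, `tree`.
#' @export
read_species <- function(dir) {
  fa <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fa) == 0L) stop("no FASTA files in ", dir)
  genes <- NULL
  gf <- file.path(dir, "genes.tsv")
  if (file.exists(gf)) genes <- read.delim(gf, stringsAsFactors = FALSE)
  loci <- NULL
  lf <- file.path(dir, "loci.tsv")
  if (file.exists(lf)) loci <- read.delim(lf, stringsAsFactors = FALSE)
  genomes <- lapply(fa, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    gid <- sub("\\.fasta$", "", basename(f))
    contigs <- setNames(as.character(ss), names(ss))
    g <- if (!is.null(genes)) genes[genes$genome_id == gid, -1, drop = FALSE] else NULL
    lt <- character(0)
    if (!is.null(loci)) {
      sel <- loci[loci$genome_id == gid, ]
      lt <- setNames(sel$gene_id, sel$locus)
    }
    genome_record(gid, contigs, g, lt)
  })
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
  out <- list(genomes = genomes)
  tl <- file.path(dir, "truth_labels.tsv")
  if (file.exists(tl)) out$truth_labels <- read.delim(tl, stringsAsFactors = FALSE)
  tp <- file.path(dir, "truth_pairs.tsv")
  if (file.exists(tp)) out$truth_pairs <- read.delim(tp, stringsAsFactors = FALSE)
  nw <- file.path(dir, "lineage.nwk")
  if (file.exists(nw)) out$tree <- ape::read.tree(nw)
  out
}
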