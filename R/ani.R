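# Fragment-based average nucleotide identity (ANI).
#
# The query genome is split into consecutive non-overlapping fragments
# (default 3,000 bp; the terminal remainder is discarded); each fragment is
# placed on the reference by exact k-mer seeding followed by ungapped
# extension over the full fragment, and retained if its identity reaches the
# mapping threshold. A retained mapping is "bidirectional" when the reference
# fragment containing the mapped midpoint maps back (same procedure, roles
# swapped) to within half a fragment of the originating query fragment.
# ANI = mean identity over bidirectional mappings; the shared genome fraction
# = bidirectional mappings / total query fragments.

.contig_codes <- function(genome) {
  if (is.character(genome)) genome <- genome_record("query", c(c1 = genome))
  lens <- nchar(genome$contigs)
  codes <- unlist(lapply(genome$contigs, seq_codes), use.names = FALSE)
  ends <- cumsum(lens)
  bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  list(id = genome$genome_id, codes = codes, bounds = bounds)
}

.fragment_starts <- function(bounds, fragment_length) {
  starts <- integer(0)
  for (i in seq_len(nrow(bounds))) {
    span <- bounds[i, 2] - bounds[i, 1]
    nf <- span %/% fragment_length
    if (nf > 0L)
      starts <- c(starts, bounds[i, 1] + (seq_len(nf) - 1L) * fragment_length)
  }
  starts
}

#' Fragment-based ANI between two genomes
#'
#' @param query,reference `genome_record` objects (or plain character
#'   sequences).
#' @param fragment_length fragment size in bp.
#' @param min_fragment_identity percent identity below which a fragment
#'   mapping is discarded.
#' @param seed_k k-mer size used for exact seeding.
#' @param seed_step spacing of seed positions along a fragment.
#' @param min_fragment_coverage minimum aligned fraction of a fragment: a
#'   mapping whose ungapped X-drop extension spans less than this fraction of
#'   the fragment (e.g. because it straddles an accessory-gene indel) is
#'   discarded rather than scored against random sequence.
#' @return an object of class `ani_pair`: query/reference ids, `ani` (percent;
#'   `NA` when no fragment maps bidirectionally -- undefined, not 0),
#'   `shared_fraction` = bidirectional / total query fragments, and the
#'   fragment counts.
#' @export
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
#' compute_ani(s, s, fragment_length = 1000)$ani  # 100
compute_ani <- function(query, reference, fragment_length = 3000L,
                        min_fragment_identity = 80, seed_k = 16L,
                        seed_step = 25L, min_fragment_coverage = 0.8) {
  if (fragment_length < 2L * seed_k)
    stop("fragment_length must be at least 2 * seed_k")
  q <- .contig_codes(query)
  r <- .contig_codes(reference)
  if (length(q$codes) == 0L || length(r$codes) == 0L) stop("empty genome")
  qstarts <- .fragment_starts(q$bounds, fragment_length)
  if (length(qstarts) == 0L)
    stop("no fragments: query shorter than fragment_length")
  rstarts <- .fragment_starts(r$bounds, fragment_length)
  if (length(rstarts) == 0L)
    stop("no fragments: reference shorter than fragment_length")

  fwd <- .map_fragments_cpp(q$codes, r$codes, qstarts, fragment_length,
                            seed_k, seed_step, r$bounds)
  rev_ <- .map_fragments_cpp(r$codes, q$codes, rstarts, fragment_length,
                             seed_k, seed_step, q$bounds)
  keep_f <- fwd[, 1] >= 0 & !is.na(fwd[, 2]) & fwd[, 2] >= min_fragment_identity &
    fwd[, 3] >= min_fragment_coverage
  keep_r <- rev_[, 1] >= 0 & !is.na(rev_[, 2]) & rev_[, 2] >= min_fragment_identity &
    rev_[, 3] >= min_fragment_coverage

  half <- fragment_length / 2
  bidir <- logical(length(qstarts))
  for (i in which(keep_f)) {
    mid <- fwd[i, 1] + half
    j <- findInterval(mid, rstarts)
    if (j < 1L) next
    if (mid >= rstarts[j] + fragment_length) next   # midpoint in discarded remainder
    if (!keep_r[j]) next
    back_mid <- rev_[j, 1] + half
    if (abs(back_mid - (qstarts[i] + half)) <= half) bidir[i] <- TRUE
  }

  n_bid <- sum(bidir)
  structure(list(
    query_id = q$id, ref_id = r$id,
    ani = if (n_bid >= 1L) mean(fwd[bidir, 2]) else NA_real_,
    shared_fraction = n_bid / length(qstarts),
    n_fragments = length(qstarts), n_bidirectional = n_bid,
    fragment_length = fragment_length,
    fragments = data.frame(fragment = seq_along(qstarts),
                           query_start = qstarts,
                           ref_start = ifelse(fwd[, 1] < 0, NA_integer_, fwd[, 1]),
                           identity = fwd[, 2],
                           aligned_fraction = fwd[, 3],
                           bidirectional = bidir)),
    class = "ani_pair")
}

#' @export
print.ani_pair <- function(x, ...) {
  cat(sprintf("<ani_pair> %s vs %s (reference): ANI = %s, shared fraction = %.3f (%d/%d fragments)\n",
              x$query_id, x$ref_id,
              if (is.na(x$ani)) "undefined" else sprintf("%.3f%%", x$ani),
              x$shared_fraction, x$n_bidirectional, x$n_fragments))
  invisible(x)
}

#' All-vs-all ANI pair table
#'
#' One row per unordered genome pair, computed with the longer genome as the
#' reference (ties broken toward the lexicographically smaller id as
#' reference); the reverse comparison is omitted. Pairs with undefined ANI
#' (no bidirectional fragment) carry `NA` in the `ani` column.
#'
#' @param genomes list of `genome_record`.
#' @inheritParams compute_ani
#' @return a data.frame of class `ani_pair_table` with columns query_id,
#'   ref_id, ani, shared_fraction, n_fragments, n_bidirectional.
#' @export
pair_table <- function(genomes, fragment_length = 3000L,
                       min_fragment_identity = 80, seed_k = 16L,
                       seed_step = 25L, min_fragment_coverage = 0.8) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome_ids")
  n <- length(genomes)
  empty <- data.frame(query_id = character(0), ref_id = character(0),
                      ani = numeric(0), shared_fraction = numeric(0),
                      n_fragments = integer(0), n_bidirectional = integer(0))
  class(empty) <- c("ani_pair_table", "data.frame")
  if (n < 2L) return(empty)
  lens <- vapply(genomes, function(g) sum(nchar(g$contigs)), numeric(1))
  rows <- vector("list", n * (n - 1L) %/% 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ref_is_i <- lens[i] > lens[j] || (lens[i] == lens[j] && ids[i] < ids[j])
    qi <- if (ref_is_i) j else i
    ri <- if (ref_is_i) i else j
    ap <- compute_ani(genomes[[qi]], genomes[[ri]], fragment_length,
                      min_fragment_identity, seed_k, seed_step,
                      min_fragment_coverage)
    k <- k + 1L
    rows[[k]] <- data.frame(query_id = ids[qi], ref_id = ids[ri],
                            ani = ap$ani, shared_fraction = ap$shared_fraction,
                            n_fragments = ap$n_fragments,
                            n_bidirectional = ap$n_bidirectional)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ani_pair_table", "data.frame")
  out
}

#' Shared gene content between two annotated genomes
#'
#' Orthologs are reciprocal best hits among the (strand-normalised) gene
#' sequences with ungapped identity at or above `min_gene_identity`. The
#' shared gene fraction is the ortholog count divided by the mean gene count
#' of the two genomes; non-shared genes keep their category labels
#' (`annotated` vs `hypothetical/mobile`), which feeds the enrichment test.
#'
#' @param a,b annotated `genome_record` objects.
#' @param min_gene_identity percent identity for calling orthologs.
#' @return object of class `gene_share`.
#' @export
shared_gene_fraction <- function(a, b, min_gene_identity = 95) {
  if (nrow(a$genes) == 0L || nrow(b$genes) == 0L)
    stop("both genomes must carry gene annotations")
  sa <- lapply(gene_seqs(a), seq_codes)
  sb <- lapply(gene_seqs(b), seq_codes)
  idm <- .gene_identity_cpp(sa, sb)
  best_b <- max.col(idm, ties.method = "first")
  best_a <- max.col(t(idm), ties.method = "first")
  ia <- seq_len(nrow(idm))
  rbh <- best_a[best_b] == ia &
    idm[cbind(ia, best_b)] >= min_gene_identity
  orth <- data.frame(gene_a = a$genes$gene_id[which(rbh)],
                     gene_b = b$genes$gene_id[best_b[which(rbh)]],
                     identity = idm[cbind(which(rbh), best_b[which(rbh)])],
                     stringsAsFactors = FALSE)
  ns_a <- a$genes[!a$genes$gene_id %in% orth$gene_a, c("gene_id", "category")]
  ns_b <- b$genes[!b$genes$gene_id %in% orth$gene_b, c("gene_id", "category")]
  structure(list(
    a_id = a$genome_id, b_id = b$genome_id,
    shared_gene_fraction = nrow(orth) / mean(c(nrow(a$genes), nrow(b$genes))),
    orthologs = orth, nonshared_a = ns_a, nonshared_b = ns_b,
    n_genes_a = nrow(a$genes), n_genes_b = nrow(b$genes)),
    class = "gene_share")
}

#' @export
print.gene_share <- function(x, ...) {
  cat(sprintf("<gene_share> %s vs %s: shared fraction %.4f (%d orthologs; %d + %d nonshared)\n",
              x$a_id, x$b_id, x$shared_gene_fraction, nrow(x$orthologs),
              nrow(x$nonshared_a), nrow(x$nonshared_b)))
  invisible(x)
}

#' Write / read an ANI pair table as TSV
#'
#' Undefined ANI values are stored as `NA` and parsed back as `NA`.
#' @param pairs an `ani_pair_table`.
#' @param path file path.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "ref_id", "ani", "shared_fraction",
            "n_fragments", "n_bidirectional")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("pair table schema error: missing column(s) ", paste(miss, collapse = ", "))
  out$ani <- suppressWarnings(as.numeric(out$ani))
  class(out) <- c("ani_pair_table", "data.frame")
  out
}
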