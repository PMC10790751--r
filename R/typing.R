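# MLST-style sequence typing from 7 designated core loci, and concordance
# between ST labels and ANI-threshold clusters.

#' Assign sequence types from 7 MLST loci
#'
#' Alleles are exact nucleotide sequence matches (case-insensitive,
#' strand-normalised to the annotated strand); allele and ST numbers are
#' assigned in order of first appearance over the genome input order,
#' starting at 1. A genome missing any locus is left unassigned (`NA` ST) and
#' flagged.
#'
#' @param genomes list of `genome_record`, each carrying `locus_tags`.
#' @param loci the 7 locus names; default: the locus tags of the first genome.
#' @return object of class `st_assignment` with per-locus allele tables and a
#'   profile table (genome_id, one column per locus, st).
#' @export
assign_st <- function(genomes, loci = NULL) {
  if (is.null(loci)) loci <- names(genomes[[1]]$locus_tags)
  if (length(loci) != 7L) stop("exactly 7 loci are required")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  # per locus: named integer vector mapping allele sequence -> allele number
  alleles <- setNames(rep(list(setNames(integer(0), character(0))), 7L), loci)
  prof <- matrix(NA_integer_, nrow = length(genomes), ncol = 7L,
                 dimnames = list(ids, loci))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    for (lc in loci) {
      gid <- if (lc %in% names(g$locus_tags)) g$locus_tags[[lc]] else NA_character_
      if (is.na(gid)) next
      row <- g$genes[g$genes$gene_id == gid, ]
      if (nrow(row) != 1L) next
      s <- toupper(gene_seq(g, row[1, ]))
      num <- alleles[[lc]][s]
      if (is.na(num)) {
        num <- length(alleles[[lc]]) + 1L
        alleles[[lc]][s] <- num
      }
      prof[i, lc] <- num
    }
  }
  complete <- !apply(is.na(prof), 1L, any)
  profile_key <- apply(prof, 1L, paste, collapse = "-")
  st <- rep(NA_integer_, length(genomes))
  seen <- character(0)
  for (i in which(complete)) {
    j <- match(profile_key[i], seen)
    if (is.na(j)) { seen <- c(seen, profile_key[i]); j <- length(seen) }
    st[i] <- j
  }
  structure(list(loci = loci, alleles = alleles,
                 profiles = data.frame(genome_id = ids, prof, st = st,
                                       row.names = NULL, check.names = FALSE),
                 n_unassigned = sum(!complete)),
            class = "st_assignment")
}

#' @export
print.st_assignment <- function(x, ...) {
  n_st <- length(unique(x$profiles$st[!is.na(x$profiles$st)]))
  cat(sprintf("<st_assignment> %d genomes, %d ST(s), %d unassigned; loci: %s\n",
              nrow(x$profiles), n_st, x$n_unassigned,
              paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Pairwise concordance of ST labels with an ANI threshold
#'
#' Over all unordered genome pairs in the pair table (restricted to genomes
#' with an assigned ST), with the ST as predictor and the ANI unit as
#' reference: TP = same ST and ANI >= threshold; FP = same ST and ANI below
#' (or undefined); FN = different ST and ANI >= threshold. Precision
#' TP/(TP+FP) answers "do same-ST genomes really share >=99.5% ANI?", recall
#' TP/(TP+FN) answers "do >=99.5%-ANI pairs share an ST?".
#'
#' @param st an [assign_st()] result.
#' @param pairs `ani_pair_table`.
#' @param threshold percent ANI.
#' @return object of class `concordance_report`.
#' @export
pairwise_concordance <- function(st, pairs, threshold = 99.5) {
  prof <- st$profiles
  have <- prof$genome_id[!is.na(prof$st)]
  excluded <- setdiff(unique(c(pairs$query_id, pairs$ref_id)), have)
  if (length(excluded))
    message(sprintf("excluding %d genome(s) without ST", length(excluded)))
  p <- pairs[pairs$query_id %in% have & pairs$ref_id %in% have, , drop = FALSE]
  st_of <- setNames(prof$st, prof$genome_id)
  same <- st_of[p$query_id] == st_of[p$ref_id]
  ge <- !is.na(p$ani) & p$ani >= threshold
  tp <- sum(same & ge); fp <- sum(same & !ge); fn <- sum(!same & ge)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  by_st <- do.call(rbind, lapply(split(seq_len(nrow(p)), st_of[p$query_id]),
    function(idx) {
      s <- same[idx]
      data.frame(n_pairs_anchored = length(idx),
                 same_st_pairs = sum(s),
                 tp = sum(s & ge[idx]), fp = sum(s & !ge[idx]))
    }))
  structure(list(threshold = threshold, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 n_pairs = nrow(p), n_excluded = length(excluded),
                 by_st = by_st),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> ST vs ANI >= %g%% over %d pairs\n",
              x$threshold, x$n_pairs))
  cat(sprintf("  TP = %d, FP = %d, FN = %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision = %s, recall = %s, F1 = %s\n",
              format(x$precision, digits = 4), format(x$recall, digits = 4),
              format(x$f1, digits = 4)))
  if (x$n_excluded) cat(sprintf("  (%d genome(s) without ST excluded)\n", x$n_excluded))
  invisible(x)
}
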