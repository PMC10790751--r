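# Nested intra-species units by ANI threshold: genomospecies (95%),
# genomovar (99.5%, the midpoint of the 99.2-99.8% gap), strain (>99.99%).

#' Unit thresholds
#'
#' @param genomospecies,genomovar,strain percent ANI thresholds, strictly
#'   increasing with `strain <= 100`.
#' @return object of class `unit_thresholds`.
#' @export
unit_thresholds <- function(genomospecies = 95, genomovar = 99.5, strain = 99.99) {
  if (!(genomospecies < genomovar && genomovar < strain && strain <= 100))
    stop("thresholds must satisfy genomospecies < genomovar < strain <= 100")
  structure(list(genomospecies = genomospecies, genomovar = genomovar,
                 strain = strain), class = "unit_thresholds")
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Cluster genomes by an ANI threshold (single linkage)
#'
#' Builds a graph with an edge for every pair at or above the threshold
#' (strictly above when `strict = TRUE`, matching the ">99.99% ANI" strain
#' definition) and returns its connected components. Missing/undefined ANI is
#' treated as below threshold. Cluster labels are the smallest genome id in
#' each component, so the partition is deterministic and invariant to row
#' order.
#'
#' @param pairs `ani_pair_table` (or data.frame with query_id, ref_id, ani).
#' @param threshold percent ANI.
#' @param strict use `>` instead of `>=`.
#' @param genomes optional character vector of all genome ids (needed to
#'   report singletons absent from the pair table).
#' @return object of class `unit_assignment`: named character vector mapping
#'   genome id to cluster label.
#' @export
cluster_by_ani <- function(pairs, threshold, strict = FALSE, genomes = NULL) {
  if (!(threshold > 0 && threshold <= 100)) stop("threshold must be in (0, 100]")
  ids <- sort(unique(c(pairs$query_id, pairs$ref_id, genomes)))
  if (length(ids) == 0L) stop("no genomes")
  key <- .pair_key(pairs$query_id, pairs$ref_id)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    agree <- all(vapply(split(pairs$ani[dup], key[dup]), function(a)
      length(unique(a)) == 1L || all(is.na(a)), logical(1)))
    if (!agree) stop("conflicting duplicate pairs in table")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  hit <- !is.na(pairs$ani) & (if (strict) pairs$ani > threshold else pairs$ani >= threshold)
  g <- igraph::graph_from_data_frame(
    pairs[hit, c("query_id", "ref_id"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  labels <- vapply(split(names(comp), comp), min, character(1))
  out <- setNames(unname(labels[as.character(comp[ids])]), ids)
  structure(out, threshold = threshold, strict = strict,
            linkage = "single", class = "unit_assignment")
}

#' @export
print.unit_assignment <- function(x, ...) {
  cat(sprintf("<unit_assignment> threshold %s%g%% ANI (single linkage): %d genomes in %d cluster(s)\n",
              if (attr(x, "strict")) ">" else ">=", attr(x, "threshold"),
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Nested unit assignments at the three canonical thresholds
#'
#' Single-linkage clusters at the genomospecies (>=95%), genomovar (>=99.5%)
#' and strain (>99.99%) thresholds. Because the edge sets are nested, the
#' strain partition refines the genomovar partition, which refines the
#' genomospecies partition.
#'
#' @param pairs `ani_pair_table`.
#' @param thresholds a [unit_thresholds()].
#' @param genomes optional character vector of all genome ids.
#' @return object of class `unit_assignments`: list with one
#'   `unit_assignment` per level.
#' @export
nested_units <- function(pairs, thresholds = unit_thresholds(), genomes = NULL) {
  stopifnot(inherits(thresholds, "unit_thresholds"))
  out <- list(
    genomospecies = cluster_by_ani(pairs, thresholds$genomospecies,
                                   strict = FALSE, genomes = genomes),
    genomovar = cluster_by_ani(pairs, thresholds$genomovar,
                               strict = FALSE, genomes = genomes),
    strain = cluster_by_ani(pairs, thresholds$strain,
                            strict = TRUE, genomes = genomes))
  structure(out, class = "unit_assignments")
}

#' @export
print.unit_assignments <- function(x, ...) {
  for (lv in names(x))
    cat(sprintf("%-14s %s%g%%: %d cluster(s)\n", lv,
                if (attr(x[[lv]], "strict")) ">" else ">=",
                attr(x[[lv]], "threshold"), length(unique(unclass(x[[lv]])))))
  invisible(x)
}

#' @export
as.data.frame.unit_assignments <- function(x, ...) {
  ids <- names(x$genomospecies)
  data.frame(genome_id = ids,
             genomospecies = unclass(x$genomospecies)[ids],
             genomovar = unclass(x$genomovar)[ids],
             strain = unclass(x$strain)[ids],
             row.names = NULL, stringsAsFactors = FALSE)
}

# does partition `fine` refine partition `coarse`? (same names)
refines <- function(fine, coarse) {
  ids <- names(fine)
  all(vapply(split(unclass(coarse)[ids], unclass(fine)[ids]),
             function(g) length(unique(g)) == 1L, logical(1)))
}
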