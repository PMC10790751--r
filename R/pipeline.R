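# Orchestration: simulate -> ANI -> gap scan -> units -> typing -> enrichment,
# with a machine-readable summary.

#' Pipeline configuration
#'
#' @param seed master seed; drives the simulation and all Monte-Carlo stages.
#' @param sim a [sim_config()] (defaults to one built from `seed`).
#' @param thresholds a [unit_thresholds()].
#' @param floor,beta,n_boot gap-scan settings (see [gap_scan()]).
#' @param fragment_length,min_fragment_identity ANI settings.
#' @param stages character vector of stages to run, in dependency order.
#' @param outdir optional output directory for FASTA/TSV/JSON artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            thresholds = unit_thresholds(),
                            floor = 95, beta = 0.5, n_boot = 500L,
                            fragment_length = 3000L,
                            min_fragment_identity = 80,
                            stages = c("simulate", "ani", "gaps", "cluster",
                                       "type", "concord", "enrich"),
                            outdir = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), sim = sim, thresholds = thresholds,
                 floor = floor, beta = beta, n_boot = as.integer(n_boot),
                 fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 stages = stages, outdir = outdir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)[setdiff(names(unclass(config)), "outdir")]), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a simulated species
#'
#' Executes the enabled stages in dependency order and returns (and
#' optionally writes) a summary: species classification, unit counts at the
#' three thresholds, ST/ANI concordance, and the mobile-gene enrichment test.
#' Every artifact carries the configuration hash; rerunning with the same
#' config gives byte-identical output.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result` (invisibly writes artifacts when
#'   `config$outdir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_hash(config)
  msg <- function(...) message(sprintf("[anigap %s] ", substr(hash, 1, 8)),
                               sprintf(...))
  out <- list(config_hash = hash, seed = config$seed)
  st <- function(s) s %in% config$stages

  if (!st("simulate")) stop("pipeline currently starts from the simulate stage")
  msg("simulate: %d x %d genomes, scenario '%s'", config$sim$n_genomovars,
      config$sim$genomes_per_genomovar, config$sim$scenario)
  sim <- simulate_species(config$sim)
  out$n_genomes <- length(sim$genomes)
  out$truth_genomovars <- length(unique(sim$truth$genomovar))

  pairs <- NULL
  if (st("ani")) {
    msg("ani: %d genome pair(s)", choose(length(sim$genomes), 2))
    pairs <- pair_table(sim$genomes, fragment_length = config$fragment_length,
                        min_fragment_identity = config$min_fragment_identity)
    out$n_pairs <- nrow(pairs)
  }

  if (st("gaps") && !is.null(pairs) && nrow(pairs) > 0L) {
    msg("gaps: scanning ANI distribution")
    gr <- gap_scan(pairs$ani, species_id = "simulated", floor = config$floor,
                   beta = config$beta, n_boot = config$n_boot,
                   seed = config$seed)
    out$gap <- list(classification = gr$classification, dip = gr$dip,
                    p_value = gr$p_value,
                    valleys = gr$valleys)
    out$gap_report <- gr
  }

  if (st("cluster") && !is.null(pairs)) {
    units <- nested_units(pairs, config$thresholds,
                          genomes = names(sim$genomes))
    out$units <- units
    out$unit_counts <- vapply(units, function(u) length(unique(unclass(u))),
                              integer(1))
    msg("cluster: %s", paste(names(out$unit_counts), out$unit_counts,
                             sep = "=", collapse = ", "))
  }

  if (st("type")) {
    sta <- assign_st(sim$genomes)
    out$st <- sta
    if (st("concord") && !is.null(pairs) && nrow(pairs) > 0L) {
      out$concordance <- pairwise_concordance(sta, pairs,
                                              config$thresholds$genomovar)
      msg("concord: precision %.3f, recall %.3f",
          out$concordance$precision, out$concordance$recall)
    }
  }

  if (st("enrich") && !is.null(pairs) && nrow(pairs) > 0L) {
    shares <- lapply(seq_len(nrow(pairs)), function(i)
      shared_gene_fraction(sim$genomes[[pairs$query_id[i]]],
                           sim$genomes[[pairs$ref_id[i]]]))
    out$enrichment <- tryCatch(enrichment_test(pairs, shares),
                               error = function(e) {
                                 msg("enrich: %s", conditionMessage(e)); NULL
                               })
    out$gene_shares <- shares
  }

  out$sim <- sim
  out$pairs <- pairs
  if (!is.null(config$outdir)) .write_pipeline(out, config)
  structure(out, class = "pipeline_result")
}

.write_pipeline <- function(out, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_species(out$sim$genomes, out$sim$truth,
                file.path(config$outdir, "species"))
  if (!is.null(out$pairs))
    write_pair_table(out$pairs, file.path(config$outdir, "pairs.tsv"))
  if (!is.null(out$units))
    write.table(as.data.frame(out$units),
                file.path(config$outdir, "units.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    config_hash = out$config_hash, seed = out$seed,
    n_genomes = out$n_genomes, n_pairs = out$n_pairs,
    truth_genomovars = out$truth_genomovars,
    classification = out$gap$classification,
    dip = out$gap$dip, dip_p = out$gap$p_value,
    valleys = out$gap$valleys,
    unit_counts = as.list(out$unit_counts),
    concordance = if (!is.null(out$concordance))
      out$concordance[c("threshold", "tp", "fp", "fn",
                        "precision", "recall", "f1")],
    enrichment = if (!is.null(out$enrichment))
      out$enrichment[c("k_A", "n_A", "k_B", "n_B", "z", "p_value")])
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> config %s, seed %d\n",
              substr(x$config_hash, 1, 8), x$seed))
  cat(sprintf("  %d genomes (%d planted genomovars), %s pairs\n",
              x$n_genomes, x$truth_genomovars,
              if (is.null(x$n_pairs)) "no" else x$n_pairs))
  if (!is.null(x$gap))
    cat(sprintf("  gap classification: %s (dip %.4f, p %.4g)\n",
                x$gap$classification, x$gap$dip, x$gap$p_value))
  if (!is.null(x$unit_counts))
    cat(sprintf("  units: %s\n", paste(names(x$unit_counts), x$unit_counts,
                                       sep = "=", collapse = ", ")))
  if (!is.null(x$concordance))
    cat(sprintf("  ST concordance: precision %.3f, recall %.3f\n",
                x$concordance$precision, x$concordance$recall))
  if (!is.null(x$enrichment))
    cat(sprintf("  mobile-gene enrichment: z = %.3f, p = %.3g\n",
                x$enrichment$z, x$enrichment$p_value))
  invisible(x)
}
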