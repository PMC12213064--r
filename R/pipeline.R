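# End-to-end orchestration: simulate (or load) inputs, scan conserved
# columns, run the translated search, accumulate the codon matrix, call the
# genetic code, and (optionally) reconstruct gene content and genome
# statistics.  Every run records a manifest (parameters, seed, per-stage
# output checksums) so reruns under the same seed are verifiably identical.

#' Simulate a study and infer its genetic code in memory
#'
#' The core demonstration: generate reference families and a target genome
#' under a chosen genetic code, then recover the code from scratch.  Used by
#' the file-based pipeline, the test-suite and the acceptance script.
#'
#' @param seed Integer seed.
#' @param genetic_code `"standard"` or `"uga_trp"`.
#' @param hcaa_threshold Conservation threshold for HCAA columns.
#' @param min_count,dominance Assignment thresholds, see
#'   [infer_genetic_code()].
#' @param score_threshold Translated-search score threshold.
#' @param ... Overrides forwarded to [sim_config()].
#' @return List with `config`, `families`, `genome` (list from
#'   [simulate_genome()]), `hcaa`, `observations`, `matrix`
#'   (a `codon_matrix`) and `call` (a `genetic_code_call`).
#' @export
simulate_and_infer <- function(seed, genetic_code = c("uga_trp", "standard"),
                               hcaa_threshold = 0.90, min_count = 10,
                               dominance = 0.8, score_threshold = 60, ...) {
  genetic_code <- match.arg(genetic_code)
  config <- sim_config(seed = seed, genetic_code = genetic_code, ...)
  families <- simulate_marker_families(config)
  genome <- simulate_genome(families, config)
  hcaa <- identify_hcaa(families$alignments, threshold = hcaa_threshold)
  observations <- codon_observations(genome$genome, families$alignments,
                                     hcaa = hcaa,
                                     score_threshold = score_threshold)
  mat <- codon_matrix(observations)
  call <- infer_genetic_code(mat, min_count = min_count, dominance = dominance)
  list(config = config, families = families, genome = genome, hcaa = hcaa,
       observations = observations, matrix = mat, call = call)
}

#' Build a pipeline configuration
#'
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @param genetic_code Simulated genome's code (`"uga_trp"`/`"standard"`).
#' @param hcaa_threshold,min_count,dominance,score_threshold,window,step
#'   Stage parameters.
#' @param sim Named list of [sim_config()] overrides.
#' @param run_gene_content Also simulate an orthogroup matrix and account
#'   for losses.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, outdir,
                            genetic_code = "uga_trp",
                            hcaa_threshold = 0.90,
                            min_count = 10, dominance = 0.8,
                            score_threshold = 60,
                            window = 2000, step = 500,
                            sim = list(),
                            run_gene_content = TRUE) {
  structure(
    list(seed = as.integer(seed), outdir = outdir,
         genetic_code = genetic_code, hcaa_threshold = hcaa_threshold,
         min_count = min_count, dominance = dominance,
         score_threshold = score_threshold, window = window, step = step,
         sim = sim, run_gene_content = run_gene_content),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the simulate -> infer -> report pipeline
#'
#' Executes HCAA scanning, the six-frame translated search, codon-matrix
#' accumulation, genetic-code calling and translation-table selection on a
#' simulated genome; optionally also the orthogroup loss accounting and
#' genome statistics.  All stage outputs are written under
#' `config$outdir` and checksummed into `manifest.json`.
#'
#' @param config A `pipeline_config` (or path to its YAML form).
#' @return Invisibly, a list with the in-memory results
#'   ([simulate_and_infer()] fields, plus `ledger`, `stats`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config or a YAML path")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  inform(sprintf("pipeline seed: %d", config$seed))
  t0 <- Sys.time()

  res <- do.call(simulate_and_infer, c(
    list(seed = config$seed, genetic_code = config$genetic_code,
         hcaa_threshold = config$hcaa_threshold,
         min_count = config$min_count, dominance = config$dominance,
         score_threshold = config$score_threshold),
    config$sim
  ))

  out <- function(name) file.path(config$outdir, name)
  write_genome_fasta(res$genome$genome, out("genome.fasta"))
  write_truth_gff3(res$genome$genes, out("genes.gff3"),
                   code = config$genetic_code)
  write_hcaa_tsv(res$hcaa, out("hcaa.tsv"))
  write_codon_matrix_tsv(res$matrix, out("codon_matrix.tsv"))
  utils::write.table(tidyr::pivot_wider(res$call$probs, names_from = "aa",
                                        values_from = "p"),
                     out("logo_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_code_call_json(res$call, out("code_call.json"))

  if (isTRUE(config$run_gene_content)) {
    og <- simulate_orthogroups(seed = config$seed)
    ancestral <- infer_ancestral_proteome(og$matrix, og$roles)
    targets <- names(og$roles)[og$roles == "target"]
    res$ledger <- partition_losses(og$matrix, ancestral, targets)
    write_orthogroup_tsv(og$matrix, out("orthogroups.tsv"))
    write_ledger_json(res$ledger, out("loss_ledger.json"))
  }

  res$stats <- genome_stats(res$genome$genome, res$genome$genes,
                            window = config$window, step = config$step,
                            code = config$genetic_code)
  jsonlite::write_json(
    list(genome_length = res$stats$genome_length, gc = res$stats$gc,
         n_genes = res$stats$n_genes, gc3 = res$stats$gc3),
    out("stats.json"), auto_unbox = TRUE, digits = NA
  )

  files <- sort(setdiff(list.files(config$outdir, full.names = TRUE),
                        out("manifest.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("symbiocode")),
    seed = config$seed,
    parameters = config[c("genetic_code", "hcaa_threshold", "min_count",
                          "dominance", "score_threshold", "window", "step")],
    selected_table = res$call$selected_table,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  inform(sprintf("selected translation table: %s", res$call$selected_table))
  invisible(res)
}
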