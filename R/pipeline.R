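#' Run configuration for the end-to-end pipeline
#'
#' Collects geometry, screening, scoring and simulation parameters with
#' validated defaults.  The resolved configuration (including the seed) is
#' serialized into every output directory for provenance.
#'
#' @param geometry list of [library_geometry()] arguments (empty list =
#'   paper-scale defaults).
#' @param mode screening mode, see [screening_dimensions()].
#' @param dimensions explicit dimensions for `mode = "custom"`.
#' @param thresholds list of [scoring_thresholds()] arguments.
#' @param sim list of [signal_params()] arguments.
#' @param n_loci number of homoeologous locus pairs to simulate.
#' @param copy_numbers optional integer vector (recycled over loci); `NULL`
#'   draws zero-truncated Poisson(10.6) copy numbers.
#' @param seed integer seed governing every random stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = list(), mode = "opa1_8dim",
                       dimensions = NULL, thresholds = list(), sim = list(),
                       n_loci = 4L, copy_numbers = NULL, seed = 1L) {
  cfg <- list(geometry = geometry, mode = mode, dimensions = dimensions,
              thresholds = thresholds, sim = sim,
              n_loci = as.integer(n_loci), copy_numbers = copy_numbers,
              seed = as.integer(seed))
  # fail early on invalid parameters
  do.call(library_geometry, cfg$geometry)
  screening_dimensions(cfg$mode, cfg$dimensions)
  do.call(scoring_thresholds, cfg$thresholds)
  do.call(signal_params, cfg$sim)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full screening pipeline
#'
#' design -> simulate -> score -> deconvolve -> evaluate.  One intergenomic
#' assay is simulated per locus pair (an A-genome and a C-genome homoeolog
#' placed independently).  Every stage's output is written into `out_dir`:
#' `config.json`, `pool_manifest.tsv`, `truth.tsv`, `known.tsv`,
#' `signals.csv`, `calls.tsv`, `putative.tsv`, `report.tsv`, `audit.tsv`.
#' Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results (`design`,
#'   `screen`, `calls`, `candidates`, `report`, `audit`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  geometry <- do.call(library_geometry, config$geometry)
  dims <- screening_dimensions(config$mode, config$dimensions)
  design <- build_design(geometry, dims)
  say("design: %d dimensions, %d pools, %d clones",
      length(dims), sum(design$pool_counts), geometry$n_clones)
  write_pool_manifest(design, file.path(out_dir, "pool_manifest.tsv"))

  set.seed(config$seed)
  cn <- config$copy_numbers
  placements <- list(); assays <- list()
  for (i in seq_len(config$n_loci)) {
    la <- place_locus(design, sprintf("locus%02d.A", i), "A",
                      copy_number = if (is.null(cn)) NULL else
                        cn[(2L * i - 2L) %% length(cn) + 1L])
    lc <- place_locus(design, sprintf("locus%02d.C", i), "C",
                      copy_number = if (is.null(cn)) NULL else
                        cn[(2L * i - 1L) %% length(cn) + 1L])
    placements <- c(placements, list(la, lc))
    assays[[i]] <- assay_definition(sprintf("assay%02d", i), "intergenomic",
                                    allele1_loci = la$locus_id,
                                    allele2_loci = lc$locus_id)
  }
  params <- do.call(signal_params, config$sim)
  screen <- simulate_screen(design, placements, assays, params)
  say("simulate: %d records (%d assays x %d pools)", nrow(screen$records),
      length(assays), sum(design$pool_counts))
  write_signal_table(screen$records, file.path(out_dir, "signals.csv"))
  data.table::fwrite(screen$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  known <- stats::setNames(lapply(placements, `[[`, "clones"),
                           vapply(placements, `[[`, "", "locus_id"))
  write_known_coordinates(known, file.path(out_dir, "known.tsv"), geometry)

  th <- do.call(scoring_thresholds, config$thresholds)
  calls <- score_table(screen$records, th)
  data.table::fwrite(calls, file.path(out_dir, "calls.tsv"), sep = "\t")

  cands <- deconvolve_all(design, calls, assays, mode = config$mode,
                          dimensions = config$dimensions)
  write_candidates(cands, file.path(out_dir, "putative.tsv"), geometry)

  report <- data.table::rbindlist(lapply(cands, function(cs) {
    loci <- if (cs$allele == "snp1")
      assays[[match(cs$assay_id, vapply(assays, `[[`, "", "assay_id"))]]$allele1_loci
    else
      assays[[match(cs$assay_id, vapply(assays, `[[`, "", "assay_id"))]]$allele2_loci
    stats <- confirm(cs, unlist(known[loci]))
    stats[, locus_id := paste(loci, collapse = "+")]
    stats
  }))
  data.table::fwrite(report, file.path(out_dir, "report.tsv"), sep = "\t")

  audits <- data.table::rbindlist(lapply(assays, function(a) {
    expd <- expected_calls(design, known, a, dims)
    audit_pools(calls[assay_id == a$assay_id], expd, r_min = th$r_min)$audit
  }))
  data.table::fwrite(audits, file.path(out_dir, "audit.tsv"), sep = "\t")
  say("evaluate: %.1f%% of pool calls consistent",
      100 * mean(audits$category == "consistent"))

  resolved <- unclass(config)
  resolved$screening_dimensions <- dims
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(design = design, screen = screen, calls = calls,
                 candidates = cands, report = report, audit = audits,
                 known = known))
}
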