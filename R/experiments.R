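# End-to-end orchestration of the named experiments (A1, A10, A64, B1, B10,
# B27, C/D/E series, and the A+ head-to-head grid) from a single
# configuration with reproducible seeds.

ERROR_PRESETS <- c(MT = 0.010, DT = 0.004, QB = 0.004)

#' Experiment configuration
#'
#' An experiment id combines a template-pool letter (A-E) with a
#' primer-pool size (1, 9, 10, 27 or 64), e.g. "B27" = all ten equimolar
#' templates amplified with the 27 double-mismatch primers.
#'
#' @param experiment_id Tag like "A10" or "B27".
#' @param method "depcr" or "standard".
#' @param temperature Annealing temperature (45 or 55 in the default
#'   calibration).
#' @param n_replicates Technical replicates (default 8).
#' @param reads_per_replicate Reads per replicate (default 20000, so the
#'   default rarefaction depth of 7000 always succeeds).
#' @param error_preset "MT" (non-proofreading, 0.010/base), "DT" or "QB"
#'   (phosphorothioate-protected, 0.004/base), or "none".
#' @param classification_mode Passed to [classify_reads()].
#' @param rarefaction_depth Depth for [rarefy()]; `NA` disables rarefaction.
#' @param scrambling_mode Standard-PCR copy-annealing mode.
#' @param min_mean_quality Quality filter threshold.
#' @param seed Root seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment_id, method = c("depcr", "standard"),
                              temperature = 55, n_replicates = 8L,
                              reads_per_replicate = 20000L,
                              error_preset = c("MT", "DT", "QB", "none"),
                              classification_mode = "full_primer",
                              rarefaction_depth = 7000L,
                              scrambling_mode = "neutral",
                              min_mean_quality = 20, seed = 1L) {
  method <- match.arg(method)
  error_preset <- match.arg(error_preset)
  m <- regmatches(experiment_id,
                  regexec("^([A-E])(1|9|10|27|64)$", experiment_id))[[1]]
  if (length(m) == 0L) {
    stop("unknown experiment id: ", experiment_id,
         " (expected <template pool A-E><primer pool 1|9|10|27|64>)",
         call. = FALSE)
  }
  structure(list(experiment_id = experiment_id,
                 template_pool_id = m[2], primer_pool_id = m[3],
                 method = method, temperature = temperature,
                 n_replicates = as.integer(n_replicates),
                 reads_per_replicate = as.integer(reads_per_replicate),
                 error_preset = error_preset,
                 per_base_error_rate = if (error_preset == "none") 0 else
                   unname(ERROR_PRESETS[error_preset]),
                 classification_mode = classification_mode,
                 rarefaction_depth = rarefaction_depth,
                 scrambling_mode = scrambling_mode,
                 min_mean_quality = min_mean_quality,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one experiment end to end
#'
#' Executes design -> simulate -> emit -> classify -> rarefy -> metrics ->
#' report. All randomness derives from the config seed, so re-running with
#' the same config reproduces all outputs.
#'
#' @param config An [experiment_config()].
#' @param design A design list (default [default_design()]).
#' @param model An [efficiency_model()].
#' @param out_dir Optional run directory for FASTQ, matrix TSV and report.
#' @return A `depcr_run` list with elements `config`, `matrix` (classified
#'   counts), `rarefied`, `metrics` (per-replicate ITS/IPS/mismatch ratio),
#'   `assignment_counts` and `report`.
#' @export
run_experiment <- function(config, design = default_design(),
                           model = default_efficiency_model(),
                           out_dir = NULL) {
  space <- design$space
  template_pool <- make_pool(config$template_pool_id, kind = "templates")
  primer_pool <- make_pool(config$primer_pool_id, kind = "primers")
  rc <- run_config(method = config$method, temperature = config$temperature,
                   scrambling_mode = config$scrambling_mode,
                   per_base_error_rate = config$per_base_error_rate,
                   reads_per_replicate = config$reads_per_replicate,
                   n_replicates = config$n_replicates, seed = config$seed)
  sim <- if (config$method == "depcr") {
    simulate_depcr(template_pool, primer_pool, config$temperature, rc,
                   space, model)
  } else {
    simulate_standard_pcr(template_pool, primer_pool, config$temperature,
                          rc, space, model)
  }
  fastq_dir <- if (!is.null(out_dir)) file.path(out_dir, "fastq")
  reads <- emit_reads(sim, design, rc, out_dir = fastq_dir)
  all_reads <- do.call(rbind, reads)
  design_pairs <- design_pairs_of(space, template_pool, primer_pool)
  assignments <- classify_reads(all_reads, space,
                                mode = config$classification_mode,
                                design_pairs = design_pairs,
                                min_mean_quality = config$min_mean_quality)
  mat <- build_interaction_matrix(assignments, space, design_pairs,
                                  metadata = list(
                                    method = config$method,
                                    temperature = config$temperature,
                                    template_pool = template_pool$pool_id,
                                    primer_pool = primer_pool$pool_id))
  rare <- if (!is.na(config$rarefaction_depth)) {
    rarefy(mat, config$rarefaction_depth,
           seed = derive_seed(config$seed, 30000L))
  } else {
    mat
  }
  metrics <- matrix_metrics(rare, space, template_pool, primer_pool)
  manifest <- c(unclass(config),
                list(design_seed = 806L,
                     rarefaction_seed = derive_seed(config$seed, 30000L)))
  report <- experiment_report(
    manifest, metrics = metrics,
    matrices = list(classified = mat, rarefied = rare),
    out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_interaction_matrix(rare, file.path(out_dir, "matrix.tsv"))
    write_mapping_tsv(space, file.path(out_dir, "mapping.tsv"))
  }
  structure(list(config = config, simulated = sim, matrix = mat,
                 rarefied = rare, metrics = metrics,
                 assignment_counts = matrix_metadata(mat)$status_counts,
                 report = report),
            class = "depcr_run")
}

#' Head-to-head competition grid (perfect match vs one mismatch primer)
#'
#' For each single-mismatch primer, simulates DePCR amplification of the
#' ST0 template with the perfect-match primer V0 and that primer at
#' equimolar input, at each annealing temperature, and tabulates the
#' mismatch ratio per replicate with a Welch comparison between
#' temperatures.
#'
#' @param mismatch_primers Primer ids to compete against V0 (default
#'   V1-V9).
#' @param temperatures Annealing temperatures (default 45 and 55).
#' @param design A design list.
#' @param model An [efficiency_model()].
#' @param n_replicates Technical replicates per condition (default 4).
#' @param reads_per_replicate Copy events per replicate.
#' @param seed Root seed.
#' @return A data.frame with one row per (primer, temperature): mean and sd
#'   of the mismatch ratio, plus per-primer Welch p-value and stars
#'   comparing the two temperatures (when exactly two are given).
#' @export
run_head_to_head <- function(mismatch_primers = paste0("V", 1:9),
                             temperatures = c(45, 55),
                             design = default_design(),
                             model = default_efficiency_model(),
                             n_replicates = 4L,
                             reads_per_replicate = 20000L, seed = 1L) {
  space <- design$space
  template_pool <- make_pool("A", kind = "templates")
  rows <- list()
  ratios <- list()
  k <- 0L
  for (pid in mismatch_primers) {
    for (temp in temperatures) {
      k <- k + 1L
      pool <- make_pool(paste0("V0+", pid), members = c("V0", pid),
                        kind = "primers")
      rc <- run_config(method = "depcr", temperature = temp,
                       n_replicates = n_replicates,
                       reads_per_replicate = reads_per_replicate,
                       seed = derive_seed(seed, k))
      sim <- simulate_depcr(template_pool, pool, temp, rc, space, model)
      r <- apply(unclass(sim), 1L, mismatch_ratio, space)
      ratios[[paste(pid, temp)]] <- r
      prof <- mismatch_profile(
        design$primers[design$primers$primer_id == pid, ],
        design$templates[design$templates$template_id == "ST0", ],
        design$spec)
      rows[[k]] <- data.frame(
        primer = pid, temperature = temp,
        position = paste(prof$label, collapse = "+"),
        pairing = paste(prof$pairing, collapse = "+"),
        mean_ratio = mean(r), sd_ratio = stats::sd(r),
        expected_ratio = annealing_efficiency(prof, temp, model),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (length(temperatures) == 2L) {
    out$p_temperature <- NA_real_
    out$stars <- NA_character_
    for (pid in mismatch_primers) {
      a <- ratios[[paste(pid, temperatures[1])]]
      b <- ratios[[paste(pid, temperatures[2])]]
      p <- welch_t(a, b)$p
      out$p_temperature[out$primer == pid] <- p
      out$stars[out$primer == pid] <- significance_stars(p)
    }
  }
  out
}
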