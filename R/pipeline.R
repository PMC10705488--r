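# End-to-end pipeline driver: simulate -> call LOH -> correct -> compare
# strains -> power, with all intermediates written as plain text.

#' Run the full simulation-and-analysis pipeline
#'
#' Executes the stages in sequence, writing every intermediate artifact to
#' `out_dir`: marker map (`map.tsv/.json`), genotypes (`genotypes.tsv`),
#' simulation truth (`truth.json`), called events (`events.bed`),
#' per-clone corrected counts (`counts.tsv`), strain rate table and
#' pairwise permutation tests (`rates.tsv`, `tests.tsv`) and the
#' theoretical power curve (`power.tsv`). The run configuration (including
#' the seed) is serialized alongside the outputs (`config.yaml`). The run
#' is idempotent: existing outputs are reused unless `force = TRUE`, so
#' the same configuration always produces byte-identical files.
#'
#' @param config A list or path to a YAML file. Recognised fields (all
#'   optional, defaults shown by [pipeline_config()]): `seed`,
#'   `genome_size`, `n_chromosomes`, `mean_spacing`, `loh_rate`,
#'   `generations`, `n_lines`, `rate_multipliers`, `terminal_fraction`,
#'   `power_f_e`, `power_n_sims`, `power_n_perms`, `alpha`.
#' @param out_dir Output directory (created if absent).
#' @param force Recompute and overwrite existing outputs.
#' @param quiet Suppress stage log messages (written to stderr).
#' @return Invisibly, a list with the main in-memory results: `map`,
#'   `genotypes`, `events`, `counts`, `rates`, `tests`, `power`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(genome_size = 5e5, n_chromosomes = 2,
#'                          n_lines = 3, power_n_sims = 20,
#'                          power_n_perms = 100),
#'                     out_dir = tempfile("lohdrive_demo_"))
#' }
run_pipeline <- function(config = list(), out_dir, force = FALSE,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) {
    if (!quiet) message("[lohdrive:", stage, "] ", ...)
  }
  path <- function(f) file.path(out_dir, f)
  yaml::write_yaml(cfg, path("config.yaml"))

  # stage: simulate ---------------------------------------------------
  sim_done <- file.exists(path("genotypes.tsv")) &&
    file.exists(path("map.tsv"))
  if (sim_done && !force) {
    log_msg("simulate", "outputs exist, skipping (use force = TRUE)")
    map <- read_marker_map(path("map"))
    gm <- read_genotypes(path("genotypes.tsv"), map)
  } else {
    log_msg("simulate", "building map and cohort (seed ", cfg$seed, ")")
    lengths <- yeast_chrom_lengths(cfg$genome_size)
    if (cfg$n_chromosomes < 16) {
      lengths <- round(lengths[seq_len(cfg$n_chromosomes)] *
                         cfg$genome_size /
                         sum(lengths[seq_len(cfg$n_chromosomes)]))
    }
    map <- build_marker_map(lengths, mean_spacing = cfg$mean_spacing,
                            seed = derive_seed(cfg$seed, 0))
    scfg <- sim_config(
      loh_rate = cfg$loh_rate, generations = cfg$generations,
      n_lines = cfg$n_lines, terminal_fraction = cfg$terminal_fraction,
      rate_multipliers = unlist(cfg$rate_multipliers),
      seed = derive_seed(cfg$seed, 1)
    )
    sim <- simulate_cohort(map, scfg)
    gm <- sim$genotypes
    write_marker_map(map, path("map"))
    write_genotypes(gm, path("genotypes.tsv"))
    jsonlite::write_json(sim$truth, path("truth.json"), digits = NA,
                         dataframe = "columns")
  }

  # stage: call-loh ----------------------------------------------------
  if (file.exists(path("events.bed")) && !force) {
    log_msg("call-loh", "outputs exist, skipping")
    events <- read_events_bed(path("events.bed"))
  } else {
    log_msg("call-loh", "calling LOH events for ", ncol(gm$calls),
            " clones")
    events <- call_loh(gm)
    write_events_bed(events, path("events.bed"))
  }

  # stage: correct + stats ---------------------------------------------
  log_msg("stats", "correcting counts and comparing strains")
  counts <- correct_counts(events, gm$map)
  counts <- merge(data.frame(clone = gm$clones$clone,
                             founder = gm$clones$founder), counts,
                  by = "clone", all.x = TRUE)
  counts$detected[is.na(counts$detected)] <- 0L
  counts$corrected[is.na(counts$corrected)] <- 0
  write.table(counts, path("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  founders <- unique(gm$clones$founder)
  rates <- do.call(rbind, lapply(founders, function(f) {
    k <- sum(counts$corrected[counts$founder == f])
    n <- sum(counts$founder == f)
    ci <- bootstrap_ci(counts$corrected[counts$founder == f] /
                         cfg$generations,
                       seed = derive_seed(cfg$seed, 2))
    cbind(founder = f, event_rate(k, n, cfg$generations),
          ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  }))
  write.table(rates, path("rates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ref <- founders[1]
  tests <- do.call(rbind, lapply(setdiff(founders, ref), function(f) {
    tt <- permutation_test(counts$corrected[counts$founder == f],
                           counts$corrected[counts$founder == ref],
                           n_perm = cfg$power_n_perms,
                           seed = derive_seed(cfg$seed, 3))
    data.frame(comparison = paste(f, "vs", ref),
               statistic = tt$statistic, p_value = tt$p_value)
  }))
  if (!is.null(tests)) {
    write.table(tests, path("tests.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # stage: power --------------------------------------------------------
  log_msg("power", "theoretical power at the configured design")
  pw <- theoretical_power(
    mu = cfg$loh_rate * cfg$generations,
    n_lines = max(unlist(cfg$n_lines)),
    f_grid = cfg$power_f_e, alpha = cfg$alpha,
    n_sims = cfg$power_n_sims, n_perms = cfg$power_n_perms,
    seed = derive_seed(cfg$seed, 4)
  )
  write.table(pw, path("power.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(map = gm$map, genotypes = gm, events = events,
                 counts = counts, rates = rates, tests = tests,
                 power = pw))
}

#' Default pipeline configuration
#'
#' Fills unset fields of a pipeline configuration with defaults sized for
#' a quick demonstration run (a 1 Mb toy genome, 5 lines per founder).
#'
#' @param config Partial configuration list.
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    seed = 1L, genome_size = 1e6, n_chromosomes = 4, mean_spacing = 320,
    loh_rate = 1.76e-2, generations = 800, n_lines = 5,
    terminal_fraction = 0.192,
    rate_multipliers = list(W = 1, C = 1, D = 1),
    power_f_e = c(0.15, 0.3, 0.45), power_n_sims = 100,
    power_n_perms = 500, alpha = 0.01
  )
  modifyList(defaults, config)
}
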