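#' Configuration of the end-to-end pipeline
#'
#' Bundles the per-stage options of [run_pipeline()]: the synthetic-data
#' generator, estimation choices, simulation settings, and classifier
#' settings. One top-level seed fans out to per-stage sub-seeds so stages are
#' independently reproducible.
#'
#' @param seed Top-level integer seed.
#' @param generator A [generator_config()]; its own seed is overridden by the
#'   fan-out from `seed`.
#' @param summary Fitness summary statistic, `"median"` or `"mean"`.
#' @param plate_time_h Plate growth time point for plate fitness (default 72).
#' @param inoculum_basis `"od"` (1:1 protocol gives 0.5) or `"cfu"`
#'   (calibration-corrected).
#' @param n_cycles Life cycles to simulate (default 10).
#' @param mode Simulation mode, `"replicator"` or `"literal"`.
#' @param transfer_fraction,n_worm_founders,n_runs Stochastic-mode settings;
#'   `n_runs = 0` skips the stochastic ensemble.
#' @param n_species,planted Trait-table generator settings.
#' @param quantile_type,binary_antibiotics Classifier settings.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(),
                       summary = c("median", "mean"),
                       plate_time_h = 72,
                       inoculum_basis = c("od", "cfu"),
                       n_cycles = 10,
                       mode = c("replicator", "literal"),
                       transfer_fraction = 0.1,
                       n_worm_founders = 1e3,
                       n_runs = 0,
                       n_species = 8,
                       planted = NULL,
                       quantile_type = 7,
                       binary_antibiotics = FALSE) {
  summary <- rlang::arg_match(summary)
  inoculum_basis <- rlang::arg_match(inoculum_basis)
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(generator, "generator_config"))
  if (!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles)) {
    rlang::abort("n_cycles must be a positive integer",
                 class = "biphasix_config_error")
  }
  if (is.null(planted)) {
    planted <- stats::setNames(c("competitor", "stress_tolerator"),
                               c(generator$species_a, generator$species_b))
  }
  structure(list(
    seed = as.integer(seed), generator = generator, summary = summary,
    plate_time_h = plate_time_h, inoculum_basis = inoculum_basis,
    n_cycles = as.integer(n_cycles), mode = mode,
    transfer_fraction = transfer_fraction,
    n_worm_founders = n_worm_founders, n_runs = n_runs,
    n_species = n_species, planted = planted,
    quantile_type = quantile_type, binary_antibiotics = binary_antibiotics
  ), class = "run_config")
}

# Deterministic fan-out of the top-level seed into per-stage sub-seeds,
# kept inside the 32-bit integer range.
sub_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage * 9973) %% 2147483647)
}

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates generate -> estimate -> simulate -> classify -> test: a
#' synthetic co-culture CFU table and trait table are generated, the
#' life-cycle parameters are estimated from the CFU data, the deterministic
#' biphasic simulation is run from the estimates (plus an optional stochastic
#' ensemble), the community is classified into C-S-R strategies, the standard
#' species-abundance comparisons are tested, and a machine-readable summary
#' (milestone cycles, planted-versus-estimated recovery diagnostics, seeds)
#' is written.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed. Files written:
#'   `co.tsv`, `mono.tsv`, `traits.tsv`, `params.json`, `traj.tsv`,
#'   `csr.tsv`, `tests.tsv`, `summary.json`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`co`, `mono`, `traits`, `params`, `trajectory`, `csr`, `tests`,
#'   `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_cycles < 1) {
    rlang::abort("n_cycles must be >= 1", class = "biphasix_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "biphasix_pipeline_error", parent = e)
    })
  }

  gen <- config$generator
  gen$seed <- sub_seed(config$seed, 1L)
  co <- stage("generate", generate_co_culture_assays(gen))
  mono <- stage("generate", generate_mono_culture_assays(gen))
  traits <- stage("generate", generate_trait_table(
    config$n_species, planted = config$planted,
    seed = sub_seed(config$seed, 2L)))
  write_cfu_table(co, file.path(out_dir, "co.tsv"))
  write_cfu_table(mono, file.path(out_dir, "mono.tsv"))
  write_trait_table(traits, file.path(out_dir, "traits.tsv"))

  prop_a_initial <- if (config$inoculum_basis == "od") {
    inoculum_proportion(1, 1, basis = "od")
  } else {
    inoculum_proportion(1, 1, basis = "cfu",
                        species = c(gen$species_a, gen$species_b))
  }
  params <- stage("estimate", estimate_fitness_parameters(
    co, species_a = gen$species_a, summary = config$summary,
    plate_time_h = config$plate_time_h, prop_a_initial = prop_a_initial))
  jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)

  traj <- stage("simulate", simulate_lifecycle(params, config$n_cycles,
                                               mode = config$mode))
  readr::write_tsv(tibble::as_tibble(traj), file.path(out_dir, "traj.tsv"))
  ensemble <- NULL
  if (config$n_runs > 0) {
    ensemble <- stage("simulate", simulate_stochastic(
      params, config$n_cycles, transfer_fraction = config$transfer_fraction,
      n_worm_founders = config$n_worm_founders,
      seed = sub_seed(config$seed, 3L), n_runs = config$n_runs))
    readr::write_tsv(tibble::as_tibble(ensemble),
                     file.path(out_dir, "ensemble.tsv"))
  }

  csr <- stage("classify", csr_scores(traits, type = config$quantile_type,
                                      binary_antibiotics = config$binary_antibiotics))
  readr::write_tsv(tibble::as_tibble(csr), file.path(out_dir, "csr.tsv"))

  tests <- stage("test", compare_species_abundance(
    co,
    tibble::tibble(assay = c("growth", "early_colonization",
                             "established_colonization", "persistence",
                             "release"),
                   time_h = c(config$plate_time_h, NA, NA, NA, NA)),
    species_a = gen$species_a))
  readr::write_tsv(tests, file.path(out_dir, "tests.tsv"))

  summary <- list(
    seed = config$seed,
    sub_seeds = list(generator = gen$seed,
                     traits = sub_seed(config$seed, 2L),
                     stochastic = sub_seed(config$seed, 3L)),
    mode = config$mode,
    estimated = list(w_w_a = params$w_w_a, w_p_a = params$w_p_a,
                     k_w = params$k_w, k_p = params$k_p,
                     prop_a_initial = params$prop_a_initial),
    planted = list(w_w_a = gen$true_w_w_a, w_p_a = gen$true_w_p_a,
                   k_w = gen$k_w, k_p = gen$k_p),
    recovery = list(abs_error_w_w_a = abs(params$w_w_a - gen$true_w_w_a),
                    abs_error_w_p_a = abs(params$w_p_a - gen$true_w_p_a)),
    milestones = list(
      worm_dominance_cycle = milestone(traj, "worm", 0.5, "exceeds"),
      plate_near_fixation_cycle = milestone(traj, "plate", 0.99, "exceeds"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(list(co = co, mono = mono, traits = traits, params = params,
                 trajectory = traj, ensemble = ensemble, csr = csr,
                 tests = tests, summary = summary))
}

#' Long-format plotting table of a trajectory
#'
#' Reshapes a simulated trajectory to one row per (cycle, phase, species)
#' with the species proportion — the layout of the standard two-panel
#' composition-over-cycles figure. The pre-cycle plate state (cycle 0) is
#' dropped, so a 10-cycle trajectory yields 10 x 2 phases x 2 species = 40
#' rows.
#'
#' @param traj A `lifecycle_trajectory` from [simulate_lifecycle()].
#' @param species Length-2 character vector of species labels for roles A
#'   and B.
#' @return A tibble with columns `cycle`, `phase`, `species`, `proportion`.
#' @export
report_trajectory <- function(traj, species = c("A", "B")) {
  stopifnot(inherits(traj, "lifecycle_trajectory") || is.data.frame(traj))
  rows <- tibble::as_tibble(traj)[, c("cycle", "phase", "prop_a")]
  rows <- rows[rows$cycle >= 1, , drop = FALSE]
  if (nrow(rows) == 0) {
    rlang::abort("trajectory has no completed cycles",
                 class = "biphasix_validation_error")
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(rows, !!species[1] := .data$prop_a,
                  !!species[2] := 1 - .data$prop_a,
                  prop_a = NULL),
    cols = dplyr::all_of(species), names_to = "species",
    values_to = "proportion")
  dplyr::arrange(long, .data$cycle, .data$phase, .data$species)
}
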