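#' Configuration of the synthetic assay generator
#'
#' Describes the "planted world" the generator emulates: a two-species
#' community with known habitat-specific relative fitness, habitat carrying
#' capacities, multiplicative lognormal CFU noise, and the replicate/time
#' structure of the colonization and growth assays.
#'
#' @param true_w_w_a Planted within-host relative fitness of species A,
#'   in (0, 1). Default 0.3: the focal system's host phase favours species B
#'   (the Ochrobactrum-like host specialist persists better in worms).
#' @param true_w_p_a Planted plate relative fitness of species A, in (0, 1).
#'   Default 0.9: the Pseudomonas-like species dominates agar growth.
#' @param k_p Plate carrying capacity, CFU per plate (default 1e9).
#' @param k_w Worm carrying capacity, CFU per worm (default 1e4).
#' @param mono_means Optional named numeric vector overriding mono-culture
#'   mean CFU, with names among `plate_a`, `plate_b`, `worm_a`, `worm_b`.
#'   Defaults: each species alone reaches `k_p` on plate (stronger than its
#'   co-culture share, emulating plate competition) and exactly its
#'   co-culture share in the worm (emulating the absence of within-host
#'   competition).
#' @param noise_sigma_log Standard deviation of the natural-log CFU noise
#'   (multiplicative lognormal; default 0.3). Zero gives noiseless means.
#' @param n_replicates Replicates per assay/time point (default 6; the
#'   assays emulated use 4-6).
#' @param timepoints_h Plate growth sampling times in hours
#'   (default `c(0, 24, 72, 168)`).
#' @param mixing_weight Weight of within-host fitness (versus plate-derived
#'   uptake) in the expected early/established colonization proportions,
#'   in \[0, 1\] (default 0.5): worm composition reflects both what is taken
#'   up from the plate and what the host filters for.
#' @param species_a,species_b Species labels bound to roles A and B
#'   (defaults `"MYb11"`, `"MYb71"`).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(true_w_w_a = 0.3, true_w_p_a = 0.9,
                             k_p = 1e9, k_w = 1e4, mono_means = NULL,
                             noise_sigma_log = 0.3, n_replicates = 6,
                             timepoints_h = c(0, 24, 72, 168),
                             mixing_weight = 0.5,
                             species_a = "MYb11", species_b = "MYb71",
                             seed = 1L) {
  if (true_w_w_a <= 0 || true_w_w_a >= 1 || true_w_p_a <= 0 || true_w_p_a >= 1) {
    rlang::abort("planted fitness values must lie strictly inside (0, 1)",
                 class = "biphasix_config_error")
  }
  if (k_p <= 0 || k_w <= 0) {
    rlang::abort("carrying capacities must be positive",
                 class = "biphasix_config_error")
  }
  if (noise_sigma_log < 0) {
    rlang::abort("noise_sigma_log must be >= 0",
                 class = "biphasix_config_error")
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    rlang::abort("n_replicates must be a positive integer",
                 class = "biphasix_config_error")
  }
  if (mixing_weight < 0 || mixing_weight > 1) {
    rlang::abort("mixing_weight must lie in [0, 1]",
                 class = "biphasix_config_error")
  }
  if (!is.null(mono_means)) {
    bad <- setdiff(names(mono_means),
                   c("plate_a", "plate_b", "worm_a", "worm_b"))
    if (length(bad) > 0 || any(mono_means <= 0)) {
      rlang::abort("mono_means must be positive and named among plate_a, plate_b, worm_a, worm_b",
                   class = "biphasix_config_error")
    }
  }
  if (identical(species_a, species_b)) {
    rlang::abort("species_a and species_b must differ",
                 class = "biphasix_config_error")
  }
  structure(list(
    true_w_w_a = true_w_w_a, true_w_p_a = true_w_p_a,
    k_p = k_p, k_w = k_w, mono_means = mono_means,
    noise_sigma_log = noise_sigma_log,
    n_replicates = as.integer(n_replicates),
    timepoints_h = sort(unique(as.double(timepoints_h))),
    mixing_weight = mixing_weight,
    species_a = species_a, species_b = species_b,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Saturation profile of a plate lawn: inoculum-sized at 0 h, one order of
# magnitude below capacity at 24 h, at capacity from 72 h on.
plate_ramp <- function(time_h) {
  ifelse(time_h >= 72, 1, ifelse(time_h >= 24, 0.1, 1e-3))
}

# Expected per-assay (proportion of A, total CFU) pairs implied by a config.
co_culture_means <- function(config) {
  mix <- config$mixing_weight
  p_plate_final <- config$true_w_p_a
  p_host <- config$true_w_w_a
  p_colonization <- mix * p_host + (1 - mix) * p_plate_final
  plate <- tibble::tibble(
    assay = "growth", habitat = "plate",
    time_h = config$timepoints_h,
    prop_a = ifelse(config$timepoints_h == 0, 0.5,
             ifelse(config$timepoints_h < 72,
                    (0.5 + p_plate_final) / 2, p_plate_final)),
    total = plate_ramp(config$timepoints_h) * config$k_p
  )
  worm <- tibble::tibble(
    assay = c("early_colonization", "established_colonization",
              "persistence", "release"),
    habitat = "worm",
    time_h = c(1.5, 48, 49, 49),
    prop_a = c(p_colonization, p_colonization, p_host, p_host),
    total = c(0.01 * config$k_w, config$k_w, config$k_w, 0.1 * config$k_w)
  )
  dplyr::bind_rows(plate, worm)
}

expand_species_rows <- function(means, config, culture) {
  a <- dplyr::mutate(means, species_id = config$species_a,
                     cfu_mean = .data$prop_a * .data$total)
  b <- dplyr::mutate(means, species_id = config$species_b,
                     cfu_mean = (1 - .data$prop_a) * .data$total)
  out <- dplyr::bind_rows(a, b)
  out$culture <- culture
  out$unit <- ifelse(out$habitat == "plate", "per_plate", "per_worm")
  out
}

apply_lognormal_noise <- function(rows, config) {
  noisy <- rows[rep(seq_len(nrow(rows)), each = config$n_replicates), ,
                drop = FALSE]
  noisy$replicate <- rep(seq_len(config$n_replicates), times = nrow(rows))
  eps <- if (config$noise_sigma_log > 0) {
    stats::rnorm(nrow(noisy), mean = 0, sd = config$noise_sigma_log)
  } else {
    rep(0, nrow(noisy))
  }
  noisy$cfu <- noisy$cfu_mean * exp(eps)
  noisy[, cfu_columns]
}

#' Generate synthetic co-culture assay data
#'
#' Emits replicate-level co-culture CFU records with the structure of the
#' assays the package models: plate growth at the configured time points
#' (lawn saturating at the plate carrying capacity from 72 h, composition
#' moving from the 1:1 inoculum to the planted plate fitness), and the four
#' worm assays (early colonization, established colonization, short-term
#' persistence, release). Expected persistence and release proportions equal
#' the planted within-host fitness; expected colonization proportions mix
#' plate-derived uptake and host filtering via `mixing_weight`. Each count is
#' perturbed by multiplicative lognormal noise.
#'
#' @param config A [generator_config()].
#' @return A validated [cfu_table()].
#' @export
#' @examples
#' generate_co_culture_assays(generator_config(noise_sigma_log = 0))
generate_co_culture_assays <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  rows <- expand_species_rows(co_culture_means(config), config, "co")
  cfu_table(apply_lognormal_noise(rows, config),
            experiment_id = "synthetic-co-culture")
}

#' Generate synthetic mono-culture assay data
#'
#' Mono-culture counterparts of [generate_co_culture_assays()]: each species
#' measured alone, with plate means exceeding its co-culture share (release
#' from plate competition) and worm means equal to its co-culture share
#' (within-host competition is absent in the emulated system). Uses an
#' independent noise stream (`seed + 1`) so mono and co tables can be
#' combined.
#'
#' @param config A [generator_config()].
#' @return A validated [cfu_table()].
#' @export
generate_mono_culture_assays <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  co <- co_culture_means(config)
  defaults <- c(plate_a = config$k_p, plate_b = config$k_p,
                worm_a = NA_real_, worm_b = NA_real_)
  mm <- defaults
  if (!is.null(config$mono_means)) {
    mm[names(config$mono_means)] <- config$mono_means
  }
  build <- function(species, role) {
    plate_cap <- mm[[paste0("plate_", role)]]
    co_prop <- if (role == "a") co$prop_a else 1 - co$prop_a
    worm_cap <- mm[[paste0("worm_", role)]]
    rows <- co
    rows$species_id <- species
    rows$cfu_mean <- ifelse(
      rows$habitat == "plate",
      plate_ramp(rows$time_h) * plate_cap,
      if (is.na(worm_cap)) co_prop * rows$total
      else worm_cap * rows$total / config$k_w
    )
    rows
  }
  rows <- dplyr::bind_rows(build(config$species_a, "a"),
                           build(config$species_b, "b"))
  rows$culture <- "mono"
  rows$unit <- ifelse(rows$habitat == "plate", "per_plate", "per_worm")
  cfu_table(apply_lognormal_noise(rows, config),
            experiment_id = "synthetic-mono-culture")
}

csr_strategies <- c("competitor", "stress_tolerator", "ruderal")

# Community baseline and planted-extreme trait values. Baselines sit in the
# middle of realistic soil/host-associated bacterial ranges; extremes are
# chosen far outside so that, with at most ~25% of the community planted per
# strategy, each extreme clears the community 0.75/0.25 quantile strictly.
trait_baseline <- c(
  genome_size = 5, n_antibiotic_pathways = 3, n_siderophore_pathways = 2,
  n_catabolic_pathways = 50, max_growth_rate = 0.25, n_rrna_copies = 4,
  n_biofilm_genes = 20, n_auxotrophies = 3, codon_usage_bias = 0.6
)

strategy_extremes <- list(
  competitor = c(genome_size = 10, n_antibiotic_pathways = 8,
                 n_siderophore_pathways = 6, n_catabolic_pathways = 100),
  stress_tolerator = c(max_growth_rate = 0.08, n_rrna_copies = 1,
                       n_biofilm_genes = 45, n_auxotrophies = 9),
  ruderal = c(n_catabolic_pathways = 15, max_growth_rate = 0.6,
              n_rrna_copies = 9, codon_usage_bias = 0.95)
)

#' Generate a synthetic genome-trait table with planted strategies
#'
#' Builds a community trait table in which chosen species are planted as
#' competitor, stress-tolerator, or ruderal: their strategy-congruent traits
#' are set outside the community's 0.75/0.25 quantiles so that, at zero
#' noise, [csr_scores()] recovers the planted labels exactly. All other
#' species share the community baseline (hence score nothing and come out
#' `intermediate`).
#'
#' @param n_species Community size, at least 4 (the quantile thresholds need
#'   a distribution). Recovery is guaranteed when each strategy is planted in
#'   under a quarter of the community.
#' @param planted Named character vector, species label -> strategy
#'   (`"competitor"`, `"stress_tolerator"`, `"ruderal"`). May be empty.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Standard deviation of multiplicative lognormal jitter on
#'   all traits (default 0; counts are re-rounded, codon usage re-clamped).
#' @return A validated [trait_table()].
#' @export
#' @examples
#' generate_trait_table(6, c(MYb11 = "competitor", MYb71 = "stress_tolerator"))
generate_trait_table <- function(n_species, planted = character(),
                                 seed = 1L, noise_sd = 0) {
  if (n_species < 4) {
    rlang::abort("n_species must be at least 4 (quantile thresholds need a distribution)",
                 class = "biphasix_config_error")
  }
  planted <- unlist(planted)
  if (length(planted) > 0) {
    if (is.null(names(planted)) || any(names(planted) == "")) {
      rlang::abort("planted must be a named map species -> strategy",
                   class = "biphasix_config_error")
    }
    bad <- setdiff(planted, csr_strategies)
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown strategy: ", paste(bad, collapse = ", ")),
                   class = "biphasix_config_error")
    }
    if (length(planted) > n_species) {
      rlang::abort("more planted species than n_species",
                   class = "biphasix_config_error")
    }
  }
  n_filler <- n_species - length(planted)
  ids <- c(names(planted),
           sprintf("sp%02d", seq_len(n_filler)))
  traits <- matrix(rep(trait_baseline, each = n_species),
                   nrow = n_species,
                   dimnames = list(ids, names(trait_baseline)))
  for (i in seq_along(planted)) {
    extreme <- strategy_extremes[[planted[[i]]]]
    traits[i, names(extreme)] <- extreme
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    jitter <- exp(stats::rnorm(length(traits), 0, noise_sd))
    traits <- traits * matrix(jitter, nrow = n_species)
    count_cols <- grep("^n_", colnames(traits))
    traits[, count_cols] <- round(traits[, count_cols])
    traits[, "codon_usage_bias"] <- pmin(traits[, "codon_usage_bias"], 1)
  }
  out <- tibble::as_tibble(as.data.frame(traits))
  out$species_id <- ids
  trait_table(out)
}
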