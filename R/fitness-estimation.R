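#' Per-replicate species-A proportions from co-culture CFU records
#'
#' For each replicate at the requested assay (and optionally time point),
#' computes `proportion_a = cfu_a / (cfu_a + cfu_b)` from the co-culture
#' records of the two species. Replicates whose total is zero carry no
#' compositional information and are dropped with a warning.
#'
#' @param table A [cfu_table()].
#' @param assay Assay to select (e.g. `"persistence"`, `"growth"`).
#' @param time_h Optional sampling time in hours; `NULL` keeps all times for
#'   the assay (sensible for the single-time worm assays).
#' @param species_a Label of the species playing role A (the focal species;
#'   in the motivating system MYb11). Defaults to the alphabetically first
#'   species in the selection, with a message.
#' @return A tibble with columns `time_h`, `replicate`, `cfu_a`, `cfu_b`,
#'   `proportion_a`, ordered by time then replicate.
#' @export
cfu_to_proportions <- function(table, assay, time_h = NULL, species_a = NULL) {
  stopifnot(inherits(table, "cfu_table"))
  sel <- tibble::as_tibble(table)
  sel <- sel[sel$culture == "co" & sel$assay == assay, , drop = FALSE]
  if (!is.null(time_h)) {
    sel <- sel[sel$time_h %in% time_h, , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    rlang::abort(sprintf("no co-culture records for assay '%s'%s", assay,
                         if (is.null(time_h)) "" else
                           paste0(" at time ", paste(time_h, collapse = ", "),
                                  " h")),
                 class = "biphasix_empty_selection")
  }
  species <- sort(unique(sel$species_id))
  if (length(species) != 2) {
    rlang::abort("co-culture selection must contain exactly two species",
                 class = "biphasix_validation_error")
  }
  if (is.null(species_a)) {
    species_a <- species[1]
    rlang::inform(paste0("species_a not given; using '", species_a, "'"))
  }
  if (!species_a %in% species) {
    rlang::abort(paste0("species_a '", species_a, "' not present in selection"),
                 class = "biphasix_validation_error")
  }
  species_b <- setdiff(species, species_a)
  wide <- sel %>%
    dplyr::mutate(role = ifelse(.data$species_id == species_a, "cfu_a", "cfu_b")) %>%
    dplyr::select("time_h", "replicate", "role", "cfu") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "cfu") %>%
    dplyr::arrange(.data$time_h, .data$replicate)
  if (!all(c("cfu_a", "cfu_b") %in% names(wide))) {
    rlang::abort("selection lacks records for one species",
                 class = "biphasix_validation_error")
  }
  incomplete <- is.na(wide$cfu_a) | is.na(wide$cfu_b)
  if (any(incomplete)) {
    rlang::warn(sprintf("dropping %d replicate(s) missing one species",
                        sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  total <- wide$cfu_a + wide$cfu_b
  zero <- total == 0
  if (any(zero)) {
    rlang::warn(sprintf(
      "dropping %d replicate(s) with zero total CFU (no composition defined)",
      sum(zero)), class = "biphasix_zero_total")
    wide <- wide[!zero, , drop = FALSE]
    total <- total[!zero]
  }
  dplyr::mutate(wide, proportion_a = .data$cfu_a / (.data$cfu_a + .data$cfu_b))
}

#' Species proportion from a selective-plating count pair
#'
#' In the assays this package mirrors, co-cultured species are distinguished
#' by plating on both permissive and selective (kanamycin) media: only the
#' resistant species (role B, MYb71-like) grows on the selective plate, so
#' the focal species A is the difference. `proportion_a = (total - resistant)
#' / total`.
#'
#' @param total_cfu CFU count on the permissive plate (both species).
#' @param resistant_cfu CFU count on the selective plate (species B only).
#' @return Proportion of species A, vectorized.
#' @export
#' @examples
#' selective_plating_proportion(100, 30) # 0.7
selective_plating_proportion <- function(total_cfu, resistant_cfu) {
  if (any(total_cfu <= 0)) {
    rlang::abort("total_cfu must be positive",
                 class = "biphasix_validation_error")
  }
  if (any(resistant_cfu < 0 | resistant_cfu > total_cfu)) {
    rlang::abort("resistant_cfu must lie in [0, total_cfu]",
                 class = "biphasix_validation_error")
  }
  (total_cfu - resistant_cfu) / total_cfu
}

#' Relative fitness from replicate proportions
#'
#' Summarizes per-replicate species-A proportions into a single relative
#' fitness value. The default summary is the median: under multiplicative
#' (lognormal) CFU noise, per-replicate proportions follow a logit-symmetric
#' law whose median — not mean — is the underlying fitness.
#'
#' @param proportions Numeric vector of per-replicate proportions in \[0, 1\],
#'   or a data frame with a `proportion_a` column (as returned by
#'   [cfu_to_proportions()]).
#' @param summary `"median"` (default) or `"mean"`.
#' @return A single relative fitness value in \[0, 1\].
#' @export
estimate_relative_fitness <- function(proportions,
                                      summary = c("median", "mean")) {
  summary <- rlang::arg_match(summary)
  if (is.data.frame(proportions)) {
    proportions <- proportions$proportion_a
  }
  if (length(proportions) == 0 || all(is.na(proportions))) {
    rlang::abort("no proportions supplied", class = "biphasix_empty_selection")
  }
  if (any(proportions < 0 | proportions > 1, na.rm = TRUE)) {
    rlang::abort("proportions must lie in [0, 1]",
                 class = "biphasix_validation_error")
  }
  switch(summary,
         median = stats::median(proportions, na.rm = TRUE),
         mean = mean(proportions, na.rm = TRUE))
}

#' Carrying capacity from observed maximum population sizes
#'
#' The life-cycle model assumes populations always reach the experimentally
#' observed maximum size of their habitat. This estimator returns the maximum
#' over replicates of the species-summed total CFU: on plate, at the final
#' growth time point; in worms, over the established-colonization and
#' persistence assays.
#'
#' @param table A [cfu_table()].
#' @param habitat `"plate"` or `"worm"`.
#' @param co_only If `TRUE` (default) only co-culture records enter the
#'   totals, matching the community context the model describes.
#' @return The estimated carrying capacity (CFU per plate or per worm).
#' @export
estimate_carrying_capacity <- function(table, habitat = c("plate", "worm"),
                                       co_only = TRUE) {
  habitat <- rlang::arg_match(habitat)
  stopifnot(inherits(table, "cfu_table"))
  sel <- tibble::as_tibble(table)
  sel <- sel[sel$habitat == habitat, , drop = FALSE]
  if (co_only) sel <- sel[sel$culture == "co", , drop = FALSE]
  if (habitat == "plate") {
    sel <- sel[sel$assay == "growth", , drop = FALSE]
    if (nrow(sel) == 0) {
      rlang::abort("no plate growth records", class = "biphasix_empty_selection")
    }
    sel <- sel[sel$time_h == max(sel$time_h), , drop = FALSE]
  } else {
    sel <- sel[sel$assay %in% c("established_colonization", "persistence"), ,
               drop = FALSE]
    if (nrow(sel) == 0) {
      rlang::abort("no worm colonization/persistence records",
                   class = "biphasix_empty_selection")
    }
  }
  totals <- sel %>%
    dplyr::group_by(.data$culture, .data$assay, .data$time_h,
                    .data$replicate) %>%
    dplyr::summarise(total = sum(.data$cfu), .groups = "drop")
  max(totals$total)
}

#' Convert optical density to a CFU count
#'
#' Linear conversion through the per-species calibration constant
#' (CFU at OD 1).
#'
#' @param od Optical density at 600 nm, >= 0. Vectorized.
#' @param species_id Species label present in `calibration`.
#' @param calibration An [od_calibration()] object.
#' @return Estimated CFU count(s).
#' @export
#' @examples
#' od_to_cfu(1, "MYb11", od_calibration()) # 1.86e9
od_to_cfu <- function(od, species_id, calibration = od_calibration()) {
  stopifnot(inherits(calibration, "od_calibration"))
  if (any(od < 0)) {
    rlang::abort("od must be non-negative", class = "biphasix_validation_error")
  }
  if (!species_id %in% names(calibration)) {
    rlang::abort(paste0("no calibration constant for species '", species_id, "'"),
                 class = "biphasix_validation_error")
  }
  od * unname(calibration[[species_id]])
}

#' Proportion of species A in the inoculum
#'
#' Competition assays co-inoculate the two species at chosen optical
#' densities. The inoculum proportion of species A can be expressed on the
#' OD scale (`od_a / (od_a + od_b)`; 0.5 for the standard 1:1 protocol) or on
#' the CFU scale, converting each OD through its calibration constant first
#' (~0.699 for equal ODs with the default calibration, since the two species
#' differ in CFU per OD unit).
#'
#' @param od_a,od_b Optical densities of species A and B in the inoculum.
#' @param calibration An [od_calibration()]; needed for `basis = "cfu"`.
#' @param basis `"od"` (default) or `"cfu"`.
#' @param species Length-2 character vector naming the species playing roles
#'   A and B in `calibration` (defaults to its first two entries).
#' @return Proportion of species A in the inoculum.
#' @export
#' @examples
#' inoculum_proportion(1, 1)                 # 0.5
#' inoculum_proportion(1, 1, basis = "cfu")  # ~0.699
inoculum_proportion <- function(od_a, od_b, calibration = od_calibration(),
                                basis = c("od", "cfu"),
                                species = names(calibration)[1:2]) {
  basis <- rlang::arg_match(basis)
  if (od_a < 0 || od_b < 0) {
    rlang::abort("optical densities must be non-negative",
                 class = "biphasix_validation_error")
  }
  if (od_a + od_b <= 0) {
    rlang::abort("od_a + od_b must be positive",
                 class = "biphasix_validation_error")
  }
  if (basis == "od") {
    od_a / (od_a + od_b)
  } else {
    cfu_a <- od_to_cfu(od_a, species[1], calibration)
    cfu_b <- od_to_cfu(od_b, species[2], calibration)
    cfu_a / (cfu_a + cfu_b)
  }
}

#' Estimate the full life-cycle parameter set from a co-culture CFU table
#'
#' Wires the individual estimators together the way the model is
#' parameterized from assay data: within-host relative fitness from
#' short-term persistence proportions (bacteria retained in the worm are the
#' ones transferred in the passaging protocol), plate relative fitness from
#' agar proportions after 3 days of growth (the duration of the free-living
#' phase), and carrying capacities from the observed maximum population
#' sizes in each habitat.
#'
#' @param table A [cfu_table()] with co-culture records.
#' @param species_a Label of the focal species (role A).
#' @param summary Summary statistic for fitness, `"median"` (default) or
#'   `"mean"`.
#' @param plate_time_h Plate growth time point used for plate fitness
#'   (default 72 h).
#' @param prop_a_initial Inoculum proportion of A (default 0.5, the 1:1
#'   OD-basis protocol); compute a CFU-basis value with
#'   [inoculum_proportion()] if wanted.
#' @return A [fitness_parameters()] object.
#' @export
estimate_fitness_parameters <- function(table, species_a,
                                        summary = c("median", "mean"),
                                        plate_time_h = 72,
                                        prop_a_initial = 0.5) {
  summary <- rlang::arg_match(summary)
  w_w_a <- estimate_relative_fitness(
    cfu_to_proportions(table, "persistence", species_a = species_a),
    summary = summary)
  w_p_a <- estimate_relative_fitness(
    cfu_to_proportions(table, "growth", time_h = plate_time_h,
                       species_a = species_a),
    summary = summary)
  fitness_parameters(
    w_w_a = w_w_a,
    w_p_a = w_p_a,
    k_w = estimate_carrying_capacity(table, "worm"),
    k_p = estimate_carrying_capacity(table, "plate"),
    prop_a_initial = prop_a_initial
  )
}
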