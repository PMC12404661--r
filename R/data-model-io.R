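#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# Controlled vocabularies shared across the package.
cfu_habitats <- c("plate", "worm")
cfu_assays <- c("growth", "early_colonization", "established_colonization",
                "persistence", "release")
cfu_cultures <- c("mono", "co")
cfu_units <- c("per_plate", "per_worm")
worm_assays <- setdiff(cfu_assays, "growth")

cfu_columns <- c("species_id", "habitat", "assay", "culture",
                 "time_h", "replicate", "cfu", "unit")

trait_columns <- c("species_id", "genome_size", "n_antibiotic_pathways",
                   "n_siderophore_pathways", "n_catabolic_pathways",
                   "max_growth_rate", "n_rrna_copies", "n_biofilm_genes",
                   "n_auxotrophies", "codon_usage_bias")

#' Construct and validate a CFU assay table
#'
#' A CFU table is the universal assay record of the package: one row per
#' colony-count measurement, keyed by species, habitat, assay, culture mode,
#' sampling time, and replicate. Counts are stored as reals because plated
#' counts are back-multiplied by dilution factors.
#'
#' @param observations A data frame with columns `species_id`, `habitat`
#'   (`"plate"` or `"worm"`), `assay` (`"growth"`, `"early_colonization"`,
#'   `"established_colonization"`, `"persistence"`, `"release"`), `culture`
#'   (`"mono"` or `"co"`), `time_h` (hours, non-negative), `replicate`
#'   (positive integer), `cfu` (non-negative real), and `unit`
#'   (`"per_plate"` or `"per_worm"`).
#' @param experiment_id Optional label attached to the table.
#'
#' @details Validation enforces, per row: `cfu >= 0`, `time_h >= 0`,
#'   `replicate >= 1`; unit consistency (`plate` rows carry `per_plate`,
#'   `worm` rows carry `per_worm`); habitat consistency (the `growth` assay
#'   is plate-only, all colonization/persistence/release assays are
#'   worm-only); and uniqueness of the key
#'   (species, habitat, assay, culture, time, replicate). Co-culture records
#'   that do not come in species pairs per (assay, time, replicate) are
#'   flagged with a warning, not rejected.
#'
#' @return A tibble of class `cfu_table`, row order preserved.
#' @seealso [read_cfu_table()], [write_cfu_table()]
#' @export
#' @examples
#' cfu_table(data.frame(
#'   species_id = c("MYb11", "MYb71"), habitat = "plate", assay = "growth",
#'   culture = "co", time_h = 72, replicate = 1L, cfu = c(9e8, 1e8),
#'   unit = "per_plate"
#' ))
cfu_table <- function(observations, experiment_id = NULL) {
  obs <- tibble::as_tibble(observations)
  missing <- setdiff(cfu_columns, names(obs))
  if (length(missing) > 0) {
    abort(paste0("CFU table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "biphasix_schema_error")
  }
  obs <- obs[, cfu_columns]
  obs$species_id <- as.character(obs$species_id)
  obs$habitat <- as.character(obs$habitat)
  obs$assay <- as.character(obs$assay)
  obs$culture <- as.character(obs$culture)
  obs$unit <- as.character(obs$unit)
  obs$time_h <- as.double(obs$time_h)
  obs$replicate <- as.integer(obs$replicate)
  obs$cfu <- as.double(obs$cfu)
  validate_cfu_rows(obs)
  structure(obs,
            class = c("cfu_table", class(tibble::tibble())),
            experiment_id = experiment_id %||% "unnamed")
}

validate_cfu_rows <- function(obs) {
  fail_rows <- function(bad, what) {
    if (any(bad)) {
      abort(sprintf("invalid CFU record(s) at row(s) %s: %s",
                    paste(which(bad), collapse = ", "), what),
            class = "biphasix_validation_error")
    }
  }
  fail_rows(!obs$habitat %in% cfu_habitats, "unknown habitat")
  fail_rows(!obs$assay %in% cfu_assays, "unknown assay")
  fail_rows(!obs$culture %in% cfu_cultures, "unknown culture mode")
  fail_rows(!obs$unit %in% cfu_units, "unknown unit")
  fail_rows(is.na(obs$cfu) | obs$cfu < 0, "cfu must be a non-negative number")
  fail_rows(is.na(obs$time_h) | obs$time_h < 0, "time_h must be >= 0")
  fail_rows(is.na(obs$replicate) | obs$replicate < 1, "replicate must be >= 1")
  fail_rows(obs$habitat == "plate" & obs$unit != "per_plate",
            "plate records must use unit per_plate")
  fail_rows(obs$habitat == "worm" & obs$unit != "per_worm",
            "worm records must use unit per_worm")
  fail_rows(obs$assay == "growth" & obs$habitat != "plate",
            "growth assay records must be plate records")
  fail_rows(obs$assay %in% worm_assays & obs$habitat != "worm",
            "colonization/persistence/release records must be worm records")
  key <- paste(obs$species_id, obs$habitat, obs$assay, obs$culture,
               obs$time_h, obs$replicate, sep = "\r")
  dup <- duplicated(key)
  fail_rows(dup, "duplicate (species, habitat, assay, culture, time, replicate) key")
  check_co_pairs(obs)
  invisible(obs)
}

# Co-culture rows should carry both species per (assay, time, replicate);
# incomplete groups are reported, not fatal (single-species plating failures
# do occur in the assays this format mirrors).
check_co_pairs <- function(obs) {
  co <- obs[obs$culture == "co", , drop = FALSE]
  if (nrow(co) == 0) return(invisible(TRUE))
  grp <- paste(co$habitat, co$assay, co$time_h, co$replicate, sep = "\r")
  n_species <- tapply(co$species_id, grp, function(s) length(unique(s)))
  incomplete <- sum(n_species < 2)
  if (incomplete > 0) {
    warn(sprintf(
      "%d co-culture group(s) (assay, time, replicate) carry only one species",
      incomplete), class = "biphasix_incomplete_pair")
  }
  invisible(TRUE)
}

#' Read a CFU assay table from TSV
#'
#' Parses a UTF-8 tab-separated file with a mandatory header naming all
#' [cfu_table()] columns. Numbers may be plain or scientific notation.
#'
#' @param path Path to a TSV file.
#' @param experiment_id Optional label; defaults to the file name.
#' @return A validated [cfu_table()].
#' @export
read_cfu_table <- function(path, experiment_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "biphasix_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    habitat = readr::col_character(),
    assay = readr::col_character(),
    culture = readr::col_character(),
    time_h = readr::col_double(),
    replicate = readr::col_integer(),
    cfu = readr::col_double(),
    unit = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  cfu_table(raw, experiment_id = experiment_id %||% basename(path))
}

#' Write a CFU assay table to TSV
#'
#' The output is a plain UTF-8 TSV that [read_cfu_table()] parses back to an
#' identical table (full double precision is preserved).
#'
#' @param table A [cfu_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cfu_table <- function(table, path) {
  stopifnot(inherits(table, "cfu_table"))
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Construct and validate a genome-trait table
#'
#' One row per species, holding the genomic traits used by the C-S-R
#' life-history classifier: genome size (Mb), counts of antibiotic,
#' siderophore and catabolic pathways, maximal growth rate (per hour, e.g.
#' inferred from codon usage), rRNA operon copies, biofilm genes,
#' auxotrophies, and codon usage bias of highly expressed genes (in [0, 1]).
#'
#' @param traits Data frame with columns `species_id`, `genome_size`,
#'   `n_antibiotic_pathways`, `n_siderophore_pathways`, `n_catabolic_pathways`,
#'   `max_growth_rate`, `n_rrna_copies`, `n_biofilm_genes`, `n_auxotrophies`,
#'   `codon_usage_bias`, and optionally `doubling_time_h`.
#'
#' @details If `doubling_time_h` is absent it is filled as
#'   `log(2) / max_growth_rate`; if present it must agree with that value
#'   within 5% (rounding slack for hand-transcribed tables).
#' @return A tibble of class `trait_table`.
#' @export
trait_table <- function(traits) {
  tr <- tibble::as_tibble(traits)
  missing <- setdiff(trait_columns, names(tr))
  if (length(missing) > 0) {
    abort(paste0("trait table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "biphasix_schema_error")
  }
  tr$species_id <- as.character(tr$species_id)
  num_cols <- setdiff(union(trait_columns, "doubling_time_h"), "species_id")
  for (col in intersect(num_cols, names(tr))) {
    value <- suppressWarnings(as.double(tr[[col]]))
    if (anyNA(value) && !anyNA(tr[[col]])) {
      abort(paste0("non-numeric values in trait column ", col),
            class = "biphasix_validation_error")
    }
    tr[[col]] <- value
  }
  counts <- c("n_antibiotic_pathways", "n_siderophore_pathways",
              "n_catabolic_pathways", "n_rrna_copies", "n_biofilm_genes",
              "n_auxotrophies")
  for (col in counts) {
    if (any(is.na(tr[[col]]) | tr[[col]] < 0)) {
      abort(paste0("trait column ", col, " must be non-negative"),
            class = "biphasix_validation_error")
    }
  }
  if (any(is.na(tr$genome_size) | tr$genome_size <= 0)) {
    abort("genome_size must be positive", class = "biphasix_validation_error")
  }
  if (any(is.na(tr$max_growth_rate) | tr$max_growth_rate <= 0)) {
    abort("max_growth_rate must be positive",
          class = "biphasix_validation_error")
  }
  if (any(is.na(tr$codon_usage_bias) | tr$codon_usage_bias < 0 |
            tr$codon_usage_bias > 1)) {
    abort("codon_usage_bias must lie in [0, 1]",
          class = "biphasix_validation_error")
  }
  if (anyDuplicated(tr$species_id)) {
    abort("duplicate species_id in trait table",
          class = "biphasix_validation_error")
  }
  implied <- log(2) / tr$max_growth_rate
  if (!"doubling_time_h" %in% names(tr) || all(is.na(tr$doubling_time_h))) {
    tr$doubling_time_h <- implied
  } else {
    filled <- ifelse(is.na(tr$doubling_time_h), implied, tr$doubling_time_h)
    off <- abs(filled - implied) / implied > 0.05
    if (any(off)) {
      abort(sprintf(
        "doubling_time_h disagrees with log(2)/max_growth_rate by > 5%% for: %s",
        paste(tr$species_id[off], collapse = ", ")),
        class = "biphasix_validation_error")
    }
    tr$doubling_time_h <- filled
  }
  tr <- tr[, c(trait_columns, "doubling_time_h")]
  structure(tr, class = c("trait_table", class(tibble::tibble())))
}

#' Read a genome-trait table from TSV
#'
#' @param path Path to a TSV file with one row per species and the
#'   [trait_table()] columns (`doubling_time_h` optional).
#' @return A validated [trait_table()]; `doubling_time_h` is filled from
#'   `max_growth_rate` when absent.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "biphasix_io_error")
  }
  raw <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  trait_table(raw)
}

#' Write a genome-trait table to TSV
#'
#' @param table A [trait_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Optical-density to CFU calibration constants
#'
#' Holds, per species, the CFU count corresponding to an optical density
#' (600 nm) of 1 in the standard suspension. The defaults are the
#' experimentally determined constants for the two focal microbiota members:
#' at OD = 1 there are ~1.86e9 MYb11 (Pseudomonas lurida) CFUs and ~8.0e8
#' MYb71 (Ochrobactrum vermis) CFUs.
#'
#' @param cfu_per_od Named numeric vector, species label -> CFU at OD 1;
#'   all values must be positive.
#' @return A named numeric vector of class `od_calibration`.
#' @export
#' @examples
#' od_calibration()
#' od_calibration(c(sppA = 2e9, sppB = 5e8))
od_calibration <- function(cfu_per_od = c(MYb11 = 1.86e9, MYb71 = 8.0e8)) {
  if (is.null(names(cfu_per_od)) || any(names(cfu_per_od) == "")) {
    abort("cfu_per_od must be a fully named numeric vector",
          class = "biphasix_validation_error")
  }
  if (any(!is.finite(cfu_per_od) | cfu_per_od <= 0)) {
    abort("all calibration values must be positive and finite",
          class = "biphasix_validation_error")
  }
  structure(as.double(cfu_per_od), names = names(cfu_per_od),
            class = "od_calibration")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
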