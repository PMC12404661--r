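#' Convert a maximal growth rate to a doubling time
#'
#' `doubling_time = log(2) / r_max`. For the two focal microbiota members,
#' codon-usage-based inference gives r_max = 0.4/h (doubling in ~1.7 h, fast)
#' and r_max = 0.12/h (~5.8 h, slow).
#'
#' @param r_max Maximal growth rate per hour, > 0. Vectorized.
#' @return Doubling time in hours.
#' @export
#' @examples
#' growth_rate_to_doubling_time(0.4)  # 1.73 h
#' growth_rate_to_doubling_time(0.12) # 5.78 h
growth_rate_to_doubling_time <- function(r_max) {
  if (any(!is.finite(r_max) | r_max <= 0)) {
    rlang::abort("r_max must be positive", class = "biphasix_domain_error")
  }
  log(2) / r_max
}

#' Convert a doubling time to a maximal growth rate
#'
#' Inverse of [growth_rate_to_doubling_time()]: `r_max = log(2) / doubling`.
#'
#' @param doubling_time_h Doubling time in hours, > 0. Vectorized.
#' @return Maximal growth rate per hour.
#' @export
doubling_time_to_growth_rate <- function(doubling_time_h) {
  if (any(!is.finite(doubling_time_h) | doubling_time_h <= 0)) {
    rlang::abort("doubling_time_h must be positive",
                 class = "biphasix_domain_error")
  }
  log(2) / doubling_time_h
}

#' Classify growth as fast or slow
#'
#' Codon-usage surveys of growth across hundreds of thousands of organisms
#' show a bimodal distribution with a 5-hour doubling-time threshold
#' separating slow from fast growers (equivalently r_max of
#' log(2)/5 ~ 0.14/h). A species doubling in strictly less than the
#' threshold is `fast`; at exactly the threshold or above, `slow`.
#'
#' @param doubling_time_h Doubling time in hours, > 0. Vectorized.
#' @param threshold_h Threshold in hours (default 5).
#' @return Character vector, `"fast"` or `"slow"`.
#' @export
#' @examples
#' classify_growth(growth_rate_to_doubling_time(c(0.4, 0.12)))
classify_growth <- function(doubling_time_h, threshold_h = 5) {
  if (any(!is.finite(doubling_time_h) | doubling_time_h <= 0)) {
    rlang::abort("doubling_time_h must be positive",
                 class = "biphasix_domain_error")
  }
  ifelse(doubling_time_h < threshold_h, "fast", "slow")
}

csr_trait_rules <- list(
  competitor = list(high = c("genome_size", "n_antibiotic_pathways",
                             "n_siderophore_pathways", "n_catabolic_pathways"),
                    low = character()),
  stress_tolerator = list(high = c("n_biofilm_genes", "n_auxotrophies"),
                          low = c("max_growth_rate", "n_rrna_copies")),
  ruderal = list(high = c("max_growth_rate", "n_rrna_copies",
                          "codon_usage_bias"),
                 low = c("n_catabolic_pathways"))
)

#' Community quantile thresholds for trait scoring
#'
#' For every trait column, the 0.75 and 0.25 empirical quantiles of the
#' community distribution. A species' trait contributes to a strategy when it
#' falls strictly above the 0.75 quantile (high-quantity traits) or strictly
#' below the 0.25 quantile (low-quantity traits).
#'
#' @param table A [trait_table()] with at least 4 species.
#' @param type Quantile definition, passed to [stats::quantile()]
#'   (default 7, linear interpolation of order statistics — the default of
#'   the analysis ecosystem the scoring scheme comes from).
#' @return A tibble with columns `trait`, `q25`, `q75`.
#' @export
#' @examples
#' quantile_thresholds(generate_trait_table(6))
quantile_thresholds <- function(table, type = 7) {
  stopifnot(inherits(table, "trait_table"))
  if (nrow(table) < 4) {
    rlang::abort("quantile thresholds need at least 4 species",
                 class = "biphasix_validation_error")
  }
  traits <- setdiff(trait_columns, "species_id")
  tibble::tibble(
    trait = traits,
    q25 = purrr::map_dbl(traits, ~ unname(
      stats::quantile(table[[.x]], 0.25, type = type))),
    q75 = purrr::map_dbl(traits, ~ unname(
      stats::quantile(table[[.x]], 0.75, type = type)))
  )
}

#' Grime C-S-R scores from a genome-trait table
#'
#' Counts, per species, the strategy-congruent traits in the community's
#' extreme quartiles. Competitor traits: high genome size, antibiotic
#' pathways, siderophore pathways, catabolic pathways. Stress-tolerator
#' traits: slow growth (low maximal growth rate), few rRNA copies, many
#' biofilm genes, many auxotrophies. Ruderal traits: few catabolic pathways,
#' fast growth, many rRNA copies, strong codon usage bias. "High" means
#' strictly above the community 0.75 quantile and "low" strictly below the
#' 0.25 quantile, so a trait on which the community is flat contributes to
#' nobody. The strategy with the highest trait count is the species' life
#' history assignment; ties (including the all-zero case) are `intermediate`.
#'
#' @param table A [trait_table()] with at least 4 species.
#' @param type Quantile definition (see [quantile_thresholds()]).
#' @param binary_antibiotics If `TRUE`, antibiotic pathways score on presence
#'   (count > 0) instead of the quantile rule.
#' @return A tibble of class `csr_scores`, one row per species: `species_id`,
#'   `score_c`, `score_s`, `score_r`, ternary coordinates `ternary_c`,
#'   `ternary_s`, `ternary_r` (scores normalized to sum 1; the centroid
#'   (1/3, 1/3, 1/3) when all scores are zero), `assignment`, and
#'   `growth_class` from [classify_growth()].
#' @export
#' @examples
#' csr_scores(generate_trait_table(6, c(MYb11 = "competitor")))
csr_scores <- function(table, type = 7, binary_antibiotics = FALSE) {
  stopifnot(inherits(table, "trait_table"))
  thr <- quantile_thresholds(table, type = type)
  q25 <- stats::setNames(thr$q25, thr$trait)
  q75 <- stats::setNames(thr$q75, thr$trait)
  score_one <- function(rule) {
    hits <- rep(0L, nrow(table))
    for (tr in rule$high) {
      if (tr == "n_antibiotic_pathways" && binary_antibiotics) {
        hits <- hits + (table[[tr]] > 0)
      } else {
        hits <- hits + (table[[tr]] > q75[[tr]])
      }
    }
    for (tr in rule$low) {
      hits <- hits + (table[[tr]] < q25[[tr]])
    }
    as.integer(hits)
  }
  score_c <- score_one(csr_trait_rules$competitor)
  score_s <- score_one(csr_trait_rules$stress_tolerator)
  score_r <- score_one(csr_trait_rules$ruderal)
  scores <- cbind(score_c, score_s, score_r)
  total <- rowSums(scores)
  ternary <- scores / ifelse(total == 0, 1, total)
  ternary[total == 0, ] <- 1 / 3
  out <- tibble::tibble(
    species_id = table$species_id,
    score_c = score_c, score_s = score_s, score_r = score_r,
    ternary_c = ternary[, 1], ternary_s = ternary[, 2],
    ternary_r = ternary[, 3],
    assignment = apply(scores, 1, assign_strategy_from_counts),
    growth_class = classify_growth(table$doubling_time_h)
  )
  structure(out, class = c("csr_scores", class(tibble::tibble())))
}

assign_strategy_from_counts <- function(counts) {
  top <- max(counts)
  winners <- which(counts == top)
  if (top == 0 || length(winners) > 1) "intermediate"
  else csr_strategies[winners]
}

#' Final life-history strategy from a score row
#'
#' The strategy with the strictly highest trait count wins; a tie for the
#' maximum (including all-zero scores) is `intermediate`.
#'
#' @param score_c,score_s,score_r Non-negative trait counts for the
#'   competitor, stress-tolerator and ruderal strategies. Vectorized.
#' @return Character vector of assignments.
#' @export
#' @examples
#' assign_strategy(4, 1, 0) # competitor
#' assign_strategy(2, 2, 0) # intermediate
assign_strategy <- function(score_c, score_s, score_r) {
  if (any(c(score_c, score_s, score_r) < 0)) {
    rlang::abort("scores must be non-negative",
                 class = "biphasix_validation_error")
  }
  mapply(function(c_, s_, r_) assign_strategy_from_counts(c(c_, s_, r_)),
         score_c, score_s, score_r, USE.NAMES = FALSE)
}

#' Ternary (C, S, R) coordinates from strategy scores
#'
#' Normalizes the three trait counts to sum to one, giving the species'
#' position in the strategy triangle. All-zero scores map to the centroid
#' (1/3, 1/3, 1/3).
#'
#' @inheritParams assign_strategy
#' @return A tibble with columns `ternary_c`, `ternary_s`, `ternary_r`.
#' @export
#' @examples
#' ternary_coordinates(4, 1, 0) # (0.8, 0.2, 0)
ternary_coordinates <- function(score_c, score_s, score_r) {
  total <- score_c + score_s + score_r
  zero <- total == 0
  total[zero] <- 3
  out <- tibble::tibble(
    ternary_c = ifelse(zero, 1, score_c) / total,
    ternary_s = ifelse(zero, 1, score_s) / total,
    ternary_r = ifelse(zero, 1, score_r) / total
  )
  out
}

#' @exportS3Method generics::glance
glance.csr_scores <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    n_competitor = sum(x$assignment == "competitor"),
    n_stress_tolerator = sum(x$assignment == "stress_tolerator"),
    n_ruderal = sum(x$assignment == "ruderal"),
    n_intermediate = sum(x$assignment == "intermediate")
  )
}

#' Plot C-S-R scores in the strategy triangle
#'
#' Projects the ternary coordinates into the plane (C, S, R at the corners).
#' Points off the corners are intermediate strategies.
#'
#' @param object A `csr_scores` tibble from [csr_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.csr_scores <- function(object, ...) {
  # corners: C = (0, 0), S = (1, 0), R = (0.5, sqrt(3)/2)
  df <- tibble::as_tibble(object)
  df$x <- df$ternary_s + 0.5 * df$ternary_r
  df$y <- sqrt(3) / 2 * df$ternary_r
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  corners <- data.frame(x = c(-0.04, 1.04, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                        label = c("C", "S", "R"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$assignment), size = 2) +
    ggplot2::geom_text(data = corners, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}
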