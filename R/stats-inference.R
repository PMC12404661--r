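# Memo cache for permutation-null distributions: the Type-I-error style
# simulations below re-test thousands of same-shape samples, and the null
# distribution depends only on (n1, midrank multiset).
.biphasix_cache <- new.env(parent = emptyenv())

mw_null_min_u <- function(ranks, n1) {
  key <- paste0(n1, "|", paste(signif(sort(ranks), 12), collapse = ","))
  cached <- .biphasix_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- length(ranks)
  n2 <- n - n1
  subsets <- utils::combn(n, n1)
  u <- colSums(matrix(ranks[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  min_u <- pmin(u, n1 * n2 - u)
  .biphasix_cache[[key]] <- min_u
  min_u
}

#' Exact Mann-Whitney U test
#'
#' Two-sided rank-sum test for a location difference between two independent
#' samples, with the p-value computed by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings (conditional on the observed
#' mid-rank pattern, so ties are handled exactly). The reported statistic is
#' `U = min(U_x, U_y)`, the convention under which strong separations print
#' as small values (U = 0, 1, ...). The two-sided p-value is the null
#' probability of a `min(U_x, U_y)` at least as extreme (as small) as
#' observed.
#'
#' For combined sizes above `exact_max` a normal approximation with tie
#' correction and continuity correction is used instead, with a message.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param comparison_id Optional label carried into the result.
#' @param exact_max Largest combined sample size for exact enumeration
#'   (default 20).
#' @return A one-row tibble: `comparison_id`, `statistic_name` (`"U"`),
#'   `statistic`, `p_value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
mann_whitney_exact <- function(x, y, comparison_id = NA_character_,
                               exact_max = 20) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both samples must be nonempty",
                 class = "biphasix_validation_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y))
  u_x <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_min <- min(u_x, n1 * n2 - u_x)
  if (n1 + n2 <= exact_max) {
    null_min <- mw_null_min_u(ranks, n1)
    p <- mean(null_min <= u_min + 1e-9)
    method <- "exact enumeration"
  } else {
    rlang::inform(paste0("combined sample size ", n1 + n2, " > ", exact_max,
                         "; using normal approximation"))
    n <- n1 + n2
    tie_sizes <- table(ranks)
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(u_x - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  tibble::tibble(comparison_id = comparison_id, statistic_name = "U",
                 statistic = u_min, p_value = p,
                 n1 = n1, n2 = n2, method = method)
}

signed_rank_null_min_v <- function(abs_ranks) {
  key <- paste0("V|", paste(signif(sort(abs_ranks), 12), collapse = ","))
  cached <- .biphasix_cache[[key]]
  if (!is.null(cached)) return(cached)
  sums <- 0
  for (r in abs_ranks) sums <- c(sums, sums + r)
  total <- sum(abs_ranks)
  min_v <- pmin(sums, total - sums)
  .biphasix_cache[[key]] <- min_v
  min_v
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired rank test. Zero differences are discarded; the absolute
#' differences are mid-ranked; the statistic is `V`, the smaller of the
#' positive and negative signed-rank sums; and the two-sided p-value
#' enumerates all `2^m` sign assignments of the `m` nonzero differences
#' (again conditional on the observed tie pattern). With all differences of
#' one sign at m pairs, `V = 0` and `p = 2 / 2^m` (0.03125 at m = 6). All
#' differences zero gives `p = 1` (no evidence).
#'
#' @param x,y Paired numeric samples of equal length.
#' @param comparison_id Optional label carried into the result.
#' @param exact_max Largest number of nonzero differences for exact
#'   enumeration (default 20).
#' @return A one-row tibble: `comparison_id`, `statistic_name` (`"V"`),
#'   `statistic`, `p_value`, `n1`, `n2` (both the pair count), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
wilcoxon_signed_rank_exact <- function(x, y, comparison_id = NA_character_,
                                       exact_max = 20) {
  if (length(x) != length(y)) {
    rlang::abort("paired samples must have equal length",
                 class = "biphasix_validation_error")
  }
  if (length(x) == 0) {
    rlang::abort("samples must be nonempty",
                 class = "biphasix_validation_error")
  }
  d <- x - y
  nz <- d[d != 0]
  n_pairs <- length(x)
  if (length(nz) == 0) {
    return(tibble::tibble(comparison_id = comparison_id, statistic_name = "V",
                          statistic = 0, p_value = 1,
                          n1 = n_pairs, n2 = n_pairs,
                          method = "exact enumeration"))
  }
  abs_ranks <- rank(abs(nz))
  v_plus <- sum(abs_ranks[nz > 0])
  total <- sum(abs_ranks)
  v <- min(v_plus, total - v_plus)
  m <- length(nz)
  if (m <= exact_max) {
    null_min <- signed_rank_null_min_v(abs_ranks)
    p <- mean(null_min <= v + 1e-9)
    method <- "exact enumeration"
  } else {
    rlang::inform(paste0(m, " nonzero differences > ", exact_max,
                         "; using normal approximation"))
    tie_sizes <- table(abs_ranks)
    mu <- m * (m + 1) / 4
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (abs(v_plus - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  tibble::tibble(comparison_id = comparison_id, statistic_name = "V",
                 statistic = v, p_value = p,
                 n1 = n_pairs, n2 = n_pairs, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: sorted p-values are scaled by `m / rank`, a
#' running minimum from the largest down enforces monotonicity, values are
#' capped at 1, and results are returned in input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03)) # 0.03 0.04 0.04
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    rlang::abort("p-values must lie in (0, 1]",
                 class = "biphasix_validation_error")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Run a family of exact comparisons on a CFU table
#'
#' Convenience wrapper: for each requested assay (and optional time point),
#' compares log10 CFU of the two species across co-culture replicates with
#' the exact Mann-Whitney test (or the paired signed-rank test when
#' `paired = TRUE`, pairing by replicate), then adjusts the family of
#' p-values by Benjamini-Hochberg FDR.
#'
#' @param table A [cfu_table()].
#' @param comparisons A data frame with columns `assay` and optionally
#'   `time_h` (NA keeps all times for the assay).
#' @param species_a Focal species label (role A).
#' @param paired Use the paired signed-rank test (default `FALSE`).
#' @param log10_transform Compare log10(CFU + 1) rather than raw counts
#'   (default `TRUE`, matching how such assay data are usually analysed).
#' @return A tibble of [mann_whitney_exact()]-style rows plus `p_adjusted`.
#' @export
compare_species_abundance <- function(table, comparisons, species_a,
                                      paired = FALSE, log10_transform = TRUE) {
  stopifnot(inherits(table, "cfu_table"))
  comparisons <- tibble::as_tibble(comparisons)
  if (!"assay" %in% names(comparisons)) {
    rlang::abort("comparisons must have an 'assay' column",
                 class = "biphasix_validation_error")
  }
  if (!"time_h" %in% names(comparisons)) comparisons$time_h <- NA_real_
  results <- purrr::pmap(comparisons, function(assay, time_h, ...) {
    sel_time <- if (is.na(time_h)) NULL else time_h
    props <- cfu_to_proportions(table, assay, time_h = sel_time,
                                species_a = species_a)
    a <- props$cfu_a
    b <- props$cfu_b
    if (log10_transform) {
      a <- log10(a + 1)
      b <- log10(b + 1)
    }
    id <- if (is.na(time_h)) assay else paste0(assay, "@", time_h, "h")
    if (paired) wilcoxon_signed_rank_exact(a, b, comparison_id = id)
    else mann_whitney_exact(a, b, comparison_id = id)
  })
  out <- dplyr::bind_rows(results)
  out$p_adjusted <- bh_fdr(out$p_value)
  out
}
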