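#' Parameter set of the biphasic life-cycle model
#'
#' Bundles the five quantities the discrete two-species model needs: the
#' relative fitness of species A within the host (`w_w_a`; species B has
#' `1 - w_w_a`), the relative fitness of A in the free-living plate
#' environment (`w_p_a`), the two carrying capacities (`k_w` CFU per worm,
#' `k_p` CFU per plate), and the proportion of A in the initial inoculum
#' (`prop_a_initial`).
#'
#' Both habitats are assumed saturated every phase: populations always reach
#' their carrying capacity, so only composition carries between phases.
#'
#' @param w_w_a Within-host relative fitness of species A, in \[0, 1\].
#' @param w_p_a Plate (environmental) relative fitness of species A, in \[0, 1\].
#' @param k_w Carrying capacity of the host, CFU per worm (> 0).
#' @param k_p Carrying capacity of the plate, CFU per plate (> 0).
#' @param prop_a_initial Proportion of species A in the inoculum, in \[0, 1\].
#' @return An object of class `fitness_parameters`.
#' @export
#' @examples
#' fitness_parameters(w_w_a = 0.3, w_p_a = 0.9)
fitness_parameters <- function(w_w_a, w_p_a, k_w = 1e4, k_p = 1e9,
                               prop_a_initial = 0.5) {
  check_fraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      rlang::abort(paste0(name, " must be a single number in [0, 1]"),
                   class = "biphasix_validation_error")
    }
  }
  check_fraction(w_w_a, "w_w_a")
  check_fraction(w_p_a, "w_p_a")
  check_fraction(prop_a_initial, "prop_a_initial")
  if (!is.numeric(k_w) || k_w <= 0 || !is.numeric(k_p) || k_p <= 0) {
    rlang::abort("carrying capacities k_w and k_p must be positive",
                 class = "biphasix_validation_error")
  }
  structure(list(w_w_a = w_w_a, w_p_a = w_p_a, k_w = k_w, k_p = k_p,
                 prop_a_initial = prop_a_initial),
            class = "fitness_parameters")
}

#' @export
print.fitness_parameters <- function(x, ...) {
  cat("Biphasic life-cycle fitness parameters\n")
  cat(sprintf("  w_W_A (host)  : %.4f   w_W_B: %.4f\n", x$w_w_a, 1 - x$w_w_a))
  cat(sprintf("  w_P_A (plate) : %.4f   w_P_B: %.4f\n", x$w_p_a, 1 - x$w_p_a))
  cat(sprintf("  K_W: %.4g CFU/worm   K_P: %.4g CFU/plate\n", x$k_w, x$k_p))
  cat(sprintf("  Prop_A_initial: %.4f\n", x$prop_a_initial))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fitness_parameters <- function(x, ...) {
  tibble::tibble(
    term = c("w_w_a", "w_p_a", "k_w", "k_p", "prop_a_initial"),
    estimate = c(x$w_w_a, x$w_p_a, x$k_w, x$k_p, x$prop_a_initial)
  )
}

#' Initialize the plate phase of the life cycle
#'
#' Before the first cycle the lawn is actively inoculated and already at the
#' plate carrying capacity, so abundances at time zero are
#' `n_P_A(0) = prop_a_initial * k_p` and `n_P_B(0) = k_p - n_P_A(0)`.
#'
#' @param params A [fitness_parameters()] object.
#' @return Named numeric vector `c(n_a, n_b)` of plate abundances at t = 0.
#' @export
initialize_plate <- function(params) {
  stopifnot(inherits(params, "fitness_parameters"))
  n_a <- params$prop_a_initial * params$k_p
  c(n_a = n_a, n_b = params$k_p - n_a)
}

#' One round of relative-fitness selection between two types
#'
#' The replicator update `p * w / (p * w + (1 - p) * (1 - w))` gives the new
#' proportion of species A after one phase of selection in which A has
#' relative fitness `w` and B has `1 - w`. Boundaries are absorbing: for
#' `p` of 0 or 1 the update returns `p`; for `w` of 0 or 1 with interior `p`
#' it returns the corresponding fixation endpoint.
#'
#' @param p Current proportion(s) of species A, in \[0, 1\]. Vectorized.
#' @param w Relative fitness of species A, in \[0, 1\].
#' @return Updated proportion(s), clamped to \[0, 1\].
#' @export
#' @examples
#' replicator_update(0.3, 0.7) # 0.5
#' replicator_update(0.5, 0.9) # 0.9
replicator_update <- function(p, w) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(w < 0 | w > 1, na.rm = TRUE)) {
    rlang::abort("p and w must lie in [0, 1]",
                 class = "biphasix_validation_error")
  }
  num <- p * w
  den <- num + (1 - p) * (1 - w)
  out <- ifelse(den == 0, p, num / den)
  pmin(pmax(out, 0), 1)
}

#' Advance the community through one full life cycle
#'
#' A cycle is worm phase then plate phase. In the default `replicator` mode
#' plate bacteria colonize worms according to their within-host relative
#' fitness (`prop_W(t+1) = replicator_update(prop_P(t), w_w_a)`, abundances
#' rescaled to `k_w` since worms are maximally colonized every iteration),
#' then the worm community seeds the plate and grows according to plate
#' fitness (`prop_P(t+1) = replicator_update(prop_W(t+1), w_p_a)`, rescaled
#' to `k_p`).
#'
#' `literal` mode instead applies the unnormalized proportional weighting
#' `prop_W(t+1) = prop_P(t) * w_w_a` (and analogously on plate). Because both
#' factors are below 1 for interior fitness values, proportions shrink every
#' cycle under this reading; it is retained for transparency only (see the
#' package vignette).
#'
#' @param prop_p Plate-phase proportion of species A entering the cycle.
#' @param params A [fitness_parameters()] object.
#' @param mode `"replicator"` (default) or `"literal"`.
#' @return List with elements `prop_w` and `prop_p`: the worm- and
#'   plate-phase proportions of species A after the cycle.
#' @export
step_cycle <- function(prop_p, params, mode = c("replicator", "literal")) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(params, "fitness_parameters"))
  if (any(prop_p < 0 | prop_p > 1)) {
    rlang::abort("prop_p must lie in [0, 1]",
                 class = "biphasix_validation_error")
  }
  if (mode == "replicator") {
    prop_w <- replicator_update(prop_p, params$w_w_a)
    prop_p_next <- replicator_update(prop_w, params$w_p_a)
  } else {
    prop_w <- pmin(pmax(prop_p * params$w_w_a, 0), 1)
    prop_p_next <- pmin(pmax(prop_w * params$w_p_a, 0), 1)
  }
  list(prop_w = prop_w, prop_p = prop_p_next)
}

#' Simulate the deterministic biphasic life cycle
#'
#' Iterates [step_cycle()] for `n_cycles` cycles from the inoculated plate
#' state of [initialize_plate()]. Cycle indexing is 1-based: cycle 0 is the
#' pre-cycle plate state, and "dominant after four cycles" means the worm
#' phase of cycle 4.
#'
#' @param params A [fitness_parameters()] object.
#' @param n_cycles Number of life cycles to simulate (default 10, matching
#'   the serial-passage design the model mirrors).
#' @param mode `"replicator"` (default) or `"literal"`; see [step_cycle()].
#' @return A tibble of class `lifecycle_trajectory` with columns `cycle`,
#'   `phase` (`"plate"` or `"worm"`), `n_a`, `n_b` (CFU abundances), and
#'   `prop_a`. Cycle 0 has a plate row only; cycles 1..`n_cycles` have a worm
#'   row then a plate row.
#' @export
#' @examples
#' simulate_lifecycle(fitness_parameters(w_w_a = 0.3, w_p_a = 0.9), 3)
simulate_lifecycle <- function(params, n_cycles = 10,
                               mode = c("replicator", "literal")) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(params, "fitness_parameters"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
        n_cycles != round(n_cycles)) {
    rlang::abort("n_cycles must be a positive integer",
                 class = "biphasix_validation_error")
  }
  n_cycles <- as.integer(n_cycles)
  prop_p <- params$prop_a_initial
  cycle <- integer(2 * n_cycles + 1)
  phase <- character(2 * n_cycles + 1)
  prop <- double(2 * n_cycles + 1)
  cycle[1] <- 0L; phase[1] <- "plate"; prop[1] <- prop_p
  row <- 1L
  for (t in seq_len(n_cycles)) {
    st <- step_cycle(prop_p, params, mode = mode)
    cycle[row + 1L] <- t; phase[row + 1L] <- "worm"; prop[row + 1L] <- st$prop_w
    cycle[row + 2L] <- t; phase[row + 2L] <- "plate"; prop[row + 2L] <- st$prop_p
    prop_p <- st$prop_p
    row <- row + 2L
  }
  k <- ifelse(phase == "worm", params$k_w, params$k_p)
  traj <- tibble::tibble(
    cycle = cycle, phase = phase,
    n_a = prop * k, n_b = (1 - prop) * k, prop_a = prop
  )
  new_trajectory(traj, mode = mode, params = params)
}

new_trajectory <- function(traj, mode, params) {
  structure(traj,
            class = c("lifecycle_trajectory", class(tibble::tibble())),
            mode = mode, params = params)
}

#' Stochastic serial-transfer simulation of the life cycle
#'
#' Emulates the experimental-evolution transfer regime: each cycle, a finite
#' number of founder cells colonizes the worms (a binomial draw around the
#' fitness-weighted plate proportion), and a fixed fraction of the
#' worm-associated community (the 10% bottleneck of the passaging protocol)
#' is sampled binomially to seed the next plate, where growth again follows
#' plate relative fitness. Extinction is absorbing.
#'
#' @param params A [fitness_parameters()] object.
#' @param n_cycles Number of cycles per run.
#' @param transfer_fraction Fraction of the worm community transferred to the
#'   next plate (default 0.1).
#' @param n_worm_founders Number of founder cells colonizing the worm
#'   population each cycle (default 1e3).
#' @param seed Integer seed; the ensemble is fully reproducible from it.
#' @param n_runs Number of independent runs (default 100).
#' @return A tibble of class `lifecycle_ensemble`: columns `run`, `cycle`,
#'   `phase`, `prop_a`. Cycle 0 is the shared initial plate state.
#' @export
simulate_stochastic <- function(params, n_cycles = 10, transfer_fraction = 0.1,
                                n_worm_founders = 1e3, seed = 1L,
                                n_runs = 100) {
  stopifnot(inherits(params, "fitness_parameters"))
  if (transfer_fraction <= 0 || transfer_fraction > 1) {
    rlang::abort("transfer_fraction must lie in (0, 1]",
                 class = "biphasix_validation_error")
  }
  if (n_worm_founders < 1) {
    rlang::abort("n_worm_founders must be a positive count",
                 class = "biphasix_validation_error")
  }
  if (n_runs < 1) {
    rlang::abort("n_runs must be >= 1", class = "biphasix_validation_error")
  }
  set.seed(as.integer(seed))
  n_founders <- round(n_worm_founders)
  n_transfer <- max(1, round(transfer_fraction * n_founders))
  n_cycles <- as.integer(n_cycles)

  # All runs advance in lock-step so the whole ensemble is vectorized over
  # runs; rbinom() handles size up to ~2^31 so founder counts of 1e7+ are fine.
  prop_p <- rep(params$prop_a_initial, n_runs)
  rows <- vector("list", n_cycles + 1L)
  rows[[1]] <- tibble::tibble(run = seq_len(n_runs), cycle = 0L,
                              phase = "plate", prop_a = prop_p)
  for (t in seq_len(n_cycles)) {
    p_col <- replicator_update(prop_p, params$w_w_a)
    founders_a <- stats::rbinom(n_runs, n_founders, p_col)
    prop_w <- founders_a / n_founders
    sampled_a <- stats::rbinom(n_runs, n_transfer, prop_w)
    prop_seed <- sampled_a / n_transfer
    prop_p <- replicator_update(prop_seed, params$w_p_a)
    rows[[t + 1L]] <- tibble::tibble(
      run = rep(seq_len(n_runs), 2L),
      cycle = t,
      phase = rep(c("worm", "plate"), each = n_runs),
      prop_a = c(prop_w, prop_p)
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$run, .data$cycle,
                        dplyr::desc(.data$phase))
  structure(out, class = c("lifecycle_ensemble", class(tibble::tibble())),
            params = params, transfer_fraction = transfer_fraction,
            n_worm_founders = n_founders, seed = as.integer(seed))
}

#' First cycle at which a trajectory crosses a proportion threshold
#'
#' @param traj A `lifecycle_trajectory` from [simulate_lifecycle()].
#' @param phase `"worm"` or `"plate"`.
#' @param threshold Proportion threshold in (0, 1).
#' @param direction `"exceeds"` (strictly above) or `"falls_below"`
#'   (strictly below).
#' @return The smallest 1-based cycle index at which the proportion of
#'   species A in the requested phase crosses the threshold, or `NA_integer_`
#'   if it never does. Cycle 0 (the pre-cycle plate state) is not considered.
#' @export
#' @examples
#' traj <- simulate_lifecycle(fitness_parameters(0.3, 0.9), 10)
#' milestone(traj, "worm", 0.5, "exceeds")
milestone <- function(traj, phase = c("worm", "plate"), threshold,
                      direction = c("exceeds", "falls_below")) {
  phase <- rlang::arg_match(phase)
  direction <- rlang::arg_match(direction)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must lie strictly inside (0, 1)",
                 class = "biphasix_validation_error")
  }
  rows <- traj[traj$phase == phase & traj$cycle >= 1, , drop = FALSE]
  if (nrow(rows) == 0) return(NA_integer_)
  hit <- if (direction == "exceeds") rows$prop_a > threshold
         else rows$prop_a < threshold
  if (!any(hit)) return(NA_integer_)
  as.integer(min(rows$cycle[hit]))
}

#' @exportS3Method generics::glance
glance.lifecycle_trajectory <- function(x, ...) {
  params <- attr(x, "params")
  tibble::tibble(
    mode = attr(x, "mode"),
    n_cycles = max(x$cycle),
    w_w_a = params$w_w_a,
    w_p_a = params$w_p_a,
    final_prop_worm = utils::tail(x$prop_a[x$phase == "worm"], 1),
    final_prop_plate = utils::tail(x$prop_a[x$phase == "plate"], 1),
    worm_dominance_cycle = milestone(x, "worm", 0.5, "exceeds"),
    plate_near_fixation_cycle = milestone(x, "plate", 0.99, "exceeds")
  )
}

#' @exportS3Method generics::tidy
tidy.lifecycle_trajectory <- function(x, ...) {
  report_trajectory(x)
}

#' Plot a simulated life-cycle trajectory
#'
#' Two panels (plate and worm phase), proportion of each species against
#' cycle number — the standard presentation of serial-passage composition
#' dynamics.
#'
#' @param object A `lifecycle_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lifecycle_trajectory <- function(object, ...) {
  long <- report_trajectory(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$proportion,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "life cycle", y = "proportion of community",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
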