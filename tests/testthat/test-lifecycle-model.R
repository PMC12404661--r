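test_that("plate initialization splits the carrying capacity by inoculum share", {
  expect_equal(initialize_plate(fitness_parameters(0.3, 0.9, k_p = 1e9,
                                                   prop_a_initial = 0.5)),
               c(n_a = 5e8, n_b = 5e8))
  expect_equal(initialize_plate(fitness_parameters(0.3, 0.9, k_p = 1e9,
                                                   prop_a_initial = 1)),
               c(n_a = 1e9, n_b = 0))
  expect_equal(initialize_plate(fitness_parameters(0.3, 0.9, k_p = 1e9,
                                                   prop_a_initial = 0.699)),
               c(n_a = 6.99e8, n_b = 3.01e8))
})

test_that("replicator update matches its closed form and absorbs boundaries", {
  expect_equal(replicator_update(0.5, 0.5), 0.5)
  expect_equal(replicator_update(0.3, 0.7), 0.5)
  expect_equal(replicator_update(0.5, 0.9), 0.9)
  expect_equal(replicator_update(0, 0.9), 0)
  expect_equal(replicator_update(1, 0.1), 1)
  expect_equal(replicator_update(0.5, 0), 0)
  expect_equal(replicator_update(0.5, 1), 1)
  expect_equal(replicator_update(0, 1), 0)   # degenerate 0/0 guard
  expect_equal(replicator_update(1, 0), 1)
  expect_error(replicator_update(1.1, 0.5), class = "biphasix_validation_error")
})

test_that("replicator update is strictly increasing in p and w with fixed points {0,1}", {
  grid <- seq(0.05, 0.95, by = 0.05)
  for (w in grid) {
    out <- replicator_update(grid, w)
    expect_true(all(diff(out) > 0))
  }
  for (p in grid) {
    out <- vapply(grid, function(w) replicator_update(p, w), numeric(1))
    expect_true(all(diff(out) > 0))
    # interior fixed points exist only at neutrality
    expect_true(all(abs(replicator_update(p, grid[grid != 0.5]) - p) > 0))
    expect_equal(replicator_update(p, 0.5), p)
  }
})

test_that("one cycle applies worm then plate selection", {
  params <- fitness_parameters(w_w_a = 0.3, w_p_a = 0.9)
  st <- step_cycle(0.5, params)
  expect_equal(st$prop_w, 0.3)
  expect_equal(st$prop_p, 27 / 34)
  neutral <- fitness_parameters(0.5, 0.5)
  st0 <- step_cycle(0.42, neutral)
  expect_equal(st0$prop_w, 0.42)
  expect_equal(st0$prop_p, 0.42)
  lit <- step_cycle(0.5, params, mode = "literal")
  expect_equal(lit$prop_w, 0.15)
  expect_equal(lit$prop_p, 0.135)
  expect_error(step_cycle(0.5, params, mode = "magic"))
})

test_that("the deterministic trajectory matches hand-iterated values and conserves capacity", {
  params <- fitness_parameters(0.3, 0.9, k_w = 1e4, k_p = 1e9,
                               prop_a_initial = 0.5)
  traj <- simulate_lifecycle(params, 3)
  worm <- traj$prop_a[traj$phase == "worm"]
  plate <- traj$prop_a[traj$phase == "plate" & traj$cycle >= 1]
  expect_equal(round(worm, 3), c(0.3, 0.623, 0.864))
  expect_equal(round(plate, 3), c(0.794, 0.937, 0.983))
  k <- ifelse(traj$phase == "worm", 1e4, 1e9)
  expect_equal(traj$n_a + traj$n_b, k)
  expect_identical(tibble::as_tibble(simulate_lifecycle(params, 3)),
                   tibble::as_tibble(traj))
})

test_that("plate proportion increases monotonically toward fixation when favoured", {
  for (w_p in c(0.6, 0.75, 0.9)) {
    for (w_w in c(0.5, 0.65, 0.8)) {
      traj <- simulate_lifecycle(fitness_parameters(w_w, w_p), 60)
      plate <- traj$prop_a[traj$phase == "plate"]
      rising <- plate < 1 - 1e-12
      expect_true(all(diff(plate[rising]) > 0))
      expect_lt(abs(plate[length(plate)] - 1), 1e-6)
    }
  }
})

test_that("literal mode proportions shrink every cycle for interior fitness", {
  traj <- simulate_lifecycle(fitness_parameters(0.3, 0.9), 5, mode = "literal")
  plate <- traj$prop_a[traj$phase == "plate"]
  expect_true(all(diff(plate) < 0))
})

test_that("B-perspective trajectory mirrors the A-perspective one", {
  a <- simulate_lifecycle(fitness_parameters(0.3, 0.9, prop_a_initial = 0.42), 8)
  b <- simulate_lifecycle(fitness_parameters(0.7, 0.1, prop_a_initial = 0.58), 8)
  expect_equal(b$prop_a, 1 - a$prop_a, tolerance = 1e-14)
})

test_that("the replicator trajectory equals the odds-product oracle", {
  for (case in list(c(0.3, 0.9, 0.5), c(0.7, 0.2, 0.35), c(0.45, 0.55, 0.9))) {
    traj <- simulate_lifecycle(fitness_parameters(case[1], case[2],
                                                  prop_a_initial = case[3]), 10)
    oracle <- oracle_odds_trajectory(case[3], case[1], case[2], 10)
    expect_equal(traj$prop_a[traj$phase == "worm"], oracle$prop_w,
                 tolerance = 1e-12)
    expect_equal(traj$prop_a[traj$phase == "plate" & traj$cycle >= 1],
                 oracle$prop_p, tolerance = 1e-12)
  }
})

test_that("milestones report the first strict threshold crossing", {
  traj <- simulate_lifecycle(fitness_parameters(0.3, 0.9), 3)
  expect_identical(milestone(traj, "worm", 0.5, "exceeds"), 2L)
  expect_identical(milestone(traj, "plate", 0.99, "exceeds"), NA_integer_)
  flat <- simulate_lifecycle(fitness_parameters(0.5, 0.5), 5)
  expect_identical(milestone(flat, "worm", 0.5, "exceeds"), NA_integer_)
  expect_identical(milestone(traj, "worm", 0.5, "falls_below"), 1L)
  expect_error(milestone(traj, "worm", 1, "exceeds"),
               class = "biphasix_validation_error")
})

test_that("glance summarizes a trajectory", {
  g <- glance(simulate_lifecycle(fitness_parameters(0.3, 0.9), 10))
  expect_equal(g$n_cycles, 10)
  expect_identical(g$worm_dominance_cycle, 2L)
  expect_gt(g$final_prop_plate, 0.99)
})

test_that("stochastic mode is reproducible, absorbing, and validated", {
  params <- fitness_parameters(0.3, 0.9)
  e1 <- simulate_stochastic(params, 5, seed = 11, n_runs = 20)
  e2 <- simulate_stochastic(params, 5, seed = 11, n_runs = 20)
  expect_identical(tibble::as_tibble(e1), tibble::as_tibble(e2))
  gone <- simulate_stochastic(fitness_parameters(0.3, 0.9,
                                                 prop_a_initial = 0),
                              5, seed = 1, n_runs = 10)
  expect_true(all(gone$prop_a == 0))
  expect_error(simulate_stochastic(params, 5, transfer_fraction = 0),
               class = "biphasix_validation_error")
  expect_error(simulate_stochastic(params, 5, n_worm_founders = 0),
               class = "biphasix_validation_error")
})

test_that("autoplot renders a two-panel proportion figure", {
  plt <- autoplot(simulate_lifecycle(fitness_parameters(0.3, 0.9), 5))
  expect_s3_class(plt, "ggplot")
  built <- ggplot2::ggplot_build(plt)
  expect_gt(length(built$data), 0)
})
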