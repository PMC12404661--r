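test_that("growth rate / doubling time conversions reproduce the published values", {
  expect_equal(round(growth_rate_to_doubling_time(0.4), 1), 1.7)
  expect_equal(round(growth_rate_to_doubling_time(0.12), 1), 5.8)
  expect_equal(round(doubling_time_to_growth_rate(5), 2), 0.14)
  r <- c(0.05, 0.14, 0.4, 2)
  expect_equal(doubling_time_to_growth_rate(growth_rate_to_doubling_time(r)),
               r, tolerance = 1e-12)
  expect_error(growth_rate_to_doubling_time(0), class = "biphasix_domain_error")
  expect_error(doubling_time_to_growth_rate(-2),
               class = "biphasix_domain_error")
})

test_that("growth is classified fast/slow at the 5 h doubling threshold", {
  expect_identical(classify_growth(growth_rate_to_doubling_time(0.4)), "fast")
  expect_identical(classify_growth(growth_rate_to_doubling_time(0.12)), "slow")
  expect_identical(classify_growth(5), "slow")  # boundary convention
  expect_identical(classify_growth(4.999), "fast")
})

trait_fixture <- function(values, trait = "genome_size") {
  n <- length(values)
  base <- tibble::tibble(
    species_id = sprintf("s%d", seq_len(n)), genome_size = 5,
    n_antibiotic_pathways = 3, n_siderophore_pathways = 2,
    n_catabolic_pathways = 50, max_growth_rate = 0.25, n_rrna_copies = 4,
    n_biofilm_genes = 20, n_auxotrophies = 3, codon_usage_bias = 0.6
  )
  base[[trait]] <- values
  trait_table(base)
}

test_that("quantile thresholds use linear interpolation of order statistics", {
  thr <- quantile_thresholds(trait_fixture(c(3, 4, 5, 6, 7)))
  expect_equal(thr$q75[thr$trait == "genome_size"], 6)
  expect_equal(thr$q25[thr$trait == "genome_size"], 4)
  thr4 <- quantile_thresholds(trait_fixture(c(1, 2, 3, 4)))
  expect_equal(thr4$q75[thr4$trait == "genome_size"], 3.25)
  expect_equal(thr4$q25[thr4$trait == "genome_size"], 1.75)
  # degenerate trait: Q75 = Q25 = the value, so nobody scores on it
  thr_flat <- quantile_thresholds(trait_fixture(rep(4, 5)))
  expect_equal(thr_flat$q75[thr_flat$trait == "genome_size"], 4)
  expect_equal(thr_flat$q25[thr_flat$trait == "genome_size"], 4)
  expect_error(quantile_thresholds(trait_fixture(c(1, 2, 3))),
               class = "biphasix_validation_error")
})

test_that("csr scores count extreme-quartile strategy-congruent traits", {
  tt <- generate_trait_table(6, c(MYb11 = "competitor"))
  sc <- csr_scores(tt)
  row <- sc[sc$species_id == "MYb11", ]
  expect_equal(row$score_c, 4L)
  expect_identical(row$assignment, "competitor")
  expect_true(all(sc$score_c[sc$species_id != "MYb11"] == 0))

  flat <- csr_scores(trait_fixture(rep(5, 6)))
  expect_true(all(flat$assignment == "intermediate"))
  expect_true(all(abs(flat$ternary_c - 1 / 3) < 1e-12))

  shuffled <- tt[c(4, 2, 6, 1, 3, 5), ]
  sc2 <- csr_scores(trait_table(shuffled))
  merged <- merge(sc, sc2, by = "species_id")
  expect_equal(merged$score_c.x, merged$score_c.y)
  expect_equal(merged$score_s.x, merged$score_s.y)
  expect_equal(merged$score_r.x, merged$score_r.y)
})

test_that("binary antibiotic mode scores on presence instead of quantile", {
  tt <- generate_trait_table(6, c(MYb11 = "competitor"))
  sc <- csr_scores(tt, binary_antibiotics = TRUE)
  # every species carries at least one antibiotic pathway, so all score it
  expect_true(all(sc$score_c >= 1))
})

test_that("scores are invariant under strictly monotone trait rescaling", {
  tt <- generate_trait_table(8, c(a = "competitor", b = "stress_tolerator",
                                  c = "ruderal"), seed = 3, noise_sd = 0.15)
  ref <- csr_scores(tt)[, c("score_c", "score_s", "score_r")]
  maps <- list(function(x) 3 * x + 1, sqrt, function(x) log(x + 1),
               function(x) x^3)
  set.seed(42)
  traits <- setdiff(names(tt), c("species_id", "doubling_time_h"))
  for (i in 1:10) {
    warped <- tibble::as_tibble(tt)
    col <- sample(traits, 1)
    warped[[col]] <- maps[[sample(length(maps), 1)]](warped[[col]])
    # bypass range validation: compare the scoring path on raw columns
    warped <- structure(warped, class = class(tt))
    warped$doubling_time_h <- log(2) / warped$max_growth_rate
    got <- csr_scores(warped)[, c("score_c", "score_s", "score_r")]
    expect_equal(tibble::as_tibble(got), tibble::as_tibble(ref))
  }
})

test_that("ternary coordinates normalize scores and handle the all-zero case", {
  tc <- ternary_coordinates(4, 1, 0)
  expect_equal(unlist(tc), c(ternary_c = 0.8, ternary_s = 0.2, ternary_r = 0))
  expect_equal(unlist(ternary_coordinates(0, 0, 0)),
               c(ternary_c = 1, ternary_s = 1, ternary_r = 1) / 3)
  expect_equal(rowSums(ternary_coordinates(c(4, 0, 2), c(1, 0, 2), c(0, 0, 5))),
               rep(1, 3), tolerance = 1e-12)
})

test_that("assignments take the unique argmax and fall back to intermediate", {
  expect_identical(assign_strategy(4, 1, 0), "competitor")
  expect_identical(assign_strategy(2, 2, 0), "intermediate")
  expect_identical(assign_strategy(0, 0, 0), "intermediate")
  expect_identical(assign_strategy(0, 1, 3), "ruderal")
  expect_error(assign_strategy(-1, 0, 0), class = "biphasix_validation_error")
})

test_that("autoplot places scores in the strategy triangle", {
  plt <- autoplot(csr_scores(generate_trait_table(
    6, c(MYb11 = "competitor", MYb71 = "stress_tolerator"))))
  expect_s3_class(plt, "ggplot")
})
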