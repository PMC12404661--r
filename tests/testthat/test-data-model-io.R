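make_obs <- function(...) {
  base <- data.frame(
    species_id = c("MYb11", "MYb71"), habitat = "plate", assay = "growth",
    culture = "co", time_h = 72, replicate = 1L, cfu = c(9e8, 1e8),
    unit = "per_plate", stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("cfu_table validates well-formed records and keeps row order", {
  tbl <- cfu_table(make_obs())
  expect_s3_class(tbl, "cfu_table")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$species_id, c("MYb11", "MYb71"))
})

test_that("cfu_table rejects invariant violations with informative errors", {
  expect_error(cfu_table(make_obs()[, -7]), "missing required column",
               class = "biphasix_schema_error")
  expect_error(cfu_table(make_obs(cfu = c(-5, 1e8))), "row\\(s\\) 1",
               class = "biphasix_validation_error")
  expect_error(cfu_table(make_obs(time_h = -1)),
               class = "biphasix_validation_error")
  expect_error(cfu_table(make_obs(replicate = 0L)),
               class = "biphasix_validation_error")
  expect_error(cfu_table(make_obs(unit = "per_worm")), "per_plate",
               class = "biphasix_validation_error")
  expect_error(cfu_table(make_obs(habitat = "worm")),
               class = "biphasix_validation_error")
  expect_error(cfu_table(make_obs(species_id = "MYb11")), "duplicate",
               class = "biphasix_validation_error")
  expect_warning(cfu_table(make_obs(replicate = c(1L, 2L))),
                 class = "biphasix_incomplete_pair")
})

test_that("CFU TSV round-trip is the identity, including scientific notation", {
  tbl <- generate_co_culture_assays(generator_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cfu_table(tbl, path)
  back <- read_cfu_table(path, experiment_id = attr(tbl, "experiment_id"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tbl))

  one <- cfu_table(make_obs(cfu = c(1.86e9, 8.0e8)))
  write_cfu_table(one, path)
  expect_identical(read_cfu_table(path)$cfu, c(1.86e9, 8.0e8))
})

test_that("empty table writes a header-only file that reads back empty", {
  tbl <- cfu_table(make_obs()[0, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cfu_table(tbl, path)
  expect_identical(length(readLines(path)), 1L)
  expect_equal(nrow(read_cfu_table(path)), 0)
})

test_that("missing files raise I/O errors", {
  expect_error(read_cfu_table("no/such/file.tsv"), class = "biphasix_io_error")
  expect_error(read_trait_table("no/such/file.tsv"), class = "biphasix_io_error")
})

make_traits <- function(...) {
  base <- data.frame(
    species_id = c("a", "b"), genome_size = c(6, 4),
    n_antibiotic_pathways = c(4, 1), n_siderophore_pathways = c(3, 1),
    n_catabolic_pathways = c(80, 40), max_growth_rate = c(0.4, 0.12),
    n_rrna_copies = c(6, 2), n_biofilm_genes = c(10, 30),
    n_auxotrophies = c(1, 5), codon_usage_bias = c(0.86, 0.67),
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("trait table autofills doubling time as log(2)/r_max", {
  tbl <- trait_table(make_traits())
  expect_equal(tbl$doubling_time_h, log(2) / c(0.4, 0.12), tolerance = 1e-12)
  expect_equal(round(tbl$doubling_time_h, 3), c(1.733, 5.776))
})

test_that("trait table validation enforces ranges and consistency", {
  expect_error(trait_table(make_traits(codon_usage_bias = c(1.2, 0.5))),
               "codon_usage_bias", class = "biphasix_validation_error")
  expect_error(trait_table(make_traits(max_growth_rate = c(0, 0.1))),
               class = "biphasix_validation_error")
  expect_error(trait_table(make_traits(n_rrna_copies = c(-1, 2))),
               class = "biphasix_validation_error")
  # stated doubling time disagreeing with r_max by more than 5% is rejected
  expect_error(trait_table(make_traits(doubling_time_h = c(3, 5.78))),
               "doubling_time_h", class = "biphasix_validation_error")
  # within the 5% slack it is accepted as given
  expect_silent(trait_table(make_traits(doubling_time_h = c(1.7, 5.8))))
})

test_that("trait TSV round-trip is the identity", {
  tbl <- trait_table(make_traits())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(tbl, path)
  expect_equal(tibble::as_tibble(read_trait_table(path)),
               tibble::as_tibble(tbl))
})

test_that("validation accepts every valid and rejects every invalid random record", {
  set.seed(11)
  for (i in 1:25) {
    habitat <- sample(c("plate", "worm"), 1)
    assay <- if (habitat == "plate") "growth" else
      sample(c("early_colonization", "established_colonization",
               "persistence", "release"), 1)
    rec <- data.frame(
      species_id = sample(c("x", "y"), 1), habitat = habitat, assay = assay,
      culture = "mono",  # a single row in "co" would trip the pair warning
      time_h = stats::runif(1, 0, 200), replicate = sample(1:6, 1),
      cfu = stats::rlnorm(1, 10, 2),
      unit = if (habitat == "plate") "per_plate" else "per_worm",
      stringsAsFactors = FALSE
    )
    expect_s3_class(cfu_table(rec), "cfu_table")
    broken <- rec
    field <- sample(c("cfu", "time_h", "replicate", "unit"), 1)
    broken[[field]] <- switch(field, cfu = -1, time_h = -1, replicate = 0L,
                              unit = setdiff(c("per_plate", "per_worm"),
                                             rec$unit))
    expect_error(cfu_table(broken), class = "biphasix_validation_error")
  }
})

test_that("od_calibration holds positive named constants", {
  cal <- od_calibration()
  expect_equal(unname(cal[["MYb11"]]), 1.86e9)
  expect_equal(unname(cal[["MYb71"]]), 8.0e8)
  expect_error(od_calibration(c(1e9, 2e9)), class = "biphasix_validation_error")
  expect_error(od_calibration(c(a = -1)), class = "biphasix_validation_error")
})
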