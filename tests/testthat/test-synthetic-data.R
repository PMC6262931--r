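test_that("abundance generator is deterministic and honours the spec", {
  spec <- abundance_spec(
    n_records = 500,
    true_fractions = c(calanoid = 0.6, cyclopoid = 0.3,
                       harpacticoid = 0.05, poecilostomatoid = 0.05),
    seed = 11)
  a <- generate_abundance_records(spec)
  b <- generate_abundance_records(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 500L)
  expect_equal(sum(a$decoy), round(0.2 * 500))
  # non-decoys all pass the composition filters; decoys all fail
  kept <- filter_records(a)
  expect_equal(nrow(kept), sum(!a$decoy))
  expect_false(any(kept$decoy))
})

test_that("degenerate mixtures and out-of-window depths behave as planted", {
  pure <- abundance_spec(
    n_records = 50,
    true_fractions = c(calanoid = 1, cyclopoid = 0,
                       harpacticoid = 0, poecilostomatoid = 0),
    seed = 2)
  kept <- filter_records(generate_abundance_records(pure))
  expect_true(all(kept$order == "calanoid"))

  deep <- abundance_spec(
    n_records = 50,
    true_fractions = c(calanoid = 1, cyclopoid = 0,
                       harpacticoid = 0, poecilostomatoid = 0),
    depth_range_m = c(150, 400), seed = 2)
  expect_equal(nrow(filter_records(generate_abundance_records(deep))), 0L)
})

test_that("abundance spec validation names the offending field", {
  expect_error(abundance_spec(n_records = 0,
    true_fractions = c(calanoid = 1, cyclopoid = 0,
                       harpacticoid = 0, poecilostomatoid = 0)),
    "n_records")
  expect_error(abundance_spec(n_records = 10,
    true_fractions = c(calanoid = 0.7, cyclopoid = 0.7,
                       harpacticoid = 0, poecilostomatoid = 0)),
    "true_fractions")
  expect_error(abundance_spec(n_records = 10,
    true_fractions = c(calanoid = 1, cyclopoid = 0,
                       harpacticoid = 0, poecilostomatoid = 0),
    mesh_values_um = c(200, 333)),
    "mesh_values_um")
})

test_that("ingestion generator reproduces an exact allometry when noiseless", {
  spec <- ingestion_spec(group = "calanoid", setting = "field", n = 40,
                         allometry_intercept = 0.05,
                         allometry_exponent = 1,
                         noise_sd_log10 = 0, seed = 5)
  recs <- generate_ingestion_records(spec)
  expect_equal(nrow(recs), 40L)
  expect_equal(recs$ingestion_ugC_per_day / recs$body_mass_ugC,
               rep(0.05, 40))
  expect_true(all(recs$body_mass_ugC >= 1 & recs$body_mass_ugC <= 100))
  # minimal spec returns exactly n records
  expect_equal(nrow(generate_ingestion_records(
    ingestion_spec(group = "cyclopoid", setting = "laboratory", n = 3,
                   allometry_intercept = 0.1, seed = 1))), 3L)
  expect_error(ingestion_spec(group = "calanoid", setting = "field",
                              n = 10, allometry_intercept = -1),
               "allometry_intercept")
  expect_identical(generate_ingestion_records(spec),
                   generate_ingestion_records(spec))
})

test_that("ingestion generator plants a recoverable exponent", {
  spec <- ingestion_spec(group = "calanoid", setting = "field", n = 500,
                         allometry_intercept = 0.1,
                         allometry_exponent = 0.8,
                         noise_sd_log10 = 0.1, seed = 9)
  recs <- generate_ingestion_records(spec)
  fit <- ols_log10(recs$body_mass_ugC, recs$ingestion_ugC_per_day)
  expect_lt(abs(fit["slope"] - 0.8), 0.05)
})

test_that("clone library plants the advertised structure", {
  spec <- clone_spec(n_copepods = 17, n_otus = 4,
                     within_otu_divergence = 0,
                     between_otu_divergence = 0.10, seed = 3)
  lib <- generate_clone_library(spec)
  expect_length(lib$sequences, 17 * 5)
  expect_true(all(grepl("^cop\\d+\\|clone\\d+$", names(lib$sequences))))
  expect_equal(rowSums(lib$incidence), stats::setNames(rep(5L, 17),
                                                       rownames(lib$incidence)))
  # pairwise reference divergence (substitution-only, so Hamming over
  # length) is at least the between bound
  refs <- strsplit(as.character(lib$references), "")
  L <- length(refs[[1]])
  for (i in 1:3) for (j in (i + 1):4)
    expect_gte(sum(refs[[i]] != refs[[j]]) / L, 0.10)
  expect_identical(as.character(generate_clone_library(spec)$sequences),
                   as.character(lib$sequences))
})

test_that("degenerate and infeasible clone specs behave correctly", {
  one <- generate_clone_library(clone_spec(
    n_copepods = 1, n_otus = 1, within_otu_divergence = 0,
    between_otu_divergence = 0.1, seed = 1))
  expect_length(unique(as.character(one$sequences)), 1L)
  expect_equal(unname(one$incidence[1, 1]), 5L)

  expect_error(clone_spec(n_copepods = 2, n_otus = 10,
                          within_otu_divergence = 0,
                          between_otu_divergence = 0.5,
                          seq_length_bp = 100),
               "infeasible")
  expect_error(clone_spec(n_copepods = 2, n_otus = 2,
                          within_otu_divergence = 0.2,
                          between_otu_divergence = 0.1),
               "within_otu_divergence")
})
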