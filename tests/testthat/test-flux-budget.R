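test_that("physiological closure splits ingestion exactly", {
  unit <- close_physiology(1)
  expect_equal(unname(unit[c("growth", "respiration", "egestion")]),
               c(0.3, 0.4, 0.3))
  expect_equal(sum(unit[c("growth", "respiration", "egestion")]), 1)
  expect_equal(unname(unit["assimilation"]), 0.7)

  # unicellular baseline: phytoplankton 8.67 + ciliates 2.82 GtC/yr
  base <- close_physiology(11.49)
  expect_equal(unname(base["egestion"]), 3.447)
  expect_equal(unname(base["sinking"]), 0.10341)

  expect_equal(unname(close_physiology(0)), rep(0, 6))
})

test_that("inconsistent rate triples raise a warning", {
  expect_warning(budget_params(GGE = 0.4), "inconsistent")
  expect_silent(budget_params())
})

test_that("the nitrogen ledger applies source C:N and excretion splits", {
  # single source at C:N 6.6: 6.6 GtC -> 1 GtN ingested
  n1 <- nitrogen_ledger(c(phytoplankton = 6.6))
  expect_equal(unname(n1["N_total"]), 1)
  expect_equal(unname(n1["NH4_N"]), 0.2)
  expect_equal(unname(n1["debris_N"]), 0.4)

  n2 <- nitrogen_ledger(c(phytoplankton = 8.67, ciliate = 2.82))
  expect_equal(unname(n2["N_total"]), 8.67 / 6.6 + 2.82 / 5.0)
  expect_equal(unname(n2["N_total"]), 1.87764, tolerance = 1e-5)

  # metazoan prey convert at the zooplankton C:N of 6.86
  n3 <- nitrogen_ledger(c(metazoan = 6.86))
  expect_equal(unname(n3["N_metazoan"]), 1)
  expect_error(nitrogen_ledger(c(bacteria = 1)), "bacteria")

  # ledger does not force closure: residual is whatever is left
  expect_equal(unname(n2["residual_N"]),
               unname(n2["N_total"] - n2["NH4_N"] - n2["debris_N"] -
                      n2["growth_N"]))
})

test_that("headline percentages match the published derivations", {
  expect_equal(round(headline_metrics(2.80)[["pct_of_PP"]], 1), 6.2)
  expect_equal(round(headline_metrics(1.79)[["pct_of_PP"]], 1), 4.0)
  expect_equal(round(headline_metrics(2.80)[[
    "pct_increment_over_unicellular"]], 1), 24.4)
  expect_equal(round(headline_metrics(1.79)[[
    "pct_increment_over_unicellular"]], 1), 15.6)
  expect_equal(round(headline_metrics(1.79)[["pct_PP_indirect"]], 1), 18.9)
  expect_error(headline_metrics(1, budget_params(I_phyto_GtC = 0,
                                                 I_ciliate_GtC = 0)),
               "unicellular")
})

test_that("percentages are invariant to a common flux rescale", {
  h1 <- headline_metrics(2.0)
  h2 <- headline_metrics(2.0 * 3, budget_params(
    PP_GtC_per_yr = 45 * 3, I_phyto_GtC = 8.67 * 3,
    I_ciliate_GtC = 2.82 * 3))
  expect_equal(h1, h2)
})

test_that("the regeneration ratio matches an independent recomputation", {
  # oracle: regenerated N is 60% of ingested N both with and without the
  # link, so the ratio reduces to total ingested N with/without
  oracle <- (8.67 / 6.6 + 2.82 / 5.0 + 2.80 / 6.86) /
            (8.67 / 6.6 + 2.82 / 5.0)
  expect_equal(regeneration_ratio(2.80), oracle)
  expect_equal(regeneration_ratio(2.80), 1.2174, tolerance = 1e-4)
  # consistent with the published 17 -> 20.7 nutrient increase as a ratio
  expect_equal(regeneration_ratio(2.80), 20.7 / 17, tolerance = 1e-3)
  expect_equal(regeneration_ratio(0), 1)
})

test_that("the assembled budget carries intervals and reduces at zero link", {
  b <- assemble_budget(1.79, 2.80)
  expect_equal(unname(b$with_link[, "ingestion"]),
               c(11.49 + 1.79, 11.49 + 2.80))
  # componentwise low <= high everywhere
  expect_true(all(b$with_link["low", ] <= b$with_link["high", ]))
  expect_true(all(b$nitrogen$with_link["low", ] <=
                  b$nitrogen$with_link["high", ]))
  expect_lte(b$exports$DOM[["low"]], b$exports$DOM[["high"]])
  expect_true(all(budget_edges(b)$low >= 0))

  null <- assemble_budget(0, 0)
  expect_equal(unname(null$with_link["low", ]), unname(null$baseline))
  expect_equal(unname(null$with_link["high", ]), unname(null$baseline))

  expect_error(assemble_budget(2, 1), "exceeds")
  # scenario objects are accepted directly
  st <- list(realm = "coastal", B_cal_GtC = 0.12, B_cyc_GtC = 0.078)
  sc <- annual_ingestion(st, wsir_table(), setting = "field")
  expect_equal(assemble_budget(sc, sc)$I_met[["low"]], sc$I_annual_GtC)
})

test_that("every link-driven flux is monotone in the link ingestion", {
  grid <- seq(0, 5, by = 0.5)
  prev <- NULL
  for (I in grid) {
    b <- assemble_budget(I, I)
    cur <- c(b$with_link["low", ],
             HTL = b$exports$HTL[["low"]],
             remin = b$exports$remineralization[["low"]],
             DOM = b$exports$DOM[["low"]],
             NH4 = b$nitrogen$with_link["low", "NH4_N"],
             regen = b$regeneration_ratio[["low"]])
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("edge table and DOT dump describe the same graph", {
  b <- assemble_budget(1.79, 2.80)
  edges <- budget_edges(b)
  expect_true(all(c("PP", "ciliates", "metazoan_prey") %in% edges$from))
  expect_true(all(c("HTL", "DOM", "remineralization", "NH4_pool",
                    "sinking_export") %in% edges$to))
  dot <- budget_dot(b)
  expect_match(dot, "digraph")
  expect_match(dot, "metazoan_prey")
  expect_equal(length(gregexpr("->", dot)[[1]]), nrow(edges))
})
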