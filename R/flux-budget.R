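#' Scalar parameters of the pelagic C and N flux budget
#'
#' Bundles the physiological and stoichiometric constants of the top-100 m
#' steady-state budget. Copepod physiology uses assimilation efficiency
#' `AE = 0.7`, gross growth efficiency `GGE = 0.3`, ingestion = 2.5 x
#' respiration and growth = 0.75 x respiration, a consistent triple
#' (`GGE + 1/2.5 + (1 - AE) = 1`), so carbon closes exactly at the copepod
#' node. Nitrogen follows ingestion through source-specific C:N ratios
#' (phytoplankton 6.6, ciliates 5.0, metazoan zooplankton prey 6.86);
#' excreted ammonium and debris/pellet release are 20% and 40% of ingested
#' N. Export splits to higher trophic levels (8%), remineralization (8%)
#' and DOM (3%-5% interval) come from the COBALT ecosystem model; sinking
#' is 3% of egestion.
#'
#' `PP_GtC_per_yr = 45` is used as the annual primary-production
#' denominator for the headline percentages; the same 45 GtC figure is also
#' cited in the literature as phytoplankton standing stock, and the
#' percentage chain only closes with it as an annual flux, so the
#' interpretation is recorded here as an explicit parameter.
#'
#' @param PP_GtC_per_yr Primary production denominator, GtC/yr.
#' @param I_phyto_GtC Global copepod ingestion of phytoplankton, GtC/yr.
#' @param I_ciliate_GtC Global copepod ingestion of ciliates, GtC/yr.
#' @param AE Assimilation efficiency, fraction of ingested C absorbed.
#' @param GGE Gross growth efficiency, fraction of ingested C to biomass.
#' @param ingestion_to_respiration Ingestion / respiration ratio.
#' @param growth_to_respiration Growth / respiration ratio.
#' @param f_NH4 Excreted ammonium fraction of ingested N.
#' @param f_debris Debris + fecal-pellet fraction of ingested N.
#' @param CN_zoo,CN_phyto,CN_ciliate Molar C:N of metazoan zooplankton
#'   prey, phytoplankton and ciliates.
#' @param f_HTL Fraction exported to higher trophic levels (fisheries).
#' @param f_remin Remineralized fraction.
#' @param f_DOM Dissolved-organic-matter fraction, an interval `c(lo, hi)`.
#' @param f_sink_of_egestion Sinking-export fraction of egestion.
#' @param export_base Copepod-ledger flux the HTL/remineralization/DOM
#'   fractions multiply: `"growth"` (production, default) or
#'   `"ingestion"`. The source model's base is not fully specified, so it
#'   is a named choice here.
#' @return An object of class `budget_params` (a named list).
#' @examples
#' p <- budget_params()
#' p$AE
#' @export
budget_params <- function(PP_GtC_per_yr = 45,
                          I_phyto_GtC = 8.67,
                          I_ciliate_GtC = 2.82,
                          AE = 0.7,
                          GGE = 0.3,
                          ingestion_to_respiration = 2.5,
                          growth_to_respiration = 0.75,
                          f_NH4 = 0.2,
                          f_debris = 0.4,
                          CN_zoo = 6.86,
                          CN_phyto = 6.6,
                          CN_ciliate = 5.0,
                          f_HTL = 0.08,
                          f_remin = 0.08,
                          f_DOM = c(0.03, 0.05),
                          f_sink_of_egestion = 0.03,
                          export_base = c("growth", "ingestion")) {
  export_base <- match.arg(export_base)
  check_number(PP_GtC_per_yr, "PP_GtC_per_yr", lower = 0,
               strict_lower = TRUE)
  check_number(I_phyto_GtC, "I_phyto_GtC", lower = 0)
  check_number(I_ciliate_GtC, "I_ciliate_GtC", lower = 0)
  for (nm in c("AE", "GGE", "f_NH4", "f_debris", "f_HTL", "f_remin",
               "f_sink_of_egestion"))
    check_number(get(nm), nm, lower = 0, upper = 1)
  check_number(ingestion_to_respiration, "ingestion_to_respiration",
               lower = 0, strict_lower = TRUE)
  check_number(growth_to_respiration, "growth_to_respiration", lower = 0)
  for (nm in c("CN_zoo", "CN_phyto", "CN_ciliate"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_interval(f_DOM, "f_DOM", lower = 0)
  if (any(f_DOM > 1)) stop_field("f_DOM", "must lie in [0, 1]")
  if (abs(GGE - growth_to_respiration / ingestion_to_respiration) > 1e-9)
    warning(sprintf(
      "inconsistent physiological rates: GGE = %.4g but growth/ingestion ",
      GGE), "respiration ratios imply ",
      sprintf("%.4g", growth_to_respiration / ingestion_to_respiration),
      call. = FALSE)
  structure(list(PP_GtC_per_yr = PP_GtC_per_yr,
                 I_phyto_GtC = I_phyto_GtC, I_ciliate_GtC = I_ciliate_GtC,
                 AE = AE, GGE = GGE,
                 ingestion_to_respiration = ingestion_to_respiration,
                 growth_to_respiration = growth_to_respiration,
                 f_NH4 = f_NH4, f_debris = f_debris,
                 CN_zoo = CN_zoo, CN_phyto = CN_phyto,
                 CN_ciliate = CN_ciliate,
                 f_HTL = f_HTL, f_remin = f_remin, f_DOM = f_DOM,
                 f_sink_of_egestion = f_sink_of_egestion,
                 export_base = export_base),
            class = "budget_params")
}

#' Close the copepod carbon physiology at a given ingestion
#'
#' Splits total copepod carbon ingestion into growth (`GGE * I`),
#' respiration (`I / ingestion_to_respiration`) and egestion
#' (`(1 - AE) * I`), plus assimilation (`AE * I`) and sinking export
#' (`f_sink_of_egestion * egestion`). With the default consistent rate
#' triple the three output fluxes sum exactly to ingestion.
#'
#' @param I_total_C Total copepod carbon ingestion, GtC/yr.
#' @param params A [budget_params()].
#' @return Named numeric vector `ingestion, assimilation, growth,
#'   respiration, egestion, sinking` (GtC/yr).
#' @examples
#' close_physiology(1)        # growth 0.3, respiration 0.4, egestion 0.3
#' close_physiology(11.49)    # unicellular baseline
#' @export
close_physiology <- function(I_total_C, params = budget_params()) {
  check_number(I_total_C, "I_total_C", lower = 0)
  stopifnot(inherits(params, "budget_params"))
  growth <- params$GGE * I_total_C
  respiration <- I_total_C / params$ingestion_to_respiration
  egestion <- (1 - params$AE) * I_total_C
  c(ingestion = I_total_C,
    assimilation = params$AE * I_total_C,
    growth = growth,
    respiration = respiration,
    egestion = egestion,
    sinking = params$f_sink_of_egestion * egestion)
}

# C:N for a named ingestion source
cn_for_source <- function(source, params) {
  switch(source,
         phytoplankton = params$CN_phyto,
         ciliate = params$CN_ciliate,
         metazoan = params$CN_zoo,
         stop("no C:N ratio configured for source: ", source,
              call. = FALSE))
}

#' Nitrogen ledger of copepod feeding
#'
#' Converts per-source carbon ingestion to nitrogen through each source's
#' C:N ratio, then applies the excretion split: ammonium = `f_NH4` and
#' debris/pellets = `f_debris` of total ingested N; growth N is growth C
#' over the copepod C:N. The ledger does not force closure -- the remaining
#' N is reported as a residual.
#'
#' @param I_by_source Named numeric vector of carbon ingestion (GtC/yr) per
#'   source; recognised names are `phytoplankton`, `ciliate`, `metazoan`.
#' @param params A [budget_params()].
#' @return Named numeric vector with per-source ingested N
#'   (`N_<source>`), `N_total`, `NH4_N`, `debris_N`, `growth_N`,
#'   `residual_N` (GtN/yr).
#' @examples
#' nitrogen_ledger(c(phytoplankton = 8.67, ciliate = 2.82))
#' @export
nitrogen_ledger <- function(I_by_source, params = budget_params()) {
  stopifnot(inherits(params, "budget_params"))
  if (!is.numeric(I_by_source) || is.null(names(I_by_source)))
    stop("I_by_source must be a named numeric vector", call. = FALSE)
  if (any(I_by_source < 0)) stop("ingestion values must be non-negative")
  N_s <- vapply(names(I_by_source), function(s)
    I_by_source[[s]] / cn_for_source(s, params), numeric(1))
  names(N_s) <- paste0("N_", names(I_by_source))
  N_total <- sum(N_s)
  growth_C <- params$GGE * sum(I_by_source)
  NH4 <- params$f_NH4 * N_total
  debris <- params$f_debris * N_total
  growth_N <- growth_C / params$CN_zoo
  c(N_s, N_total = N_total, NH4_N = NH4, debris_N = debris,
    growth_N = growth_N,
    residual_N = N_total - NH4 - debris - growth_N)
}

#' Headline percentages for the metazoan-copepod link
#'
#' Expresses the annual metazoan-link ingestion `I_met` relative to the
#' rest of the budget: share of primary production (`100 I_met / PP`),
#' increment over unicellular (phytoplankton + ciliate) ingestion, and the
#' share of PP that reaches copepods indirectly through their metazoan
#' prey. The indirect share assumes the prey themselves feed on
#' phytoplankton with a gross efficiency of `AE * GGE` (0.21 by default),
#' so sustaining `I_met` consumes `I_met / (AE * GGE)` of PP.
#'
#' @param I_met Annual metazoan-link carbon ingestion, GtC/yr.
#' @param params A [budget_params()].
#' @return Named numeric vector `pct_of_PP, pct_increment_over_unicellular,
#'   pct_PP_indirect` (percent).
#' @examples
#' headline_metrics(2.80)
#' @export
headline_metrics <- function(I_met, params = budget_params()) {
  check_number(I_met, "I_met", lower = 0)
  stopifnot(inherits(params, "budget_params"))
  I_uni <- params$I_phyto_GtC + params$I_ciliate_GtC
  if (params$PP_GtC_per_yr <= 0) stop("PP must be positive")
  if (I_uni <= 0)
    stop("unicellular ingestion is zero; increment undefined",
         call. = FALSE)
  c(pct_of_PP = 100 * I_met / params$PP_GtC_per_yr,
    pct_increment_over_unicellular = 100 * I_met / I_uni,
    pct_PP_indirect =
      100 * (I_met / (params$AE * params$GGE)) / params$PP_GtC_per_yr)
}

#' Nitrogen-regeneration ratio with and without the metazoan link
#'
#' Regenerated N (ammonium + debris/pellets, `f_NH4 + f_debris` = 60% of
#' ingested N by default) scales with total ingested N, so the with-link /
#' baseline ratio equals the ratio of total ingested N. This is the
#' dimensionless form of the budget's increase in nutrients returned to
#' the photic layer.
#'
#' @param I_met Annual metazoan-link carbon ingestion, GtC/yr.
#' @param params A [budget_params()].
#' @return The ratio (>= 1).
#' @examples
#' regeneration_ratio(2.80)  # ~1.217
#' @export
regeneration_ratio <- function(I_met, params = budget_params()) {
  check_number(I_met, "I_met", lower = 0)
  base <- nitrogen_ledger(c(phytoplankton = params$I_phyto_GtC,
                            ciliate = params$I_ciliate_GtC), params)
  with_link <- nitrogen_ledger(c(phytoplankton = params$I_phyto_GtC,
                                 ciliate = params$I_ciliate_GtC,
                                 metazoan = I_met), params)
  unname(with_link["N_total"] / base["N_total"])
}

#' Assemble the full C and N budget with interval-valued link fluxes
#'
#' Combines the unicellular baseline (phytoplankton + ciliate ingestion,
#' point values) with the metazoan-copepod link carried as an interval
#' `[low, high]` of annual ingestion. Every link-driven flux becomes an
#' interval; export splits (HTL, remineralization, DOM) are attached as
#' fractions of the configured copepod-ledger base; sinking is a fraction
#' of egestion.
#'
#' @param scenario_low,scenario_high [annual_ingestion()] scenarios (or
#'   bare numbers, GtC/yr) bounding the link; `low <= high` required. Pass
#'   the same value twice for a point budget.
#' @param params A [budget_params()].
#' @return An object of class `flux_budget`: list with `I_met` (interval),
#'   `baseline` (point C ledger), `with_link` (C ledger, low/high matrix),
#'   `nitrogen` (baseline and low/high ledgers), `exports` (HTL, remin,
#'   DOM low/high), `headline` (metrics at low/high),
#'   `regeneration_ratio` (interval), and `params`.
#' @examples
#' b <- assemble_budget(1.79, 2.80)
#' b$headline
#' @export
assemble_budget <- function(scenario_low, scenario_high,
                            params = budget_params()) {
  as_I <- function(x)
    if (inherits(x, "ingestion_scenario")) x$I_annual_GtC else x
  lo <- as_I(scenario_low); hi <- as_I(scenario_high)
  check_number(lo, "scenario_low", lower = 0)
  check_number(hi, "scenario_high", lower = 0)
  if (lo > hi)
    stop("scenario_low exceeds scenario_high", call. = FALSE)
  stopifnot(inherits(params, "budget_params"))

  I_uni <- params$I_phyto_GtC + params$I_ciliate_GtC
  baseline <- close_physiology(I_uni, params)
  ledger <- function(I_met) close_physiology(I_uni + I_met, params)
  with_link <- rbind(low = ledger(lo), high = ledger(hi))

  n_base <- nitrogen_ledger(c(phytoplankton = params$I_phyto_GtC,
                              ciliate = params$I_ciliate_GtC), params)
  n_link <- function(I_met)
    nitrogen_ledger(c(phytoplankton = params$I_phyto_GtC,
                      ciliate = params$I_ciliate_GtC,
                      metazoan = I_met), params)
  nitrogen <- list(baseline = n_base,
                   with_link = rbind(low = n_link(lo), high = n_link(hi)))

  base_flux <- with_link[, params$export_base]
  exports <- list(
    HTL = params$f_HTL * base_flux,
    remineralization = params$f_remin * base_flux,
    DOM = c(low = params$f_DOM[1] * base_flux[["low"]],
            high = params$f_DOM[2] * base_flux[["high"]]))

  headline <- rbind(low = headline_metrics(lo, params),
                    high = headline_metrics(hi, params))

  structure(list(
    I_met = c(low = lo, high = hi),
    baseline = baseline,
    with_link = with_link,
    nitrogen = nitrogen,
    exports = exports,
    headline = headline,
    regeneration_ratio = c(low = regeneration_ratio(lo, params),
                           high = regeneration_ratio(hi, params)),
    params = params
  ), class = "flux_budget")
}

#' @export
print.flux_budget <- function(x, ...) {
  iv <- function(v) sprintf("[%.3f, %.3f]", v[1], v[2])
  cat("Pelagic C/N flux budget, top 100 m (GtC/yr unless noted)\n")
  cat(sprintf("  metazoan-copepod link ingestion %s\n", iv(x$I_met)))
  cat(sprintf("  total copepod ingestion         %s (baseline %.2f)\n",
              iv(x$with_link[, "ingestion"]), x$baseline[["ingestion"]]))
  for (f in c("growth", "respiration", "egestion", "sinking"))
    cat(sprintf("  %-16s %s\n", f, iv(x$with_link[, f])))
  cat(sprintf("  HTL export       %s\n", iv(x$exports$HTL)))
  cat(sprintf("  remineralization %s\n", iv(x$exports$remineralization)))
  cat(sprintf("  DOM              %s\n", iv(x$exports$DOM)))
  cat(sprintf("  link as %% of PP  [%.1f, %.1f]\n",
              x$headline["low", "pct_of_PP"],
              x$headline["high", "pct_of_PP"]))
  cat(sprintf("  increment over unicellular ingestion [%.1f, %.1f] %%\n",
              x$headline["low", "pct_increment_over_unicellular"],
              x$headline["high", "pct_increment_over_unicellular"]))
  cat(sprintf("  PP reaching copepods indirectly [%.1f, %.1f] %%\n",
              x$headline["low", "pct_PP_indirect"],
              x$headline["high", "pct_PP_indirect"]))
  cat(sprintf("  N regeneration ratio vs baseline [%.4f, %.4f]\n",
              x$regeneration_ratio[1], x$regeneration_ratio[2]))
  invisible(x)
}

#' Node/edge table of a flux budget
#'
#' Flattens a [assemble_budget()] result into an edge list suitable for
#' graph rendering or export, with low/high bounds per edge (equal for
#' point-valued unicellular fluxes).
#'
#' @param budget A `flux_budget`.
#' @return Data frame with columns `from, to, element, low, high`.
#' @export
budget_edges <- function(budget) {
  stopifnot(inherits(budget, "flux_budget"))
  p <- budget$params
  wl <- budget$with_link
  e <- function(from, to, element, low, high = low)
    data.frame(from = from, to = to, element = element,
               low = low, high = high, stringsAsFactors = FALSE)
  out <- rbind(
    e("PP", "copepods", "C", p$I_phyto_GtC),
    e("ciliates", "copepods", "C", p$I_ciliate_GtC),
    e("metazoan_prey", "copepods", "C",
      budget$I_met[["low"]], budget$I_met[["high"]]),
    e("copepods", "respiration", "C",
      wl["low", "respiration"], wl["high", "respiration"]),
    e("copepods", "copepod_growth", "C",
      wl["low", "growth"], wl["high", "growth"]),
    e("copepods", "egestion", "C",
      wl["low", "egestion"], wl["high", "egestion"]),
    e("egestion", "sinking_export", "C",
      wl["low", "sinking"], wl["high", "sinking"]),
    e("copepods", "HTL", "C",
      budget$exports$HTL[["low"]], budget$exports$HTL[["high"]]),
    e("copepods", "remineralization", "C",
      budget$exports$remineralization[["low"]],
      budget$exports$remineralization[["high"]]),
    e("copepods", "DOM", "C",
      budget$exports$DOM[["low"]], budget$exports$DOM[["high"]]),
    e("copepods", "NH4_pool", "N",
      budget$nitrogen$with_link["low", "NH4_N"],
      budget$nitrogen$with_link["high", "NH4_N"]),
    e("copepods", "debris_pellets", "N",
      budget$nitrogen$with_link["low", "debris_N"],
      budget$nitrogen$with_link["high", "debris_N"])
  )
  rownames(out) <- NULL
  out
}

#' DOT rendering of a flux budget graph
#'
#' @param budget A `flux_budget`.
#' @return A single string of Graphviz DOT source.
#' @export
budget_dot <- function(budget) {
  edges <- budget_edges(budget)
  lab <- ifelse(edges$low == edges$high,
                sprintf("%.3g %s", edges$low, edges$element),
                sprintf("[%.3g, %.3g] %s", edges$low, edges$high,
                        edges$element))
  paste0("digraph flux_budget {\n  rankdir=LR;\n",
         paste(sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       edges$from, edges$to, lab), collapse = "\n"),
         "\n}\n")
}
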