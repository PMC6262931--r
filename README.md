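# copelink

Carbon flux budgets for the metazoan-copepod trophic link.

Small copepods (< 2 mm) are modelled in global ocean ecosystem models as
grazers of phytoplankton and microzooplankton, yet gut-content clone
libraries show they routinely ingest metazoan prey — decapod and bivalve
larvae, fish, other copepods. `copelink` is an R package for marine
trophic ecologists and biogeochemical modellers that quantifies this
overlooked trophic pathway at global scale and propagates it through a
steady-state C and N budget of the top 100 m of the ocean.

## The estimation chain

1. **Composition** — filter plankton-database abundance records (adults
   and copepodites, ≤ 100 m, 100–116 µm mesh) and compute the
   calanoid/cyclopoid shares per realm, merging the carnivorous
   poecilostomatoids into the cyclopoids.
2. **WSIR** — weight-specific ingestion rates (µgC prey · µgC
   copepod⁻¹ · day⁻¹) per group and setting, fitted from feeding-study
   records by the log-log allometric regression
   `log10(I) = a + b·log10(M)` evaluated at the mean body mass, or taken
   from the published defaults (field 0.023/0.063, laboratory
   0.396/0.241 for calanoids/cyclopoids).
3. **Standing stock** — global adult copepod carbon
   `B = Z₀ · (1 + 1/3) · 0.8 · 0.6` = 0.1984 GtC from a 0.31 GtC
   zooplankton stock, partitioned by the realm composition profiles.
4. **Annual ingestion** — `I = (B_cal·WSIR_cal + B_cyc·WSIR_cyc) · 365`
   per realm × setting, spanning the global link range.
5. **Flux budget** — physiological closure (AE = 0.7, GGE = 0.3,
   ingestion = 2.5 × respiration), a source-stoichiometric N ledger
   (C:N 6.6 / 5.0 / 6.86), export splits (HTL 8 %, remineralization 8 %,
   DOM 3–5 %, sinking 3 % of egestion) and the headline percentages of
   primary production.

A gut-content module clusters clone sequences into OTUs at < 1 %
divergence (global alignment, greedy centroid linkage) and summarises
diet incidence across oceanographic conditions, including the packaged
17-copepod × 16-OTU incidence fixture. Synthetic-data generators with
planted ground truth (composition mixtures, allometric feeding records,
clone libraries) make every stage testable offline.

## Worked example

```r
library(copelink)

res <- run_pipeline(run_config(mode = "replication"), out_dir = NULL)
res$scenarios
#>     realm    setting I_annual_GtC I_calanoid_GtC I_cyclopoid_GtC
#> 1 coastal      field     2.801010       1.007400       1.7936100
#> 2 coastal laboratory    24.206070      17.344800       6.8612700
#> 3 oceanic      field     1.789834       1.520664       0.2691703
#> 4 oceanic laboratory    27.211543      26.181860       1.0296831
```

The field scenarios bracket the conservative global estimate of the
link (1.79–2.80 GtC/yr ingested by small copepods from metazoan prey);
the laboratory scenarios, measured near food saturation, bracket the
upper range (24.2–27.2 GtC/yr).

```r
assemble_budget(1.79, 2.80)
#> Pelagic C/N flux budget, top 100 m (GtC/yr unless noted)
#>   metazoan-copepod link ingestion [1.790, 2.801]
#>   total copepod ingestion         [13.280, 14.291] (baseline 11.49)
#>   growth           [3.984, 4.287]
#>   respiration      [5.312, 5.716]
#>   egestion         [3.984, 4.287]
#>   sinking          [0.120, 0.129]
#>   HTL export       [0.319, 0.343]
#>   remineralization [0.319, 0.343]
#>   DOM              [0.120, 0.214]
#>   link as % of PP  [4.0, 6.2]
#>   increment over unicellular ingestion [15.6, 24.4] %
#>   PP reaching copepods indirectly [18.9, 29.6] %
#>   N regeneration ratio vs baseline [1.1390, 1.2175]
```

Read: the link adds 1.8–2.8 GtC/yr on top of the 11.49 GtC/yr copepods
already ingest from phytoplankton and ciliates — a 15.6–24.4 % increment
that raises copepod growth, fecal-pellet export and the nitrogen
regenerated to the photic layer by the same proportion, and represents
4.0–6.2 % of primary production directly (18.9–29.6 % indirectly,
through what the metazoan prey themselves consumed).

```r
fix <- load_gut_incidence()
diet_summary(fix$incidence, fix$conditions, fix$taxonomy)
#> Diet incidence summary: 16 OTUs detected
#>   downwelling  n=7, distinct OTUs 7, richness 1.86 +/- 0.69 [1, 3]
#>   upwelling    n=10, distinct OTUs 12, richness 2.00 +/- 1.15 [1, 4]
#>   phyla:  Chordata 1, Crustacea 13, Mollusca 2
#>   richness t test: t = -0.291, p = 0.775
```

Every copepod species examined carried metazoan prey; richness does not
differ significantly between upwelling and downwelling conditions.

`run_pipeline(config, out_dir = "out")` additionally writes the scenario
table, the budget as edge list/JSON/DOT, the diet summary and a
provenance block recording every parameter.

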