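# metammi

AMMI analysis and yield-stability selection for balanced multi-environment
variety trials, in R.

Multi-location trials confront breeders with genotype-by-environment
interaction (GEI): the part of yield variation left after genotype and
environment main effects, which decides whether a hybrid is broadly stable
or specifically adapted. metammi implements the Additive Main effects and
Multiplicative Interaction (AMMI) treatment of an RCBD trial end to end:

* **Model.** For cell means of a G×E table,
  `y_ge = μ + α_g + β_e + Σ_n λ_n γ_gn δ_en + q_ge`: additive main effects
  by double-centering, then the SVD of the centered interaction matrix.
  Scores are √λ-scaled on both sides, the only convention under which a
  published score table and its companion ANOVA table are simultaneously
  consistent; axis *n* carries plot-basis SS `r·λ_n²` and Gollob degrees
  of freedom `G + E − 1 − 2n` for its approximate F test.
* **Stability.** ASV (origin distance in the IPCA1/IPCA2 plane with the
  first axis weighted by `SS_IPCA1/SS_IPCA2`) and the genotype selection
  index GSI = rank(yield, descending) + rank(ASV, ascending), competition
  ranking.
* **Selection.** AMMI1/AMMI2 biplot coordinates with quadrant grouping and
  per-environment winner lists from the truncated fitted matrix.
* **Validation.** A seeded synthetic RCBD generator with planted low-rank
  interaction and a recovery-study harness.

It ships a published reference dataset — grain yields (t/ha) of 69 maize
hybrids × 5 Polish locations (Kobierzyce, Mikulice, Płaczkowo, Radzików,
Smolice; ASCII names in the files), 2017, three blocks — as plain-CSV cell
means plus the published scores, for regression testing and worked
examples.

## Worked example

```r
library(metammi)

ref <- smoliceMaize()               # packaged 69 x 5 reference trial, r = 3
fit <- fitAmmi(ref$means, errorMs = 432.9 / 680, errorDf = 680)
axisSummary(fit)
#>   axis singularValue        ss df       ms        f            p explainedPct
#> 1    1      7.592617 172.94350 71 2.435824 3.826196 3.654387e-20     33.67852
#> 2    2      7.111174 151.70640 69 2.198643 3.453633 9.312705e-17     29.54287
#> 3    3      6.008158 108.29389 67 1.616327 2.538929 1.971394e-09     21.08884
#> 4    4      5.182310  80.56902 65 1.239523 1.947045 2.851375e-05     15.68978
```

The interaction SS (3 × Σλ² ≈ 513.5 on the plot basis) splits into four
multiplicative axes; the first explains 33.7 % of GEI and is highly
significant against the pooled error MS 0.64 on 680 d.f. (F ≈ 3.83).

```r
head(stabilityTable(fit, sort = TRUE), 3)
#>     genotype   mean       ipca1      ipca2       asv rankYield rankAsv gsi
#> 41  SMH_1706 14.920 0.078034215 0.08998485 0.1265338         1       2   3
#> 42  SMH_1707 14.374 0.007514313 0.13438456 0.1346573         4       6  10
#> 47  SMH_1711 14.368 -0.032355696 0.12764230 0.1328649         5       5  10
```

SMH_1706 is simultaneously the top-yielding hybrid (14.92 t/ha) and nearly
the most stable (ASV 0.127), giving the best selection index in the trial.
`perEnvironmentSelections(fit, nAxes = 2)` lists the AMMI-predicted
winners per location, `plotAmmi1(fit)` / `plotAmmi2(fit)` draw the
biplots, and `runPipeline("fixture", outDir = "out", errorMs = 432.9/680,
errorDf = 680)` writes the full CSV/JSON/text bundle in one call. A thin
command-line wrapper lives at `inst/scripts/ammi-report.R`.

Replicate-level data enter through `readTrialLong()` (long CSV:
genotype, environment, block, yield; names remappable), which feeds
`partitionRcbd()` for the full ANOVA including blocks and pooled error.

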