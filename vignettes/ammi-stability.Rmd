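---
title: "AMMI analysis of multi-environment trials with metammi"
author: "metammi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AMMI analysis of multi-environment trials with metammi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metammi)
```

## The problem and the model

Variety trials repeated across locations rarely rank genotypes the same
way everywhere: part of the yield variation is genotype-by-environment
interaction (GEI), the non-additive remainder after genotype and
environment main effects. Breeders want both faces of that remainder —
genotypes that are *stable* (small interaction, consistent everywhere) and
genotypes with *specific adaptation* (large interaction aligned with a
target location).

metammi implements the Additive Main effects and Multiplicative
Interaction (AMMI) treatment of a balanced RCBD multi-environment trial.
For the mean yield of genotype $g$ in environment $e$ (over $r$ blocks):

$$y_{ge} = \mu + \alpha_g + \beta_e
  + \sum_{n=1}^{N} \lambda_n\, \gamma_{gn}\, \delta_{en} + q_{ge},$$

where $\mu$ is the grand mean, $\alpha_g$ and $\beta_e$ are centered main
effects, and the interaction is the singular value decomposition of the
double-centered matrix $z_{ge} = y_{ge} - \bar y_{g\cdot} - \bar y_{\cdot e}
+ \bar y_{\cdot\cdot}$: singular values $\lambda_n$ (descending) with
orthonormal axes $\gamma_{\cdot n}$, $\delta_{\cdot n}$. $q_{ge}$ collects
the axes beyond the $N$ retained. Plot error lives a level below, in the
replicate-level ANOVA.

The pipeline is: `cellMeans()` → `partitionRcbd()`/`partitionMeans()` →
`fitAmmi()` → `stabilityTable()` / `ammi1Coords()` / `ammi2Coords()` /
`perEnvironmentSelections()`, or all at once via `runPipeline()`.

## Score scaling — the one convention that matters

SVD output can be attached to the two sides in several ways. metammi uses
*symmetric square-root scaling*: genotype scores $u_{gn}\sqrt{d_n}$ and
environment scores $v_{en}\sqrt{d_n}$. Consequences, all enforced by
tests:

* the outer product of the two score columns of axis $n$ reconstructs that
  axis's interaction term — summing over all axes returns $z$ exactly;
* $\sum_g \text{score}_{gn}^2 = \sum_e \text{score}_{en}^2 = d_n$;
* the plot-basis sum of squares of axis $n$ is $r\,d_n^2$, so the printed
  scores of a published table and its companion ANOVA table are mutually
  consistent under exactly this scaling (for the packaged reference
  dataset: environment axis-1 scores have $\sum v^2 \approx 7.59 =
  \sqrt{172.9/3}$). That consistency is why this convention was chosen;
  with full-$d$ or unit scaling the two published tables cannot both hold.

Axis signs are arbitrary. The default orientation rule (`orient =
"env-max"`) flips each axis so the environment with the largest absolute
score is positive. For the reference dataset this reproduces the published
axis-1 signs; the published axis-2 signs follow no such rule, so
comparisons to published score tables should always be made up to per-axis
sign. Every substantive quantity — SS, explained %, ASV, fitted values,
selections — is sign-invariant (tested).

## Testing the axes: Gollob degrees of freedom

Axis $n$ of a $G \times E$ table receives $G + E - 1 - 2n$ degrees of
freedom. With an external pooled error mean square (from the
replicate-level ANOVA, or supplied when only a published mean table is
available) each axis gets an approximate F test; `gollobTest()` recommends
retaining the leading run of consecutive significant axes. This is a
liberal test — it tends to keep more axes than cross-validation would —
but it is the standard desk procedure when raw plots are unavailable.
Default retention (`nAxes = "auto"`): the Gollob recommendation when error
information is present, otherwise 2 (the biplot convention).

The explained-% column of `ammiAnovaTable()` deliberately follows the
mixed convention of published AMMI tables: main strata as a share of the
total SS, interaction axes as a share of the interaction SS. The two
denominators are different; read the column accordingly.

## Stability and selection

The AMMI stability value for genotype $g$ is

$$\mathrm{ASV}_g = \sqrt{\left(w\, \mathrm{IPCA1}_g\right)^2 +
 \mathrm{IPCA2}_g^2}, \qquad w = \frac{SS_{\mathrm{IPCA1}}}{SS_{\mathrm{IPCA2}}}
 = \frac{d_1^2}{d_2^2},$$

a weighted distance from the biplot origin; the weight is basis-invariant
because $r$ cancels. ASV needs two non-degenerate axes — for a rank-1 (or
additive) interaction the weight is undefined and `asv()` refuses rather
than guessing; `runPipeline()` then skips the stability stage and flags it.

The genotype selection index is the sum of two *competition* (minimum)
ranks: mean yield ranked descending, ASV ranked ascending; ties share the
smallest applicable rank. Competition ranking was chosen because published
GSI columns are integer-valued and no averaging rule is ever stated; it is
the one place where a different tie rule could change results, and it is
isolated in `rankValues()`.

```{r stability}
ref <- smoliceMaize()
fit <- fitAmmi(ref$means, errorMs = 432.9 / 680, errorDf = 680)
axisSummary(fit)[, c("axis", "ss", "df", "f", "explainedPct")]
head(stabilityTable(fit, sort = TRUE))
```

A note on the packaged reference tables: the published GSI column is not
arithmetically consistent with the published ASV column for one genotype
(SMH_1724, whose printed scores give ASV 0.082 while the published
narrative and GSI ranks imply 0.919). Recomputing GSI from the printed ASV
column therefore shifts a few entries — in particular the best recomputed
GSI is 3, not the published 2. metammi always recomputes; the published
column is kept verbatim in `smoliceMaize()$genotypeScores` for reference.

## Biplots and per-environment winners

`ammi1Coords()` (mean vs IPCA1, grand-mean reference line) reads overall
performance against interaction size; `ammi2Coords()` (IPCA1 vs IPCA2)
groups genotypes and environments into four quadrants of specific
adaptation. A coordinate of exactly zero is assigned to the positive side
— an arbitrary but deterministic tie rule. `perEnvironmentSelections()`
ranks genotypes within each environment by the AMMI-estimated yield
truncated to `nAxes` terms. The retained-axis count materially changes
these lists; since published per-environment rankings rarely state their
$N$, the honest use is to scan:

```{r selections}
lapply(setNames(1:4, paste0("N=", 1:4)), function(n) {
  sel <- perEnvironmentSelections(fit, nAxes = n, topK = 4)
  split(sel$genotype, sel$environment)[["Kobierzyce"]]
})
```

## The synthetic generator

`generateMet()` realizes the generative reading of the model: centered
Gaussian main effects, a planted low-rank interaction $\sum_k d_k u_k
v_k^\top$ built from random orthonormal zero-sum axes, block effects
nested in environments, i.i.d. Gaussian plot error, one integer seed, and
no leakage into the caller's RNG state. Defaults emulate the reference
trial's conditions, derived once from its ANOVA partition: $G=69$, $E=5$,
$r=3$, $\mu = 13.18$ t/ha, `alphaSd = 0.92` ($\sum\alpha^2 = 853.4/(rE)$),
`betaSd = 0.86` ($\sum\beta^2 = 609.1/(rG)$), singular values
$(7.59, 7.11, 6.01, 5.18) = \sqrt{SS_n/r}$, `errorSd = 0.8` (error MS
0.64) and `blockSd = 0.12` (the block mean square implied by the
degrees-of-freedom arithmetic of the reference ANOVA, whose block stratum
is not printed).

What it does *not* emulate: spatial field trend, heteroscedastic or
correlated plot error, missing plots, genotype-specific error variance,
and weather-driven structure in the environment effects. Passing recovery
tests therefore demonstrate correctness of the estimator under the model's
own assumptions, not robustness to real-field violations of them.

`recoveryStudy()` wraps repeated generate–fit cycles and reports bias and
RMSE of the singular values, the axis-1 explained-% distribution, and the
Spearman agreement between planted and estimated ASV rankings. The test
suite runs it at $G=50$, $E=5$, $r=3$, $d=(6,3)$, error SD 0.3 (40
replicates in the unit test, 200 in the end-to-end check) — sizes chosen
to exercise the estimator well away from degeneracy while keeping the
default suite fast.

## Numerical choices and degenerate inputs

* Completeness and balance are hard requirements: unbalanced replication
  is rejected, not averaged, because the plot-basis conversion multiplies
  by a single common $r$; there is no missing-cell imputation.
* Axes with $d_n \le \max(10^{-10} d_1,\ 10^{-12}\max(1, |\mu|))$ are
  treated as numerically zero when counting usable axes, so an exactly
  additive table reports zero usable axes rather than machine noise.
* Tied singular values keep the SVD's own descending order; no re-sorting.
* All invariants (orthogonality, zero sums, reconstruction, SS
  conservation) are asserted at $10^{-9}$ in the tests.
* Yields must be strictly positive (t/ha); the generator refuses
  parameter combinations that produce nonpositive plots.

## Limitations

Fixed-effects only (no REML variance components, no mixed-model shrinkage
of scores); no GGE biplot, no Eberhart–Russell regression, Wricke
ecovalence or Shukla variance; no mega-environment delineation beyond the
per-environment winner lists. Reproductions from printed mean tables
inherit the table's rounding: with 2-d.p. means, SS of order 500 are
reproducible to roughly ±1.5 and sqrt-scaled scores to ±0.01–0.02, which
is the tolerance regime used throughout the tests.
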