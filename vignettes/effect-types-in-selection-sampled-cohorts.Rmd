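---
title: "Total or controlled direct effects when adjusting for risk factors in selection-sampled cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total or controlled direct effects when adjusting for risk factors in selection-sampled cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectpath)
```

## The problem

Studies comparing health outcomes between immigrants and non-immigrants
typically regress the outcome $D$ on country of birth $E$ plus a set of
observed outcome risk factors (smoking, BMI, socioeconomic status, ...).
The adjustment is meant to remove bias from the unequal distribution of
those risk factors across the compared groups. But an unequal distribution
is not always bias. It can arise in two very different ways:

* **Mediation.** The populations already differed in the risk factor before
  migration ($E \to R_0$). The risk factor then lies on a causal path
  $E \to R_0 \to R \to D$, and adjusting for it removes part of the effect
  under study.
* **Selection.** The risk factor affects who ends up in the analyzed dataset
  ($R_0 \to S$, with the sample restricted to $S = 1$). Restriction to a
  common effect (a collider, since also $E \to S$) induces a spurious
  $E$--$R_0$ association, and through $R_0 \to R \to D$ a biased
  $E$--$D$ association.

Whether an adjusted regression coefficient is a **total effect**, a
**controlled direct effect (CDE)**, or simply **biased** depends on which of
these roles the risk factor plays. `effectpath` makes that decision
executable in two independent ways -- a graphical classifier and a
simulation engine -- and verifies that they agree.

Throughout, $E$ is a binary exposure (reference vs comparison country),
$D$ a continuous outcome, $R_0$ the unmeasured pre-migration risk factor,
$R$ its measured post-migration value, $S$ the dataset-membership indicator
(always conditioned: the data are the rows with $S = 1$), and $C$ a
mediator--outcome confounder.

## The graphical classifier

For a DAG with declared node roles and a user-supplied adjustment set $Z$,
the classifier conditions on $Z \cup \{S\}$ and applies the standard path
rules: a chain or fork node blocks a path when conditioned; a collider
blocks unless it or a descendant is conditioned. The verdict is

* `BIASED` if any non-causal $E$--$D$ path is open,
* `CONTROLLED_DIRECT` if no non-causal path is open but at least one
  directed $E \to \dots \to D$ path is blocked,
* `TOTAL` otherwise.

Two deliberate choices:

* **"Causal path" is read off the full DAG before conditioning.** The total
  effect is defined over all directed paths, so a blocked directed path
  (removed mediation) is what separates `CONTROLLED_DIRECT` from `TOTAL`.
  A directed path through $S$ itself ($E \to S \to R \to D$ in the
  post-migration variant) counts as blocked by the sample restriction, so
  such models classify as `CONTROLLED_DIRECT`. The same reasoning applies
  to the variant without any biasing path: the restriction alone blocks the
  $S$-mediated path, and the classifier reports `CONTROLLED_DIRECT` with
  that blocked path listed as evidence rather than guessing a different
  label.
* **Verdicts are strict.** The argument that adjusting for $R$ "largely
  also adjusts for" its close ancestor $R_0$ is quantitative, not
  graphical: graphically a noisy descendant never blocks a chain through
  its parent. The classifier therefore calls the $R$-adjusted, $C$-omitted
  analysis `BIASED` whenever the confounding path is open, and the
  attenuation experiment (below) measures how small that bias becomes as
  the measurement noise shrinks.

`d_separated()` implements d-separation by the moral ancestral graph
construction. It is cross-checked, for every node pair and every
conditioning subset of 200 random DAGs of up to 7 nodes, against the
independent route of exhaustive path enumeration plus the open/closed rules
(`enumerate_paths()` + `path_open()`).

## The structural models

Each template DAG carries a fully parameterized structural causal model:
$E \sim \mathrm{Bernoulli}(p_E)$; every continuous node is a linear
function of its parents plus Gaussian noise; $S$ is Bernoulli with a
logistic link. Ground truths come from the do-operator:
$\mathrm{TE} = \mathrm{E}[D \mid do(E{=}1)] - \mathrm{E}[D \mid do(E{=}0)]$
and
$\mathrm{CDE}(m) = \mathrm{E}[D \mid do(E{=}1, R{=}m)] -
\mathrm{E}[D \mid do(E{=}0, R{=}m)]$,
computed analytically by linear path tracing where the model is
linear-Gaussian throughout, and by Monte Carlo contrasts otherwise (an
arrow out of $S$ breaks path-product linearity, so `analytic_effects()`
refuses those models and `mc_effects()` is used).

### Default parameters

The source analysis is qualitative; no equations or coefficients are given
there. The defaults below were fixed once, at design time, to be realistic
for the setting and to make the qualitative distinctions decisively
measurable at the default simulation budget:

| parameter | default | reading |
|---|---|---|
| $p_E$ | 0.5 | two origin populations equally represented in the full population |
| $E \to D$ | 0.3 | direct effect = CDE at $m = 0$ |
| $E \to R_0$ | 0.5 | pre-existing national difference in the risk factor |
| $R_0 \to R$ | 1.0 | $R$ is a noisy measurement of $R_0$ (noise SD 1) |
| $R \to D$ | 0.4 | risk factor affects the outcome; total effect $= 0.3 + 0.5 \cdot 1 \cdot 0.4 = 0.5$ |
| $S$: intercept 2.0, $E \to S$ $-2.5$, $R_0 \to S$ $-1.5$ | | a majority receiving country (selection probability $\approx 0.88$ at $E = 0, R_0 = 0$) and a minority immigrant subsample ($\approx 0.38$ at $E = 1$), with selection on the risk factor |
| $C \to R_0$, $C \to D$ | 0.5 each | mediator--outcome confounding |
| $S \to R$ | 0.5 | post-migration change in the risk factor (variant only) |
| noise SD | 1 | standard-normal disturbances on all continuous nodes |

On the confounder's target: the selection-only model places the arrow as
$C \to R_0$ (with $C \to D$), not $C \to R$. Only then does adjusting for
an exact copy of $R_0$ close the confounding path -- which is precisely the
time-constant argument the attenuation experiment quantifies.

The **time-constant** variant (`make_model("fig1d", time_constant = TRUE)`,
the "$R_0 = R$" case such as sex) merges the pre- and post-migration nodes
into a single measured node $R$. A two-node rendering with a deterministic
unit link would violate faithfulness -- conditioning on $R$ *is*
conditioning on $R_0$, which the strict graph rules cannot see -- so the
merged node is the representation under which graphical and numerical
verdicts coincide. The two-node construction remains available through
coefficient overrides (`"R0->R" = 1`, `"sd:R" = 0`) and is what the
attenuation experiment uses at the zero-noise end of its grid.

The effect scale is the mean difference, which is collapsible; odds-ratio
non-collapsibility would otherwise masquerade as a verdict difference. A
logistic estimator (`fit_adjusted_odds_ratio()`) exists for completeness
and flags itself as non-collapsible.

## Estimators and the verdict rule

`replicate_bias()` simulates `replicates` cohorts, applies one strategy to
each selected sample -- `none`, `adjust:R[,C]` (least squares of $D$ on $E$
plus the set), or `ipw` (weights $1/p$ from a logistic selection model fit
on the full population, weighted unadjusted fit, robust sandwich standard
errors) -- and compares the mean estimate against both truths. The
pre-registered rule: the strategy *recovers* a truth when the mean lies
within 3 combined Monte Carlo standard errors of it while the other truth
is excluded at the same criterion; *biased* when both are excluded; when
the truths coincide (no mediation) ties resolve to `recovers_total`. When
the truth itself is Monte Carlo, its standard error enters the combined
tolerance, so truth noise cannot manufacture exclusions. The default
budget, 20 replicates of $n = 200{,}000$, separates 0.3 from 0.5 by a wide
margin (the mean estimate's Monte Carlo SE is of order $10^{-3}$) and keeps
every pre-built experiment comfortably within a few minutes on one core.

The IPW estimand deserves a note. Weighting by inverse selection
probabilities estimated from pre-migration variables restores the
population distribution of those variables; it cannot undo a causal effect
of membership itself. Under the post-migration variant ($S \to R$) the
weighted estimator therefore recovers the total effect *with $S$ held at
1*, not the population total including the $S$-mediated path. Rather than
label a cell with an estimand outside the framework's scope, the grid
masks IPW for models with an arrow out of $S$ (recorded as `skipped`),
alongside the models where no risk factor enters selection and IPW has
nothing to correct. For the models where IPW applies, its classifier
verdict is computed with $S$ unconditioned and an empty adjustment set --
the graph-surgery reading of what weighting does.

The weighted-unadjusted choice of outcome model for IPW (rather than
weighted-adjusted) is the package's own: the target of IPW here is the
total effect, so the mediating risk factor must stay out of the outcome
model.

## The experiments

* `run_effect_grid()` -- six models (combined mediator/selection, the same
  with a confounder, selection-only time-constant, mediator-only, neither,
  and the post-migration variant) crossed with the applicable strategies;
  every applicable cell must be concordant between classifier and
  simulation.
* `preeclampsia_example()` -- the refugee/preeclampsia reconstruction:
  three risk-factor pairs, all combined mediators/selection factors;
  adjusting for everything but SES leaves a selection path open
  (`BIASED`), adding SES yields a `CONTROLLED_DIRECT`; adding the
  $S \to \mathrm{SES}$ and $\mathrm{SES} \to \mathrm{age}$ arrows changes
  neither verdict. Arrows among the pre-migration factors beyond those
  named are omitted, the four "other" covariates are merged into single
  nodes, and each pre-migration factor receives an arrow from $E$, per the
  pre-migration-risk-factor reading.
* `attenuation_study()` -- the selection-only model with confounder, $R$
  adjusted and $C$ omitted, across measurement-noise SDs
  $\{0, 0.1, 0.25, 0.5, 1\}$. Every noise level reuses the same replicate
  seeds (common random numbers) and the noise draw is made even at SD 0,
  so the bias curve is compared on shared randomness; the monotonicity
  flag tolerates a per-pair decrease of two combined standard errors. At
  noise 0 the bias is statistically zero; it grows with the noise.
* `interaction_study()` -- an $E \times R$ interaction (coefficient 0.2)
  in the outcome equation; the fit including the product term recovers the
  analytic CDE at the reference mediator value, the fit omitting it is
  biased. With an interaction present the CDE varies with $m$:
  $\mathrm{CDE}(m) = 0.3 + 0.2\,m$ under the defaults.

## Numerical and reproducibility choices

* One master integer seed drives everything; replicate $r$ uses the $r$-th
  draw of `sample.int(2^31 - 2)` under `set.seed(master)`
  (`derive_seeds()`), so runs are independent, reproducible, and
  restartable. `simulate_cohort()` restores the caller's RNG state.
* Monte Carlo do-contrasts pair their two arms on a shared seed, so in
  fully linear models the paired difference is exact and the reported
  standard error collapses accordingly.
* Path enumeration is ordered lexicographically by node sequence;
  topological order breaks ties lexicographically; CSV output formats
  doubles with fixed precision -- identical configurations produce
  byte-identical outputs.
* Degenerate inputs are rejected loudly: cycles (with a witness), duplicate
  edges, adjustment sets containing unmeasured nodes or the
  exposure/outcome, zero-variance design columns, perfect separation in
  logistic fits, selection probabilities below a positivity floor
  ($10^{-6}$), and selected-view statistics after a do-intervention on $S$.

## What the simulations do and do not show

The generator emulates the qualitative structure of selection-sampled
comparisons: pre-existing differences, selection on risk factors and
exposure, measurement of risk factors post-selection, mediator--outcome
confounding, and post-selection change. It is linear-Gaussian with a
logistic selection link. Passing tests therefore demonstrate that the
classifier's verdicts are the correct *estimand labels* under these
structures -- not that real immigrant datasets are linear, homoscedastic,
or free of time-varying confounding, survival outcomes, effect
heterogeneity beyond a single product term, or misclassified exposure.
Natural direct and indirect effects are out of scope, as is any search for
minimal sufficient adjustment sets: the package evaluates the adjustment
sets users supply, which is how the applied literature actually proceeds.
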