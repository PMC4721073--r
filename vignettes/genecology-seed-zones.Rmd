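---
title: "Methods: variance decomposition and seed-zone delineation from common-garden trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance decomposition and seed-zone delineation from common-garden trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecol)
```

## The problem

Seed transfer in reforestation is governed by seed zones: geographic units
within which planting stock is assumed to be adequately adapted. Delineating
them requires knowing how much phenotypic variance in adaptive traits lies
*among* tree populations, and how that among-population variation is
structured by the climate and ecology of the seed sources. `genecol`
implements that analysis for controlled common-garden trials, in which bulk
seedlots from hundreds of natural populations are grown together in
growth-chamber environments programmed to emulate a latitudinal temperature
gradient, so that trait differences between seedlots are genetic.

Five traits are carried through the pipeline: height (cm) and root-collar
diameter (mm) after two growing seasons, budbreak and budset as
day-of-season of first observation, and freeze injury (%) from
electrolyte-leakage tests.

## Freeze-injury index

For a sample frozen at test temperature $t$, conductance of the leachate is
measured after freezing ($L_t$) and after heat-killing the same sample
($L_k$); an unfrozen control from the same measurement batch supplies $L_0$
and $L_d$. The index of injury is

$$I_t = 100\,\frac{R_t - R_0}{1 - R_0},\qquad R_t = L_t/L_k,\quad R_0 = L_0/L_d .$$

$I_t$ is 0 when the frozen sample leaks no more than the control and 100 at
full kill, and is invariant to rescaling all four conductances by a common
factor (a meter-calibration property the tests verify). Noisy controls can
produce slightly negative raw values; `injury_index()` retains the raw value
and by default clamps the reported index to $[0, 100]$, since the index is
defined as a percentage of cell damage.

Freeze tests are run at three temperatures chosen to give intermediate
damage. Only the two treatments with mean injury closest to 50% across
populations enter the cold-hardiness summary — that is where populations are
maximally differentiated, and a third treatment adds little. Ties are broken
toward the colder temperature. The summary itself is a least-squares mean
per population and chamber from the additive fixed-effects model
`injury ~ population + treatment`, the minimal model consistent with
"least-squares means of the two freeze treatments": with balanced data it
reduces to the simple mean, and a population missing one treatment is
adjusted by the grand treatment contrast. Block effects are not included in
this summary; the chamber-level design terms are handled by the variance
decomposition instead.

## Variance decomposition and $V_{pop}$

Each trait is analysed under the all-random nested model

$$Y_{ijkl} = \mu + P_i + E_j + (P \times E)_{ij} + B(E)_{jk} + L(B)_{kl} + e_{ijkl},$$

with populations $P$, chamber environments $E$ (the drought chamber is
simply a fourth environment level), their interaction, incomplete blocks
nested in chambers, seedling positions nested in blocks, and residual.
Chambers are not replicated treatments, which is why the environment is
treated as random and its variance carries a very large standard error (it
has only four levels).

Estimation is REML. The fit itself is delegated to `lme4`; the package then
evaluates its own restricted-likelihood machinery (a sparse Woodbury form of
the deviance and its exact analytic gradient) to (a) polish the optimum —
the REML criterion is extremely flat near the solution, and a bounded
quasi-Newton step with the analytic gradient pins the estimates to the
balanced-ANOVA closed form to $10^{-6}$ on balanced designs — and (b) obtain
standard errors from the inverse curvature (observed information) of the
deviance in the variance parameterization, the asymptotic Wald convention of
mixed-model software. Numerical choices that matter:

* Negative components are handled by the optimizer's nonnegativity bound;
  estimates at the boundary are flagged `pinned`, and their SEs are still
  reported, computed just inside the boundary (variance tables convention-
  ally print SEs even for 0.0 estimates).
* The information matrix is differentiated with scale-aware central
  differences (5% relative steps): each deviance evaluation carries sparse-
  Cholesky rounding noise, so tiny steps would measure noise rather than
  curvature in flat directions such as the environment component.
* A term with fewer than two levels is dropped with a warning. The
  position-in-block term is dropped when no position holds replicate
  observations, because a single seedling per position makes $\sigma^2_L$
  inseparable from $\sigma^2_e$ for a single trait.
* Components are also expressed as percent of the summed components; SEs
  are divided by the same total, i.e. the total is treated as fixed. This
  matches how such tables are conventionally printed and is an
  approximation (the total is itself estimated).

Among-population differentiation is

$$V_{pop} = \frac{\sigma^2_P}{\sigma^2_P + \sigma^2_e},$$

a downward-biased stand-in for $Q_{ST}$: the denominator uses the residual
variance rather than twice the additive genetic variance, which cannot be
estimated from bulk seedlots without pedigree. Its standard error follows
the standard propagation rules for a sum and a ratio,

$$SE_{P+e} = \sqrt{SE_P^2 + SE_e^2},\qquad
SE_{V_{pop}} = V_{pop}\sqrt{\left(\frac{SE_P}{\sigma^2_P}\right)^2 +
\left(\frac{SE_{P+e}}{\sigma^2_P + \sigma^2_e}\right)^2}.$$

`anova_components()` provides the balanced expected-mean-squares estimator
(one-way and crossed two-way) purely as an independent cross-check; it is
the oracle against which the REML path is tested.

## Trait matrix

The regression-tree response is built from population means per chamber:
normalized per chamber-by-trait column to standard-deviation units from the
chamber mean (sample $n-1$ convention — the population means are a sample of
provenances), imputed, and pooled. Imputation fills a missing cell with the
mean of that column over the $k$ nearest populations (default $k = 5$),
where distance is the root-mean-square difference over shared observed
columns; a column-mean fallback is available. This transparent k-nearest-row
scheme stands in for published imputation procedures whose details are not
reproducible from the trial description; it never alters observed cells.

Pooling across chambers (then re-standardizing each trait column) is the
default response because population-by-environment interaction is weak
relative to the population main effect in these trials; a per-chamber
20-column analysis is available by simply not pooling. Both modes are
provided because published analyses are ambiguous about which was used.

## Multivariate regression tree

The MRT is authored from scratch (it is the analytical core, and no
multivariate tree implementation is assumed). It greedily partitions the
population × trait matrix by external predictors, choosing at each step the
split that maximizes

$$\Delta SS = SS_{parent} - SS_{left} - SS_{right},$$

where $SS$ is the multivariate sum of squared Euclidean distances to the
node centroid. Numeric predictors (climate normals) are split at every
midpoint between consecutive distinct values; categorical predictors
(ecosystem variants, ecozones) by binary level subsets — exhaustively up to
12 levels ($2^{m-1}-1$ partitions), and above that by ordering levels along
the first principal axis of their mean responses and scanning contiguous
partitions, the classic ordered-levels heuristic (tests show it finds the
exhaustive optimum in ≥95% of random 8-level fixtures).

Determinism is enforced by explicit tie-breaking: numeric ties take the
smaller threshold, categorical ties the lexicographically smallest left
set. Growth is best-first — the frontier leaf with the largest admissible
reduction is expanded next — so trees of all intermediate sizes are nested
and `prune_to_leaves()` (keep the growth-order prefix) is well defined and
inverse to regrowing. Defaults: `min_leaf = 2` (an ecosystem is typically
represented by only a few seedlots), `min_improvement_fraction = 0.01` of
the total SS. Missing predictor values are rejected rather than handled by
surrogate splits: climate characterizations of seed sources are complete by
construction, and the response matrix is imputed upstream.

Tree size can be fixed (the reproduction mode — published trees are shown at
fixed sizes) or chosen by repeated k-fold cross-validation of the relative
held-out error (held-out SS to the assigned training-leaf centroid, divided
by total SS), with both the minimum-error and 1-SE sizes reported. On pure
noise the CV error stays at or above 1 for every size beyond the root, so
the procedure does not invent structure.

Leaf profiles are the leaf centroids in SD units; with the centered pooled
response their size-weighted mean is the zero vector, so bars in a profile
chart read as deviations from the overall mean.

## Seed-zone groups and reports

`assign_groups()` routes every population to a leaf and maps each ecosystem
variant to a group by majority of its populations (ties to the larger group);
variants split across leaves are resolved by majority and logged rather than
hidden, since zone tables list whole variants per group. A categorical level
never seen at a node routes to the child with more training populations.
Partitions from alternative predictor sets (climate vs ecozone vs variant)
are compared with the adjusted Rand index — a quantitative stand-in for the
qualitative claim that different predictor sets give similar zonations.
`render_report()` writes all tables as CSV and the tree as text and JSON;
output is deterministic, so regenerated reports are byte-identical.

## The synthetic generator

`generate_origins()` + `generate_design()` + `simulate_observations()`
emulate the trial that motivates the package: 254 (spruce-like) or 281
(pine-like) seedlots, 4 chamber environments × 8 incomplete blocks × 90
seedlings (2880 per species; 2–4 replicates per seedlot per chamber, mean
2.8 at 254 seedlots), and five traits generated additively under the nested
model above. Design constants and per-trait variance magnitudes default to
the published interior-spruce and lodgepole-pine tables (percent columns
read as trait-unit² magnitudes; only ratios matter downstream since the
analyses normalize). Choices worth recording:

* The original trials used a resolvable $\alpha$-design; the generator uses
  a randomized incomplete-block allocator with floor/ceiling-even
  replication. Downstream models treat block as an unstructured random
  label, so the co-occurrence balance of a true $\alpha$-design is
  irrelevant to everything tested here.
* Group climate structure: each of the `n_groups` planted groups draws its
  climate normals from its own multivariate distribution along a
  cold-continental → warm-valley gradient, with offsets constructed so the
  ordering MCMT ≤ MAT ≤ MWMT, TD = MWMT − MCMT, MSP ≤ MAP and nonnegative
  degree-days hold by construction. `group_separation` scales the spread of
  the group centers; 1 resembles a provincial gradient, larger values give
  cleanly separable groups for recovery tests.
* Population effects decompose into a between-group trait profile (85% of
  $\sigma^2_P$), a within-group slope on MAT (5%), and an independent
  seedlot draw (10%). The profiles encode the classic adaptive syndromes
  (boreal: hardy, early budbreak, late budset; montane: slow-growing, late
  budbreak, early budset; valley: fast-growing, high injury; maritime:
  very late budbreak). The 85/5/10 split reflects that in such trials most
  among-population variance is structured by source environment; it is a
  fixed generator property, not a tuning knob.
* The budset position-in-block magnitude is 0 in the published table, so
  the confounding of position with residual (one seedling per position)
  does not affect recovery tests on budset.
* Freeze tests: each seedling's latent injury follows a logistic curve in
  temperature, midpoint −13 °C for an average seedling (shifted 0.1 °C per
  unit of its cold-injury phenotype), width 2 °C. Any monotone sigmoid
  would do — the choice is logistic for invertibility. Emitted conductances
  use fixed controls ($L_0 = 10$, $L_d = 50$ µS, so $R_0 = 0.2$) and
  $L_k = 60$ µS; at `noise = 0` the injury index returns the latent injury
  exactly, making the generator → index round trip an identity that is
  tested.

What the generator does **not** emulate: spatial autocorrelation within
chambers, measurement censoring of phenology intervals, chamber programming
details, true $\alpha$-design co-occurrence balance, or real geographic
climate surfaces. Passing recovery tests therefore demonstrate correctness
of the estimators under the stated generative model, not robustness to
these real-data features.

## Problem sizes and verification

The test suite verifies, among others: the injury-index identities and the
round trip; REML = balanced-ANOVA to $10^{-6}$ and the closed-form sampling
variance of the one-way estimator; shift/scale equivariance; recovery of
$V_{pop} = 0.193$ (budset magnitudes) within 0.02 as the mean of 100
simulated trials at the full design (2880 observations, 254 populations);
split-search optimality against brute-force enumeration on all small
fixtures; SS conservation at every node to $10^{-9}$; node-for-node
equality with an independent greedy univariate tree; and ≥90% mean recovery
of five planted groups by the size-5 climate tree over 20 full-scale
simulated trials. These sizes were chosen as the smallest designs that are
faithful to the trial structure being emulated.

## Known limitations

* $V_{pop}$ underestimates $Q_{ST}$; without pedigree the additive variance
  is not estimable, and no heritability or significance testing on
  components is attempted.
* Percent-scale SEs treat the variance total as fixed.
* The environment component rests on four levels; its estimate and SE are
  both unstable by design of the trial, not of the software.
* The categorical split heuristic above 12 levels is not guaranteed optimal.
* Group counts reported for the real trials depend on the archived field
  data; on synthetic data the leaf count is a parameter, and the package
  makes no claim about reproducing specific published group counts or the
  published climate-tree variance fraction.
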