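---
title: "Methods: uncertainty and global sensitivity analysis of the PAO cycle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty and global sensitivity analysis of the PAO cycle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paosens` implements a complete uncertainty-propagation and variance-based
sensitivity pipeline around a mechanistic model of *Accumulibacter* PAO
metabolism over one anaerobic–aerobic EBPR cycle. This vignette records the
model, its assumptions, the tunable parameters, the numerical choices, and
the design decisions taken where the formulation was genuinely open — in
enough detail that a maintainer can judge what a given result does and does
not show.

## The cycle model

Ten components are tracked: dissolved O₂, acetate (S_HAc), propionate
(S_HPr), orthophosphate (S_PO4) in the bulk liquid, PAO biomass (X_PAO),
the three PHA constituents (X_PHB, X_PHV, X_PH2MV), glycogen (X_Gly) and
poly-phosphate (X_PP). All concentrations are carbon- (or phosphorus-)
molar, C-mmol/l or P-mmol/l, so elemental bookkeeping is linear; an
auxiliary CO₂ pool closes the carbon balance and is carried as an eleventh
state used only for balance checks.

Ten kinetic processes drive the cycle:

* **Anaerobic VFA uptake** (two processes, acetate and propionate):
  Monod in the dissolved VFA, saturating in the intra-cellular glycogen and
  poly-P *fractions* (reserves per biomass), proportional to biomass.
  Per C-mol VFA taken up, glycogen is consumed, PHA is formed (split among
  PHB/PHV/PH₂MV with a carbon-source-specific split: acetate mostly to PHB,
  propionate mostly to PHV/PH₂MV), CO₂ closes carbon, and phosphate is
  released 1:1 from poly-P hydrolysis to pay the ATP bill.
* **Anaerobic maintenance** (two processes): sequential — poly-P hydrolysis
  first; once poly-P is depleted, glycolysis of glycogen to PHB supplies
  maintenance ATP. The ordering is a design decision (poly-P first), chosen
  because poly-P hydrolysis is the cheaper ATP source in this formulation.
* **Aerobic PHA degradation, glycogen formation, poly-P formation,
  maintenance** (four processes, plus growth): PHA degradation saturates in
  the PHA fraction and oxygen; glycogen and poly-P formation are inhibited
  as their per-biomass fractions approach `f_Gly_max` / `f_PP_max` (hard
  caps: the rate reaches exactly zero at the cap); aerobic maintenance is
  sequential on PHA, then glycogen, then poly-P. **Growth** is the
  PHA-degradation surplus after replenishment and maintenance demands,
  converted to biomass with a yield `1 / (1 + K_eff / (1.125·δ))`, where
  `K_eff` interpolates the ATP cost of biomass synthesis between the
  acetyl-CoA (K₁) and propionyl-CoA (K₂) routes according to the current
  PHA composition, and `1.125·δ` is the ATP recovered per C-mol PHA
  oxidized (degree of reduction 4.5 electrons per C, δ ATP per NADH₂).

The pH affects the ATP cost of transporting VFA across the membrane
linearly (`0.16·pH − 0.7945` ATP per C-mol), and hence the phosphorus
release per C-mol VFA; for propionate the glycogen demand also shifts
weakly with pH, while the acetate glycogen stoichiometry is
pH-independent. Temperature acts on every kinetic rate through Arrhenius
corrections `k(T) = k(20 °C)·θ^(T−20)`.

Phase structure: 2.5 h anaerobic then 2.5 h aerobic. Anaerobically there
is no growth, so biomass is constant by construction. At the phase switch
the aerobic VFA gate closes whenever acetate + propionate has not been
depleted (threshold 10⁻³ C-mmol/l — Monod depletion is asymptotic, so a
strict zero test would never fire); residual VFA is then simply not
consumed aerobically, keeping the aerobic outputs untangled from carbon
co-uptake. Oxygen follows a saturating supply term
(`kLa = 10 h⁻¹` toward 0.25 mmol/l) because the formulation targets
controlled, non-limiting aeration; K_O2 still gates every aerobic rate so
oxygen-limited corners behave sensibly.

Stoichiometric constants live in `inst/extdata/pao_model.yaml`. They are
package-curated values in the style of the classical acetate/propionate
PAO model family, *not* transcriptions of a single source; the loader
enforces carbon closure of every process column and positivity of every
pH-resolved yield over pH 6–7.5, so edits cannot silently break the
balances. The same holds for the measurement collections in
`inst/extdata/pao_parameters.yaml`: they are synthetic literature-emulation
data whose counts and dispersion are patterned on the published record
(e.g. 33 and 90 values for the data-rich uptake and poly-P formation
rates, single point values for K₂ and K_HPr, single pooled values for the
Arrhenius coefficients so they sit in the 50 % variability tier).

## Input uncertainty characterization

For each record the variability is 50 %, 25 % or 5 % for 1, ≤ 10, or > 10
measurements; the uniform sampling range is
`a = min((1 − var)·x̄, x_min)`, `b = max((1 + var)·x̄, x_max)`, so the
range always covers the observed extremes. A zero-variance collection
falls back to the single-measurement rule around the common value
(preserving a sampleable interval). Records with more than 50 points are
fitted to an Erlang distribution by the method of moments
(`k = round(x̄²/s²)` clamped to ≥ 1, `λ = k/x̄`, so the fitted mean equals
the sample mean exactly); Erlang records are sampled untruncated through
the Gamma inverse CDF. Temperature (10–30 °C) and pH (6–7.5) are design
variables with fixed bounds.

The three PHA constituent fractions are sampled as Dirichlet(1, 1, 1)
weights — the maximum-entropy default on the simplex, since nothing pins
the concentration parameters — by pushing three unit-hypercube columns
through Gamma inverse CDFs and normalizing, then multiplying by the
sampled total PHA fraction. This keeps the design a pure column-wise
transform, so each weight keeps its own quasi-random dimension and Sobol
attribution per weight is well defined. Because the three coupled columns
sum exactly to the total, an OLS design on the physical columns would be
singular; `transform_design()` therefore also returns `analysis_values`,
in which the weight columns keep their independent Gamma coordinates —
regressions use that matrix, the simulator uses the physical one.

## Sampling and propagation

The Saltelli scheme generates `A`, `B` and `A_B^(i)` blocks from a
`2M`-dimensional digital Sobol' sequence, `N·(M+2)` rows total; the
first+total-order variant only (no second-order cross blocks). The Sobol'
generator is built in-package: primitive polynomials over GF(2) found by
deterministic search, odd initial direction numbers drawn from fixed
Mersenne-Twister streams, and a deterministic greedy selection that keeps
pairwise column correlations below ~0.15 on 512- and 1024-point prefixes
(a pragmatic stand-in for hand-optimized direction-number tables). A
half-ulp digital shift keeps all coordinates strictly inside (0, 1).
Scrambling, when requested, is a seeded per-dimension digital (XOR) shift;
it is off by default so designs are bit-reproducible.

Each parameter vector is resolved (Arrhenius corrections for its T,
pH-dependent yields, initial state from the influent descriptors and
per-biomass fractions multiplied by the initial biomass) and integrated
with a compiled right-hand side under `lsoda` (rtol 10⁻⁶, atol 10⁻⁹) on a
301-point grid (1-minute resolution, which resolves the fast anaerobic
uptake transient). Rate laws clamp negative states internally; reported
concentrations are clamped at zero, and an excursion below 10⁻⁶ aborts
that row with the offending parameters attached. The sampled space
contains genuinely hostile corners — θ^(T−20) spans roughly 0.003–150× —
and where lsoda's dense output fails the row is retried deterministically
with `vode`; residual failures (~10⁻⁴ of rows) are recorded and their
whole (A, B, A_B) tuple is dropped from estimation, which keeps the
Saltelli estimators valid. Trajectories reduce to cycle means by the
trapezoidal rule on the shared grid (the t = 0 initial value is included,
with half weight, as trapezoid implies).

## Sensitivity estimators

Standardized regression coefficients come from one OLS fit per output;
`β = b·σₓ/σ_y`, with R² per output and the conventional R² ≥ 0.7
trustworthiness flag. Constant outputs get R² = 0 with a logged message;
rank-deficient designs are an error naming the collinear columns.

First-order indices use the Saltelli estimator
`S_i = mean(y_B·(y_{AB_i} − y_A))/Var(Y)` and total-order indices the
Jansen estimator `ST_i = mean((y_A − y_{AB_i})²)/(2·Var(Y))`, with
`Var(Y)` on the pooled A∪B sample. Outputs are mean-centred first — the
expectation is unchanged, but without centring the S₁ numerator for
low-variation outputs (e.g. biomass, CV ≈ 7 %) is a difference of large
products and both the estimate and its bootstrap interval degrade badly.
Negative S₁ estimates (possible at finite N) are reported raw and clamped
at zero only for normalization and ranking. Bootstrap intervals resample
base-sample indices with whole (A, B, A_B) tuples intact (default 1,000
resamples, 95 % percentile intervals, seeded). Normalized total effects
rescale each output's ST to sum to one; rankings are per output and per
parameter group, ties broken by database order; display cut-offs (0.05
first-order, 0.3 total-order) flag rather than drop entries.

Estimator validation is independent of the metabolic model: an analytic
oracle (in `analytic_models()`, deliberately separate from the estimator
code) supplies a linear model (β² = S₁ = STᵢ, ΣS₁ = R² = 1), the Ishigami
benchmark (S₁ = 0.3139/0.4424/0, ST₃ = 0.2437 at the standard constants
a = 7, b = 0.1) and a dummy-input null; the test suite recovers all of
them within 0.02 at N = 2¹⁴.

## What the synthetic conditions do and do not show

The default database *is* the study condition of the package: it fixes
what the measurement collections look like, and therefore how wide every
input's range is. Two consequences deserve honesty:

* Under these defaults the cycle means of the storage pools, biomass and
  phosphate inherit their sampled initial conditions almost additively
  (cycle-mean biomass ≈ X_PAO_i·(1 + growth); mean phosphate carries
  r_P/C·S_VFA directly). The package's own end-to-end measurements reflect
  that: the per-output R² of the cycle-mean regressions reaches ≈ 0.8 and
  the largest first-order index (initial biomass → biomass) is ≈ 0.7.
  Variance in these outputs is therefore *first-order dominated* here. The
  interaction-dominated regime — all R² near zero, first-order indices
  uniformly small, total-order effects large — emerges only when
  initial-condition uncertainty is much tighter than kinetic/temperature
  uncertainty, so that regime-switching (VFA depletion, poly-P crashes,
  storage caps, the exponential temperature law) supplies most of the
  output variance. Users emulating a tightly instrumented reactor should
  shrink the initial-condition collections accordingly; the rest of the
  pipeline is unchanged.
* The measurement collections are synthetic. They reproduce the *structure*
  of literature abundance (tiers, one Erlang-qualified record, point values
  for poorly measured constants), not any specific survey; rankings
  computed on the defaults characterize this package's default model, not
  any published reactor.

Passing tests therefore demonstrate correctness of the machinery
(estimators against analytic truth, elemental closure, determinism,
sequencing and gating of the physics) — they do not certify the default
input ranges as a faithful reconstruction of any particular plant or
study.

## Problem sizes and runtime

The shipped analyses use deliberately moderate sizes: 4,096 quasi-random
simulations for the regression diagnostic, a 512-base-sample Saltelli
design (20,992 simulations) for the index estimates, 500–1,000 bootstrap
resamples, and 2¹⁴ evaluations for the analytic benchmarks. One cycle
solves in ~3 ms through the compiled right-hand side, so the full test
suite runs in about a minute and `scripts/acceptance.R` in under one
minute on a single CPU. Larger designs scale linearly.

## Known limitations

No anoxic phase, no GAO competitors or PAO clade structure, no multi-cycle
SRT/HRT dynamics, and no duress metabolism (PO₄-starved glycogen
accumulation, TCA-supplemented reducing power): the model covers one
anaerobic–aerobic cycle of a healthy *Accumulibacter* enrichment.
Temperature and pH are constant within a cycle. The aeration description
is a fixed saturating supply, not a controller. Second-order Sobol
indices, FAST/RBD-FAST and density-based measures are out of scope, as are
regression variants beyond OLS (the randomized sampling keeps collinearity
low and N ≫ M, which is the regime where OLS is the fit-for-purpose
choice).
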