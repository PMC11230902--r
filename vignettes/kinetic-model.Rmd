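---
title: "The two-stage resolution–coupling model behind stereoretentive enantioconvergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-stage resolution–coupling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereokin)
```

## The model

`stereokin` models a multicomponent enantioconvergent process as two
sequential bimolecular stages on nine species:

1. **Kinetic resolution.** The racemic substrate A (pools A_S, A_R) reacts
   with an unsymmetrical linker L to give the linker-bearing intermediate I:
   A_S + L → I_S at rate constant *k*₁S and A_R + L → I_R at *k*₁R, with
   selectivity factor *s* = *k*₁S/*k*₁R ≥ 1. Both reactions are simple
   second order (first order in each reactant).
2. **Coupling.** The intermediate couples with the unreacted substrate:
   opposite configurations give the heterochiral product (I_S + A_R → P_SR,
   I_R + A_S → P_RS, rate constant *k*₂-hetero), like configurations the
   homochiral one (P_SS, P_RR, *k*₂-homo).

Three assumptions reduce this to closed forms: (1) simple second-order
kinetics in both stages; (2) the coupling is much slower than the
resolution, so the stages are sequential; (3) no asymmetric induction in
the coupling, *k*₂-hetero = *k*₂-homo. Under (1) the resolution obeys
d ln A_S / d ln A_R = *s* regardless of the linker profile, which
integrates to the Kagan relations between conversion *C* and the pool
e.e.s (see `ee_product_at_conversion()`, `ee_substrate_at_conversion()`),
with the mass balance ee_s(1 − *C*) = ee_p·*C*. Under (3) each pool's
composition is invariant during coupling — consumption is proportional to
composition — so the coupling is *exactly* time-independent random
pairing, giving heterochiral e.e. (a + b)/(1 + ab) and d.r.
(1 + ab)/(1 − ab) for pool e.e.s a, b. No integration is needed for the
statistical stage; all time dependence lives in the ODE module, which is
also the only route when assumptions (2) or (3) are dropped.

With the default stoichiometry L0 = A0/2 the resolution stalls at exactly
50% conversion, where both pools carry equal e.e. — the configuration the
closed-form pipeline assumes. At *s* = 8 this gives a 62% e.e.
intermediate but a 90% e.e. final product; the amplification is why the
selectivity demands on the resolution are low.

```{r headline}
e <- ee_product_at_conversion(8, 0.5)
c(intermediate = e, final = coupled_ee(e, e))
```

## Orientation conventions

Positive e.e. means S-enrichment and the fast-reacting enantiomer is S, so
*s* ≥ 1 always; inputs with *s* < 1 are rejected rather than silently
mirrored (`mirror_pool()` flips labels explicitly). A resolution therefore
leaves an S-enriched intermediate and an R-enriched substrate pool, and the
heterochiral S,R-product inherits both majorities — the sign conventions
that make (a + b)/(1 + ab) come out positive. The mirror-symmetry property
(S↔R relabelling negates every e.e., preserves every d.r.) is enforced by
property tests; it is the guard rail against sign bugs.

## Parameters that matter

- **`s`** (dimensionless, ≥ 1): the only parameter of the closed-form
  pipeline. Common benchmarks: < 15 low, 15–30 acceptable, 30–50 good.
- **`separation_factor`** = *k*₁R/*k*₂ (default 1e3): realizes "coupling
  much slower than resolution". The inequality is a regime, not a number;
  1e3 makes the full network match the sequential pipeline to ~1e-4 in
  final e.e. (the residual scales as 1/separation), which is well inside
  the two significant figures at which such predictions are quoted.
- **`induction_ratio`** = *k*₂-hetero/*k*₂-homo (default 1): values ≠ 1
  model asymmetric induction in the coupling step and move d.r. and e.e.
  away from the statistical prediction.
- **`A0`, `L0`, `ee0`**: normalized initial amounts (A0 = 2, L0 = A0/2,
  racemic start). All outputs are ratios, so physical units are out of
  scope.

## Numerical choices

The Kagan relations are solved by bracketed root finding (`uniroot`,
tolerance 1e-10) on ee ∈ [0, min(1, 1/C − 1) − δ], δ = 1e-12; the
objective is strictly monotone so the root is unique. At extreme *s* the
root approaches the feasibility edge closer than machine precision; the
edge value (the perfect-resolution limit) is then returned. The inverse
relation `s_from_observation()` round-trips to 1e-6 relative except where
1 − C(1 + ee) underflows double precision (large *s* with high conversion),
which is a representation limit, not a solver one.

The ODE network is integrated with `deSolve::ode(method = "lsodar")` at
rtol 1e-10 / atol 1e-12 — the separated-timescale regime spans three or
more decades of rate, and the predictions must not be solver-limited.
Run-to-completion stops, via the solver's root finder, when every reaction
rate falls below 1e-10 of the fastest initial rate, with a hard time cap
(warning on cap hit). Sampling "the state at 50% conversion" is done
either by terminating exactly at the crossing of A_S + A_R through A0/2
(solver root location, preferred) or by monotone interpolation of a dense
trajectory (`state_at_conversion()`). Substrate-unit and linker-unit
conservation hold along every trajectory to better than 1e-8 relative.

The stochastic oracle is an exact Gillespie direct-method simulation of
the same six reactions in integer molecule counts (compiled code; R's RNG,
so one `set.seed` fixes a run bit-for-bit). It is the independent check on
the deterministic solution: over replicates the mean final e.e. converges
to the deterministic value as molecule numbers grow. Conservation is exact
in counts.

## The synthetic measurement generator

`generate_kr_measurements()` emulates what a bench determination of *s*
produces: (conversion, e.e.) pairs that sit exactly on the closed-form
relation for `s_true`, plus additive Gaussian noise on the e.e. —
absolute, because e.e. is what chiral HPLC reports — clipped to [0, 1)
with clipping flagged per observation (clipped points are excluded from
fits by default, since their error is no longer Gaussian). One explicit
seed per set; no global RNG state is consumed. `fit_s()` inverts the
relation by least squares on log10 *s* with a curvature-based standard
error; on 200 synthetic sets at `s_true = 8`, noise 0.01 and nine
conversions the median recovers *s* within 5% and ±2 se covers the truth
in ≥ 90% of sets (these sizes keep the whole recovery experiment under a
couple of minutes and are already deep into the asymptotic regime).

What the generator does *not* emulate: conversion measurement error,
systematic HPLC integration bias, reversibility, or catalyst deactivation.
Passing recovery tests therefore show the estimator is correct *under the
model*, not that real determinations carry these error bars.

## Scenario registry and the feasibility diagnostic

`paper_scenarios()` preconfigures the scenarios the package analyses
(keyed `fig3a`–`fig5_mismatched`), each carrying observed experimental
summaries as reference values. Observed-vs-predicted comparisons are
reported as discrepancy ratios, never asserted as equalities — more
complex kinetics or induction in the coupling step can shift stereoisomer
ratios away from the statistical prediction, and that caveat is precisely
what the diagnostic `infer_pool_ees()` quantifies. It inverts the
statistical closed forms: an observed d.r. R fixes ab = (R − 1)/(R + 1),
the observed d.e. fixes a + b = d.e.(1 + ab), and a negative discriminant
of the resulting quadratic proves *no* pool pair can explain the
observation statistically. The AM–GM bound makes this intuitive: given ab,
the d.e. cannot fall below 2√(ab)/(1 + ab). Both chiral-linker scenarios
(d.r. 3.2:1 at 93% d.e.; 1.4:1 at 66% d.e.) fail exactly this bound —
their d.e. is too *low* for their d.r. — which is the quantitative
signature of stereodifferentiation beyond random pairing.

```{r diagnostic}
infer_pool_ees(3.2, 0.93)
```

With a chiral enantiopure linker all stereoisomers are diastereomers; the
d.e. is read as the major:minor excess over the heterochiral pair, an
assumption the diagnostic flags in its documentation.

## Design decisions that were genuinely open

- **Sequential vs simultaneous stages.** Whether such a model is solved
  with the integrated closed forms or numerically as one network is
  immaterial under the separation assumption — the package provides both
  and tests their equivalence (1e-6 in e.e. across a grid of *s* and
  conversion), so the choice carries no result risk.
- **Conversion convention.** *C* is the fraction of the racemic substrate
  consumed *in the resolution stage*; "50% conversion" means half the
  racemate acylated. This is the reading under which the 62%/83%
  benchmarks reproduce.
- **Closed forms as primary path, enumeration as oracle.** The coupling
  algebra is error-prone in sign conventions, so the tests check it
  against brute-force enumeration of all molecule pairings, which cannot
  get a convention wrong.
- **Rounding.** Printed percentages are assumed round-half-even at the
  printed precision (base R rounding); e.e. defaults to two decimals
  because one decimal cannot distinguish 99.98% from 99.99%, d.r. to
  "X:1" with one decimal.

## Problem sizes

The test suite and the reproduction script use desk-scale problems
throughout: single closed-form solves, 36 ODE runs for the
closed-form/ODE equivalence grid, 20 stochastic replicates at 1e5
molecules for the stochastic/deterministic comparison, a 1000×1000 grid
for the feasibility oracle, and 200 synthetic sets for parameter
recovery. These sizes were chosen as the smallest at which each
statistical conclusion is stable (the stochastic standard error at 1e5
molecules is ~6e-4 in e.e., an order below the effects being checked).

## Known limitations

No reversibility, catalyst species or deactivation, no temperature
dependence, no diastereomer-level modelling of chiral-linker products
beyond the hetero:homo and d.e. summaries, and no prediction of *which*
catalyst or base achieves a given selectivity — the model starts from *s*
and rate-constant ratios, it does not derive them. The stochastic module
assumes a well-mixed volume. The closed forms assume irreversible,
strictly second-order steps; regimes outside them must go through the ODE
path.
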