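---
title: "Traveling waves of a two-predators/one-prey reaction-diffusion system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves of a two-predators/one-prey reaction-diffusion system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavepred)
```

## The model

The dimensional system couples a non-diffusing prey `u` to a diffusing
predator `v`:

$$u_t = a_1 u - a_2 u^2 - a_3 u v - a_4 u v^2, \qquad
  v_t - D_2 \Delta v = a_3 u v - a_5 v - a_6 v^2 + a_4 u v^2 .$$

The `u v^2` term is the novelty: two predators (a mating pair) feeding on
one prey, a gain for the predator and a loss for the prey. After
nondimensionalization two parameters survive:

$$U_t = U - U^2 - UV - UV^2, \qquad
  V_t = V_{XX} - k_1 k_2 V - k_1 V^2 + k_1 UV + k_1 UV^2 .$$

`wavepred` uses the map `k1 = sqrt(a1 a4)/a2`, `k2 = a5/(a1 k1)`. The
square root is the unique reading under which the two statements that pin
the admissible regime agree exactly: `k1 > 1` if and only if
`a4 > a2^2/a1` (strong pair-interaction), and `0 < k1 < 1` corresponds to
the ecologically rejected opposite inequality. `nondimensionalize()`
implements the map and flags the regime; the property is tested over random
rate draws. Both solution families divide by `k1 - 1`, so `k1 = 1` is
accepted by the parameter container but refused with an explicit
"degenerate" error by every solver.

`equilibria()` reports the extinction state `(0, 0)`, the prey
carrying-capacity state `(1, 0)`, and the coexistence roots obtained by
eliminating `U = 1 - V - V^2` from the predator nullcline, which leaves the
cubic `V^3 + 2V^2 + V + (k2 - 1) = 0`; roots are Newton-polished until the
kinetics vanish below `1e-12`, and negative branches are flagged
non-biological rather than dropped.

## Traveling-wave reduction and the combined equation

With `U(X,T) = u1(xi)`, `V(X,T) = v1(xi)`, `xi = X - cT`, the system
reduces to

$$-c u_1' = u_1 - u_1^2 - u_1 v_1 - u_1 v_1^2, \qquad
  -c v_1' = v_1'' - k_1 k_2 v_1 - k_1 v_1^2 + k_1 u_1 v_1 + k_1 u_1 v_1^2,$$

and the two equations are **summed** into one scalar combined ODE before
the expansion ansatz is applied. This is a real modeling commitment, not a
technicality: the constructed solutions annihilate the *sum*, and nothing
forces them to solve the prey and predator equations separately. The
package therefore keeps two residual layers (`residual_system()`,
`residual_combined()`), asserts only the combined layer for the derived
families, and ships the exact pointwise identity
`combined = prey + predator` as a property test on random smooth profiles.
`verify_family()` prints both layers plus the divergence of a PDE run
initialized from the closed form, labeled "measured, not asserted".

## The expansion engine

Both methods share one pipeline. The ansatz is polynomial in a generator
function, `u1 = sum_i alpha_i F^i`, `v1 = sum_i beta_i F^i` with zero
constant terms in the model pipeline (the engine supports nonzero
constants). Homogeneous balance matches the top degree of `u1 v1^2`
(`n + 2m`) against `v1''` (`m + 2`, since each derivative of `F` raises its
degree by one under either rule), while `u1^2` against `u1 v1` forces
`n = m`; the unique balance is `(1, 1)`. The generator rule is then
substituted — `F' = -F^2 - lambda F - mu` for the (G'/G) method, or
`(F')^2 = h0 + h1 F + h2 F^2 + h3 F^3 + h4 F^4` for the generalized
auxiliary method, the standard squared convention under which the
closed-form solution catalog actually solves the rule — and the coefficient
of every power of `F` is collected into one polynomial equation. Under the
quartic rule a lone odd power of `F'` survives; its coefficient
`c (alpha1 + beta1)` must vanish on its own, which is where the
`alpha1 = -beta1` family (wave speed free) and the `c = 0` standing family
branch apart.

### Exact algebra instead of a CAS

No computer-algebra system is involved. The engine works over exact sparse
multivariate polynomials with rational coefficients stored as reduced
integer fractions in doubles; arithmetic aborts loudly if a coefficient
would leave the exactly-representable range below 2^52, so a claimed zero
is always a real zero. Rational functions cancel only scalar and monomial
content (no polynomial gcd); what keeps expressions small is the *solver
representation*: families are triangular chains — each unknown assigned a
rational function that may reference unknowns solved later — plus at most
one quadratic minimal polynomial with a sign tag. Back-substitution proofs
substitute the chain and reduce by quadratic pseudo-remainder, which
certifies both sign branches at once and never forms nested radicals.
Numeric evaluation resolves the chain after computing the quadratic root
with the family's sign.

The solver itself is a deterministic depth-first elimination with three
rules: factor out monomial content in the unknowns (branching per factor,
e.g. `mu = 0` versus the Case I relation `c (alpha1 + beta1) = lambda
beta1`), solve equations linear in one unknown whose pivot is free of the
remaining unknowns (recording the pivot-nonzero validity condition), and
keep a terminal single-unknown quadratic as a minimal polynomial. Branches
whose prey amplitude collapses to zero are returned but tagged trivial.

Correctness is cross-checked two independent ways: an evaluation oracle
(the collected system, reassembled as a polynomial in `F`, must equal
direct numeric substitution of the ansatz into the combined ODE at random
parameter tuples to `1e-9`) and exact back-substitution of every family
into its source system.

### The two families

For the (G'/G) rule the solver returns Case I,

$$\alpha_1 = \frac{-2}{\beta_1(k_1-1)}, \quad
  \mu = \frac{k_1 k_2}{2} + \frac{1}{\beta_1^2 (k_1-1)}, \quad
  \lambda = \frac{1}{\beta_1} + \frac{k_1 \beta_1}{2} +
            \frac{2}{\beta_1^3 (k_1-1)^2}, \quad
  c = \frac{\lambda \beta_1^2 (k_1-1)}{\beta_1^2(k_1-1) - 2},$$

valid away from `beta1^2 (k1 - 1) = 2` (flagged, not hidden), and Case II
with `mu = 0`, the same `alpha1`, and `lambda` the root of a quadratic with
two sign branches; both cases satisfy `alpha1 beta1 (k1 - 1) + 2 = 0`
identically. On the slice `k1 = 2/beta1^2 + 1` Case II collapses to
`alpha1 = -beta1`, the wave speed drops out of the system entirely (it is a
genuinely free parameter there, supplied by the user and recorded as such),
and `lambda = 2(beta1^2 + 2)/(3 beta1)`,
`k2 = (4 beta1^4 + 7 beta1^2 + 16)/(9 beta1^2 + 18)` are proven as exact
identities by re-solving the system with `k2` promoted to an unknown
(`gg_case2_slice_symbolic()`).

For the quartic rule the free-speed family is `alpha1 = -beta1`, `h1 = 0`,
`h2 = 1 + k1 k2`, `h3 = 4 k1 beta1 / 3`, `h4 = (k1 - 1) beta1^2 / 2`, with
`h0` free; `h0 = 0` selects the sech² catalog branch and yields the pulse
with `V = -U` identically.

## Generator functions and their catalogs

`gg_F()` implements the three-branch general solution of the (G'/G) rule
(hyperbolic, trigonometric, rational, by the sign of
`Delta = lambda^2 - 4 mu`). The hyperbolic branch is evaluated in a
tanh-based form that is stable for large `|xi|`; its plateau values
`-lambda/2 ± sqrt(Delta)/2` are the fixed points of the generator ODE. The
integration-constant default is `A1 = 0, A2 = 1` — the bounded tanh-type
kink — because the coth-type choice `A1 = 1, A2 = 0` has a pole at the
origin; both are exposed, and poles are masked to `NaN` with a count
rather than raised.

`aux_F()` implements the closed-form catalog of the quartic rule for
`h0 = h1 = 0` (plus the `h3 = 0` and `h4 = 0` families). The exact
constants in each branch — for instance the denominator
`sqrt(delta1) - h3 sech(...)` with `delta1 = h3^2 - 4 h2 h4`, and the
rational branches `1/(sqrt(h4) xi)` and `4/(h3 xi^2)` — are fixed by the
defining-ODE identity `(F')^2 = h2 F^2 + h3 F^3 + h4 F^4`, which every
branch must pass to `1e-9` in the test suite (complex-step
differentiation, poles masked); a catalog entry that failed that identity
would be a bug, and the identity, not any transcription, is the authority.
Branch preconditions (`h2 > 0`, sign of `delta1`, ...) are checked by name.
For the pulse family `sqrt(h2 h4)` is real only when `k1 > 1`; `k1 < 1`
requests draw a complex-coefficient warning at derivation and a refusal at
evaluation, matching the regime discussion above.

## Numerical verification choices

**PDE integrator.** Method of lines, second-order central differences for
the predator Laplacian, zero-flux (mirror-ghost) boundaries — the least
committal choice for a comparison the model itself does not constrain. The
default time integrator is an explicit forward scheme substepped to the
diffusion stability bound `dt <= 0.4 dx^2 / 2`; `lsoda` (via deSolve) is
the stiff alternative behind the same interface, and the two are
cross-checked against each other on a smooth transient. Fields exceeding
`1e6` abort the run with a flag instead of an error. Snapshot times are the
user's `dt`; the substep is internal.

**Manufactured-solution convergence.** `U* = e^{-t} sin x + 2`,
`V* = e^{-t} cos x + 2` on `[0, pi]`, chosen so the predator field
satisfies the zero-flux boundaries exactly (the prey equation has no
spatial operator, so it needs no boundary compatibility). With the
explicit substep tied to `dx^2`, the measured error order in `V` at
`t = 0.5` over `nx = 64, 128, 256` is the spatial order; the suite accepts
`[1.8, 2.2]`.

**Front speed.** Per-snapshot level-crossing positions by linear
interpolation, then a least-squares line; the estimator must recover a
synthetic translation and the wave speed of a sampled closed-form kink to
`1e-6`. Multiple or missing crossings raise a "no-front" error rather than
guessing.

**Problem sizes.** Residual scans use 401–801 points on `xi ∈ [-4, 4]`;
PDE comparisons use a few hundred grid points and horizons of order 1;
the symbolic derivations are cached per session (about three seconds the
first time). These sizes make the full suite run in well under a minute
while leaving every assertion far from its tolerance.

## Figure studies and defaults

`fig1_scan()` tabulates the Case I discriminant across `k1` on both sides
of 1; it is positive throughout and diverges like `1/(k1-1)^2` at the
degenerate point, which is why the kink (hyperbolic) regime is the generic
one. The scan's fixed parameters default to `beta1 = 0.5` and `k2 = 0.5`,
the values used by the other two studies. `fig2_profiles()` evaluates the
Case II kink on the caption slice at `beta1 = 0.5` (hence `k1 = 9`,
`lambda = 3`, `k2 = 8/9`); the wave speed is free there and defaults to 1,
with the log noting the choice. `fig3_profiles()` evaluates the pulse at
`k2 = 0.5`, `beta1 = 1`, `c = 1`, `k1 = 3`, where interval arithmetic on
`tanh ∈ (-1, 1)` proves the denominator `2 sqrt(h2 h4) tanh - h3` stays in
`(2 sqrt{2.5} - 4, -2 sqrt{2.5} - 4)`, strictly negative, so the pulse is
globally smooth. CSV is the canonical figure output; plotting is an
optional ggplot2 convenience.

## Known limitations

- The exact engine has no polynomial gcd; intermediate rational functions
  can carry large common factors, and coefficients beyond 2^52 abort with
  an explicit overflow error. The shipped derivations stay far from the
  bound; pathological custom systems may not.
- Only the degree-(1,1) ansatz is wired into the model pipeline; higher
  degrees, negative powers and other expansion variants are out of scope.
- The derived formulas solve the combined traveling-wave ODE. Whether they
  solve the two reduced equations separately is measured and reported
  (they generally do not); no claim is made either way, and the PDE
  comparison is a divergence curve, not a pass/fail test.
- The pulse family has `V = -U`, so one density is negative wherever the
  other is positive; the kink branches can also dip negative depending on
  sign choices. Positivity violations are flagged in every report, and the
  package deliberately does not pick a "biologically correct" sign branch.
- Equilibrium stability is labeled, not analyzed; no bifurcation theory,
  no existence/uniqueness theory, and 1-D space only.
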