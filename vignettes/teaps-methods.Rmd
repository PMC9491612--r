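---
title: "Stability-constrained exploration of kinetic parameter space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-constrained exploration of kinetic parameter space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaps)
```

## The problem

Kinetic models of biochemical networks — ODE systems dx/dt = f(x, mu) over
species concentrations x with rate parameters mu — are routinely built with a
known reaction structure but largely unknown parameter values. Instead of
fitting one "best" parameter set, this package maps out the *whole region* of
parameter space in which the model is **biologically stable and resilient
(BSR)**: it has a prescribed fixed point x\*, the neighbourhood of x\* is
locally contracting, and relaxation back to x\* happens within a prescribed
timescale. An ensemble of such parameter sets supports distributional
analyses (which parameters does stability pin down? along which directions is
the allowable set wide or narrow?) and parallel simulations that expose
behaviour shared across the allowable region.

## The BSR objective

Three components measure the three requirements, evaluated without any ODE
integration:

* **Fixed point** — `o_fix(mu) = ||f(x*, mu)||_2`, the Euclidean residual at
  the target state (all-ones by default, since concentrations are expressed
  relative to their homeostatic values).
* **Local contraction** — `o_basin(mu) = ReLU(max_{x in X} lambda_max(M(x)))`
  with `M(x) = Df(x) + Df(x)'`, the symmetrized Jacobian, evaluated at a set
  X of observation points drawn uniformly from a box of half-width `d` around
  x\*. A negative-definite M at x certifies that neighbouring orbits contract
  at x; if `lambda_max(M) < 0` holds on a whole box, every orbit started in
  the box converges exponentially to the fixed point (the property the
  theorem tests in the test suite verify numerically). The half-width is
  grown over the search — 0.004, then 0.036, then 0.1 — so that early stages
  only need contraction very close to x\*; the final 0.1 corresponds to
  tolerating 10% perturbations of every species.
* **Relaxation** — `o_relax(mu) = ReLU(max Re lambda* - lambda_target)` over
  the non-zero eigenvalues of the fixed-point Jacobian, with
  `lambda_target = -0.3` by default (relaxation visibly complete by t = 100
  in the model's time unit). Eigenvalues with |Re| below 1e-8 are treated as
  structural zeros: conserved totals and constant species produce genuinely
  neutral directions, and a system that is neutrally stable along such
  directions is still Lyapunov stable, so they are excluded rather than
  penalized.

The scalar objective for quasi-Newton minimization is
`o_fix^2 + o_basin^w + o_relax^w` (default w = 2); the cluster-Newton stage
consumes the concatenated residual vector instead.

### Constant species, conserved cycles, and why the contraction term needs a slack

Two structural facts about flux-balanced networks shape several numerical
choices and deserve spelling out.

First, species with an identically zero derivative (a clamped pool such as
s3 in T3, or s4 in T8) are inputs, not dynamic state. The contraction matrix
M is therefore built on the *dynamic* subsystem: a constant species whose
value other rates depend on would contribute a zero diagonal entry with
non-zero off-diagonal couplings, making `lambda_max(M) > 0` unconditionally
— an artefact of including a frozen coordinate in a contraction argument
that is only about the moving ones. The relaxation term is indifferent to
this choice: a zero row only adds zero eigenvalues, which are excluded
anyway.

Second, and less obviously, *strict* box-wide contraction is unattainable
for several of the benchmark motifs. Take T1: the fixed-point constraint
forces `k3 = d(re2)/d(s3)` at x\* exactly (production and consumption of s2
balance), so the {s2, s3} principal block of M is `[[-2 k3, 2 k3], [2 k3,
-2 k3]]` — exactly singular. At observation points with s1 > 1 the coupling
exceeds k3 and the block determinant turns negative; by eigenvalue
interlacing `lambda_max(M) > 0` by a margin of order `0.1 c km2/(km2+1)`,
far above rounding noise, everywhere in the search box. The conserved cycles
of T6/T7 behave the same way. The zero set of a strict contraction penalty
is therefore *empty* for these models, and a strict objective has no plateau
to explore: in early versions of this package every search run collapsed the
entire ensemble onto a single trade-off point. The search objective
consequently penalizes `ReLU(lambda_max(M) - basin_slack)` with
`basin_slack = 0.1 = |lambda_target|/3` by default: local expansion, where
it is structurally unavoidable, must stay well below the required relaxation
rate. The `o_basin` *diagnostic* that the package reports is always the
strict ReLU. The same 0.1 ceiling defines membership in the brute-force
reference searches, so the two pipelines judge the same region. For
negative-feedback motifs (T2, T4), where strict contraction is attainable,
the allowable set is essentially unchanged by the slack.

## The search algorithm

The search alternates two stages inside an outer loop that restarts from
fresh random clouds until a stopping rule fires.

**Collection (cluster-Newton) stage.** A cloud of `n_initial` parameter sets
is drawn log-uniformly over the search box (defaults: 5e-3 to 5e4 for
ordinary parameters, 5e-1 to 5e4 for zeroth-order input fluxes; all search
arithmetic is in log10 coordinates, since the box spans seven decades). The
fixed-point condition is an *exact* constraint with an analytically solvable
structure, so each member is first projected onto the manifold
f(x\*, mu) = 0: for the built-in models the constrained parameters are
solved in closed form with the free coordinates untouched, otherwise a
minimal-norm Gauss-Newton iteration is used. Keeping the free coordinates
fixed matters — a minimal-norm projection from a random cloud splits the
correction across all coordinates and systematically drags the cloud's free
coordinates toward the centre of the box, destroying the coverage the
uniform cloud is supposed to deliver. The iterations then fit one linear
least-squares surrogate of the residual vector over the whole cloud
(residuals are log1p-compressed first; their raw dynamic range spans many
orders of magnitude and would otherwise dominate the fit), step every member
toward the zero target with per-member trust-region scaling, and collect
members whose combined objective falls below the moderate level
`cnm_threshold` (default 1e-2). After the up-front projection the combined
objective is strongly bimodal — essentially zero inside the allowable region
versus order 0.1 outside — so the precise threshold value is uncritical.
Members whose trust region collapses are re-projected and continue.

**Globalization (g-LBFGS) stage.** For each observation half-width of the
schedule, every pool member is optimized by a limited-memory BFGS with a
twist: the search direction is rotated by a random angle (up to 30 degrees,
decaying geometrically per iteration) within the plane spanned by the
descent direction and a random vector, which diversifies the entry paths
into the allowable region. Gradients are central finite differences in log10
space (step 1e-4); the eigenvalue terms are only piecewise smooth, so
analytic derivatives would break at crossings anyway, and the line search
falls back to plain descent steps when the local slope estimate is
unreliable near a kink. All of this is evaluated in lock-step batches across
the pool — the batched symmetric eigensolves are the hot loop and live in
compiled code. Members already on the zero plateau are not re-optimized:
re-optimizing a converged member under a freshly drawn observation set
ratchets it toward the corner of the region where every constraint binds,
and repeating that over all sweeps was observed to collapse ensemble
coverage.

After each sweep, `n_noise_loops` expansion loops perturb every member with
log10-Gaussian noise (sigma halving per loop), project the perturbed copies
back onto the fixed-point manifold, and keep those that already satisfy the
moderate condition at the *final* half-width, alongside all parents. Two
choices here are deliberate. The noise scale defaults to a full decade —
kicks must be commensurate with the box (seven decades), not with a unit
scale, or the loops merely dither the ensemble instead of relocating members
across broad allowable regions. And children that land *outside* the region
are discarded rather than re-optimized: optimizing them back would deposit a
copy on the boundary nearest their parent, and iterating that visibly piles
density onto the region boundary while diluting interior coverage.

The final sweep of the last stage runs untwisted, and the pool is then
projected onto the fixed-point manifold one last time, so that the published
acceptance filter — `||f(x*, mu)||_2 < 1e-6` and max non-zero
`Re lambda* < 0` — is met exactly rather than up to an optimizer's stalling
tolerance. (Minimizing the weighted sum alone cannot get there: for motifs
with a positive contraction infimum the o_basin gradient pushes the iterate
off the manifold and the components equilibrate with `o_fix` around
0.01-0.05.)

**Stopping rule.** After each outer round, for every parameter, a Wilcoxon
rank-sum test compares the values found so far against the same values
augmented with the newest round (alpha = 0.1, no multiplicity correction),
and at least 99% of the newest values must lie within the historical
min-max range. Only when both conditions hold for all parameters does the
search stop; otherwise a fresh cloud is drawn, up to `max_outer_iters`
rounds, and accepted sets are merged across rounds.

## Basin stability

The Monte-Carlo estimator integrates each sampled parameter set from
perturbed starts (each dynamic coordinate at `target * (1 + U(-h, h))`,
h = 0.15 for the small models) to t = 100 with `deSolve::lsoda`
(rtol 1e-6, atol 1e-9), then polishes the endpoint with a damped Newton
iteration on f(x) = 0 using the analytic Jacobian. A start counts as stable
when every dynamic component of the polished root lies within 90-110% of the
target *and* the root stays within half the window margin of the endpoint.
The second condition is a guard: from a sustained oscillation the root
solver can happily land on the unstable fixed point enclosed by the cycle,
and crediting that would judge a limit cycle stable — the package ships a
two-species limit-cycle fixture (`limit_cycle_model()`) whose basin
stability correctly evaluates to zero. Constant species are neither
perturbed nor judged: perturbing a clamped input genuinely moves the fixed
point, making "return to the original x\*" unsatisfiable by construction.

Stage-wise traces (`basin_trace()`) re-estimate basin stability for the
stored pool snapshots; stability rises from the loose cluster-Newton
candidates to the final ensemble.

## Reference searches

`fixed_point_reduction()` gives the closed-form solution of f(1; mu) = 0 per
built-in model (e.g. T1: `k1 = k3 = k4 = v2/(km2+1)`, free (v2, km2); T8:
`v1 = k0 (km1+1)(1+fb3-fb4)`, `v2 = k0 (km2+1)`, `v3 = k0 (km3+1)`, free
(k0, km1, fb3, fb4, km2, km3) — five free once the input flux is pinned to
0.5). `brute_force_search()` enumerates log-uniform candidates (random
draws or a tensor grid) over the free parameters, back-substitutes the
constraints so `o_fix = 0` holds by construction, and keeps points with
`max Re lambda* <= lambda_target` and `lambda_max(M) <= basin_tol` on a
frozen, seeded observation set at d = 0.1. A seeded random observation set
is used rather than a corner lattice: the corner maximum is systematically
about 10% stricter than the random-point maximum the search objective
itself uses, which (with the boundary exactly at the tolerance) would
misclassify the whole boundary band.

One genuine inconsistency had to be resolved: the brute-force sampling range
is printed as 5e-4 to 5e4 while the search box starts at 5e-3. For T1-T7
the allowable regions do not touch the 5e-3 bound and the choice is
irrelevant, but 65% of the T8 reference mass lies below the search box
(weak-feedback tails), so a comparison across that support mismatch is
bounded near cosine 0.6 no matter how good the search is. The comparison
pipelines therefore run the reference search over the searched box (5e-3
lower bound); standalone `brute_force_search()` keeps the printed 5e-4
default.

## Distribution comparison

Densities are estimated with a product-Gaussian KDE in log10 space with
per-dimension Silverman bandwidths (`sigma_j (4/((p+2) n))^(1/(p+4))`,
floored for degenerate dimensions at 1e-3 log10 units or half the grid
pitch), evaluated on a shared tensor grid over the free parameters and
normalized to sum one. Cosine similarity and Jensen-Shannon divergence
(natural log, 0 log 0 = 0) compare the flattened vectors; a random
comparator — vectors whose components are resampled from the reference
density's own value histogram, destroying spatial structure — calibrates
both indices, reported as log10 ratios with bootstrap 95% intervals.
Positive cosine ratios and negative JS ratios mean the search ensemble
carries real spatial information about the allowable region.

Grid resolution is a knob with a real trade-off: with a few thousand
ensemble members in five dimensions the KDE's shot noise is substantial
(two independent halves of the *same* reference ensemble agree only to
cosine ~0.84 at 1,211 members, ~0.95 at 12,713), so comparisons at small
sample sizes under-read the true distributional agreement. The default
resolution keeps the total cell count near 2e5 (20 points per dimension in
two dimensions, 11 in five).

`pca_full()` and `pci()` characterize ensemble shape: full-rank centered
PCA in log10 space, and the principal central axis index
`PCI(i) = sum_k c_ki k / sum_k c_ki`, `c_ki = |l_ki| / sum_m |l_km|` — a
loading-weighted mean axis number per parameter. Small PCI flags parameters
that vary along the broad leading axes of the allowable set; large PCI flags
parameters confined to its narrow trailing directions.

## Benchmark models and what passing tests show

The eight built-in models are small reaction networks — positive feedback
(T1), negative feedback (T2), a reversible pair with a clamped regulator
(T3), mutually inhibiting branches (T4), cooperating branches (T5),
conserved two-state cascades (T6, T7), and a chain with a doubly regulated
入口 reaction (T8; the regulation denominator `1 + fb3 s3 - fb4 s4` makes
positivity of `1 + fb3 - fb4` part of validity). They exercise the features
that matter for the method — Michaelis-Menten saturation, inhibition,
conservation laws, clamped species — at a scale where exhaustive reference
searches are computable. They do not emulate measurement noise, partial
observability, or model misspecification: passing the distribution
comparisons shows that the search recovers the allowable region of a
*correctly specified* model, not that the method is robust to wrong
structure.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full pipelines at desk
scale, chosen to finish in minutes on one CPU: clouds of 500 members
(2,000 for T8, whose allowable region is the thinnest in the highest
dimension), pools of 400-800, two to five outer rounds, and reference
searches of 1e5 candidate points (1e6 for the sparse T7/T8 regions) versus
the order-1e8-1e9 enumerations behind the printed reference values. At
these sizes the KDE shot-noise floor discussed above — not the search
itself — is the binding constraint on the similarity indices for the
five-dimensional T8 comparison.

## Known limitations

* Exact contraction certificates are impossible for flux-balanced
  positive-feedback and conserved-cycle motifs (singular-block argument
  above); the slack formulation is a considered response, not a numerical
  shortcut.
* The allowable set is assumed connected enough for noise-driven expansion
  to reach it from the collection stage's entry points; isolated islands
  can be missed, which fresh-cloud outer rounds mitigate but do not solve.
* SBML support is a read-only subset (kinetic laws in MathML arithmetic,
  unit compartments, no rules/events/function definitions); unsupported
  constructs are rejected loudly rather than ignored.
* Delay, stochastic and PDE models, Lyapunov-function construction, and
  symbolic stability proofs are out of scope.
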