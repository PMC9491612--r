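# teaps

Thorough exploration of the allowable kinetic-parameter space of a
biological ODE model under stability constraints.

Many biological systems are *biologically stable and resilient* (BSR): they
operate around a fixed point, tolerate moderate perturbations of their state,
and relax back within a characteristic time. For a model dx/dt = f(x, mu)
with known reaction structure but unknown kinetics, that property alone
carves out a region of parameter space — and an ensemble of parameter sets
covering that region is often more informative than any single fitted set.
This package finds such ensembles, estimates their basin stability, and
compares their distribution against exhaustive reference searches.

The BSR condition is encoded in three objective components, none of which
requires integrating the ODE:

* `o_fix(mu) = ||f(x*, mu)||_2` — the prescribed fixed point x* (all-ones by
  default) must be a root;
* `o_basin(mu) = ReLU(max_x lambda_max(Df(x) + Df(x)'))` over random
  observation points x in a box of half-width d around x* — the symmetrized
  Jacobian certifies local contraction of neighbouring orbits;
* `o_relax(mu) = ReLU(max Re lambda* - lambda_target)` over the non-zero
  eigenvalues of the fixed-point Jacobian — relaxation at least as fast as
  `lambda_target` (default -0.3).

The search (TEAPS) couples a cluster-Newton collection stage with a
globalized limited-memory-BFGS stage (randomly twisted search directions,
noise-add/re-optimize expansion loops over a growing observation region) and
repeats from fresh random clouds until per-parameter rank-sum and
containment criteria say the found distribution has stabilized. Eight
self-contained benchmark models (T1-T8) are built in; SBML models can be
imported.

## Worked example

```r
library(teaps)
m   <- bsr_model("T1")                       # positive-feedback benchmark
cfg <- teaps_config(n_initial = 300, n_collect = 200, pool_max = 200,
                    max_outer_iters = 1, seed = 42)
fit <- teaps(m, cfg)
print(fit)
summary(fit)
estimate_basin_stability(m, fit,
  basin_config(n_param_samples = 20, n_initial_states = 50, seed = 2))
```

```
TEAPS search on model T1
  outer rounds: 1 (round cap)
  parameter sets: 200 kept, 188 accepted (BSR filter: ||f(x*)|| < 1e-06, max nonzero Re lambda* < 0)

log10 parameter quantiles (accepted sets):
      2.5%    25%    50%    75% 97.5%
k1  -0.051 -0.033 -0.020 -0.007 0.080
v2   0.751  1.099  1.494  2.361 4.333
km2  0.614  1.080  1.509  2.366 4.328
k3  -0.051 -0.033 -0.020 -0.007 0.080
k4  -0.051 -0.033 -0.020 -0.007 0.080

basin stability: 0.952 +/- 0.048 (SEM; 20 sets x 50 states)
```

The stability constraint pins the first-order rates k1 = k3 = k4 into a
narrow band around 1 (their fixed-point-balance value is v2/(km2+1), and the
relaxation bound caps how slow — and the contraction bound how fast — the
chain may turn over), while v2 and km2 stay free over decades as long as
they move together; 95% of perturbed starts within ±15% of the fixed point
return to it. `plot(fit)` draws the marginal log10 histograms;
`compare_to_reference()` quantifies how well the ensemble covers the
brute-force reference region (cosine similarity / Jensen-Shannon divergence
of kernel-density profiles on a shared grid); `pca_full()` and `pci()`
summarize the wide and narrow directions of the allowable set.

A command-line front end with `run`, `brute-force`, `compare`, `basin` and
`pca` subcommands is installed at `inst/cli/teaps`.

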