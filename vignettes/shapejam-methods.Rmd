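---
title: "Methods: shape statistics, the universal line, and the vertex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape statistics, the universal line, and the vertex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette records the modelling assumptions, parameter choices, and
numerical methods behind `shapejam`, and its known limitations. All numbers
quoted here come from the package's own test suite and can be regenerated
with the code shown.

# 1. Shape statistics

A cell is a simple polygon. Its **aspect ratio** is defined through the
second area moments: with the centroidal inertia tensor of the uniform
lamina, AR = sqrt(λ₁/λ₂) ≥ 1 for eigenvalues λ₁ ≥ λ₂. This definition is

- exact for ellipse-inscribed polygons (an n-gon inscribed in an ellipse of
  axis ratio r has AR → r as n grows; `polygons_with_ar()` root-finds the
  inscribing ellipse so the *measured* AR matches the request),
- exactly invariant under rotation, translation, and uniform scaling
  (verified to 1e-12 in the tests),
- robust for near-regular polygons (all regular n-gons give AR = 1).

`validate_polygon()` rejects self-intersecting and (near-)degenerate
polygons before any moment is computed; orientation is normalised via the
signed shoelace area.

**Rescaling.** `rescale_ar()` divides by the sample mean, so the rescaled
ensemble has mean exactly 1 (to machine precision, asserted at 1e-13). This
is a contract, not an approximation: downstream distribution comparisons
assume unit mean.

# 2. The two one-parameter laws

**k-gamma.** For rescaled (unit-mean) quantities the k-gamma density is
`dgamma(x, shape = k, rate = k)`: mean 1, variance 1/k. The MLE in
`fit_kgamma()` solves the one-dimensional score equation
`log(k) - digamma(k) = log(mean(x)) - mean(log(x))` by safeguarded
root-finding; tests cross-check against brute-force likelihood
maximisation and recover k = 2.6 within 2% at n = 5·10⁴.

**Mean-field aspect-ratio law.** On AR ∈ [1, ∞),

P(AR) ∝ (AR + 1/AR)^{3/2} (1 − 1/AR²) · exp(−α (AR + 1/AR)).

All internal computation is done against the *scaled* Boltzmann factor
exp(−α(h − 2)) with h = AR + 1/AR, so normalisation constants stay finite
for α up to at least 800 (double-precision exp(−2α) underflows near
α ≈ 354 otherwise). `meanfield_norm()`, `meanfield_moments()` and the MLE
use adaptive quadrature on the scaled integrand.

**Sampling.** `sample_meanfield()` is rejection sampling in the transformed
variable w = AR + 1/AR − 2, in which the target density is a slowly varying
prefactor times exp(−αw). The envelope is an equal mixture of
Exponential(α) and Gamma(shape 2.5, rate 0.95α); the bound constant is
taken as 1.1× the maximum target/envelope ratio over a log-spaced grid. The
draw is mapped back through t = (w + sqrt(w² + 4w))/2, AR = 1 + t, with the
exact Jacobian dw/dt = t(t + 2)/(1 + t)². Measured acceptance is 45–67%
uniformly over α ∈ [0.9, 800]. The original t-space samplers fail at large
α because the exponent −α·t²/(1+t) interpolates between t² and t and no
fixed-rate gamma/Rayleigh envelope matches both regimes.

# 3. The universal scaling line

`universal_line()` sweeps α, computes (mean(AR), SD(AR)) of the mean-field
law by quadrature at each α, restricts to mean AR ∈ [1.15, 2.5], and fits a
line by least squares:

SD(AR) = 0.7176 · mean(AR) − 0.7555.

Sensitivity checks in the tests: halving or doubling the α grid, or
perturbing the fit window, moves slope and intercept by less than 0.01. The
quoted headline values 0.71 and −0.75 are the rounded coefficients.
`assess_scaling_deviation()` takes a *set of (mean, SD) points* (e.g. one
per time block or per replicate) and runs a one-sided t-test of the signed
residuals against the line, reporting `mean_residual`, `below`, and
`above`. Note the unit of inference is the summary point, not the raw AR —
raw ARs within one frame are correlated and would overstate significance.

# 4. Glassy-dynamics observables

Trajectories are periodic; displacements are computed after minimum-image
unwrapping (a frame-to-frame jump beyond half a box length is an error, not
silently wrapped). Observables:

- `msd()`: time- and ensemble-averaged mean-squared displacement.
- `self_intermediate_scattering()`: radially averaged
  F_s(q, t) = ⟨J₀(q |Δr|)⟩ (Bessel J₀, the isotropic 2-D average over the
  q-direction).
- `relaxation_time()`: first crossing of F_s below 1/e with log-linear
  interpolation; censored (NA with a flag) if no crossing occurs in the
  window.
- `persistence_time()`: the ballistic-to-diffusive crossover, located where
  the running log–log slope of the MSD first drops through 1.5 (with
  bracketing guards at 1.8 / 1.2).
- `cage_time()`: lag of the peak of the non-Gaussian parameter α₂, with a
  boundary warning when the argmax sits at the window edge.
- `mobility_subsets()`: origin-averaged displacement magnitude at the cage
  time splits cells into fast/slow fractions (deterministic tie-break by
  cell id); `subset_shape_stats()` then compares each subset to the line.

**Oracles.** The tests validate against closed forms: Brownian motion
(MSD slope 4D, F_s = exp(−q²Dt) within 0.02 pointwise, τ_α within 5%) and
the chiral active Brownian particle, whose Green–Kubo MSD has the exact
complex-antiderivative form with μ = D_r − iω:

MSD(t) = 2v₀² Re[t/μ − (1 − e^{−μt})/μ²] + 4D_t·t.

Simulator-versus-oracle comparisons use a 3-standard-error band and are
made only at lags past the ballistic regime (t ≳ 1/max(D_r, ω)): at
ballistic lags the ensemble standard error vanishes faster than the O(dt)
Euler–Maruyama discretisation bias, so the band there tests the integrator
step, not the physics. This is a statistical-power consideration, not a
loosened tolerance — the band itself is unchanged.

# 5. The vertex model

Energy E = Σ_cells [K_A (A − A₀)² + K_P (P − P₀)²] on a periodic box,
degree-3 vertices, overdamped Brownian dynamics
dx = (F/γ) dt + sqrt(2T/γ) dW. Defaults (`vm_params()`): K_A = K_P = 1,
A₀ = 1, target shape index p₀ = P₀/sqrt(A₀) = 3.72 (the solid/fluid
transition neighbourhood — a regular hexagon of unit area has perimeter
sqrt(8·sqrt(3)) ≈ 3.722, so the regular tiling is nearly tension-free),
γ = 1, dt = 0.01, temperature 0.009 unless swept.

Implementation notes:

- Forces are assembled from flat half-edge arrays with `rowsum()`; they are
  the exact analytic gradient (finite-difference checked to 1e-5) and
  conserve momentum on the torus to 1e-10.
- **T1 transitions**: an edge shorter than l_t1 = 0.04·sqrt(A₀) is flipped;
  the new edge is set to 1.02·l_t1 to avoid immediate re-flipping. Flips
  preserve cell count, vertex count, degree-3-ness and planarity
  (revalidated during long runs).
- **Adaptive stepping**: a step that would move any vertex more than a
  fraction of l_t1 is retried at dt/2 (recursively); `vm_run()` aggregates
  these events into a single summary warning rather than one per step.
- Initial states come from `periodic_voronoi()` of a perturbed hexagonal
  lattice (`disorder` scales the perturbation). The periodic Voronoi is
  built from a 3×3 tiling passed to `deldir`, keeping one representative
  triangle per torus triangle via an eps-tolerant circumcenter-in-domain
  test plus a translation-invariant dedupe key; this is exact for the
  degenerate regular lattice (all degrees 6, areas tile the box exactly).

**Frozen-cluster protocol.** `freeze_exterior()` grows a compact
edge-connected cluster of n cells (BFS from a seed cell); a vertex is
mobile iff *all* its incident cells are in the cluster. For n = 1 no vertex
is mobile, so the single cell's shape is constant and SD(AR) = 0 exactly —
this is a structural consequence of the vertex rule, not a numerical
statement. `frozen_cluster_experiment()` averages *within-run* statistics
(mean AR, SD AR) over seeds rather than pooling raw ARs: pooling would add
between-seed variance of the means into the SD and, e.g., make the n = 1
SD spuriously nonzero.

# 6. Parameter and problem-size choices

All problem sizes in the tests are this package's own choices, scaled to a
desktop test budget:

- Distribution fits: n = 5·10⁴ samples gives parameter standard errors
  well inside the 2% acceptance tolerances.
- Frozen-cluster experiment: 64 cells, cluster sizes {1, 4, 12, 24},
  temperatures {0.004, 0.012}, 3 seeds, 6000 equilibration + 6000
  production steps at snapshot stride 50. The step counts matter: with
  only 2000 production steps (~40 frames/run) the per-run SD(AR) estimates
  scatter by ~0.03, which swamps the ~0.004 low-versus-high-temperature
  deviation ordering and can produce spurious monotonicity inversions.
  6000/6000 resolves both cleanly (low-T mean |residual| 0.006 vs high-T
  0.042). Equilibration length is also physical: at T = 0.004 relaxation
  is slow, and an under-equilibrated tissue retains excess shape variance.
- Temperature sweep: T ∈ {0.003, 0.006, 0.012, 0.02} on 64 cells tracks
  the universal line within |residual| < 0.05 (measured ≤ 0.012).

# 7. Generator realism

The synthetic generators are deliberately minimal but oracle-equipped:

- `chiral_abp_trajectory()` is the dilute (non-interacting) limit; its
  headings wind at ω = ω_max·χ_cell, so |χ_cell| monotonically shortens
  the persistence time while D_r is held fixed. Ensemble chirality χ_sys
  imbalances the clockwise/counterclockwise counts.
- `polygons_with_ar()` produces unit-area ellipse-inscribed n-gons with
  independently randomised orientations; an end-to-end test samples ARs
  from the mean-field law at α = 2, builds polygons, re-measures, and
  refits α within 0.1.
- `periodic_voronoi()` of uniform points gives realistic disordered
  tessellations (Lewis-law-like area spread; a planted bimodal point
  process yields bimodal areas that model selection (`mclust`) detects).

# 8. Known limitations

1. **No persistent dynamical heterogeneity at equilibrium.** The headline
   expectation that the *fast*-mobility subset sits significantly below
   the universal line is not reproduced by this vertex model at thermal
   equilibrium, at any desk-scale configuration probed (T ∈ {0.006, 0.010,
   0.015}): the non-Gaussian parameter α₂ stays flat (≲ 0.02), and the
   fast and slow subsets are statistically identical (fast-subset mean
   residuals +0.003 to +0.010, one-sided p ≈ 1). This is expected physics:
   equilibrium Brownian vertex dynamics at these temperatures has no
   long-lived mobility memory, so a subset selected by displacement over a
   cage time decorrelates from shape. The acceptance test asserts the
   claim as written and is a documented red; reproducing it likely needs
   an out-of-equilibrium (e.g. self-propelled) variant, which is out of
   scope here. The companion claim — the *temperature sweep* tracks the
   line, and the *slow* subset is consistent with it — is green.
2. **"Far below the line at n = 1" is temperature-dependent.** At T =
   0.004 the fully equilibrated single frozen cell has mean AR ≈ 1.049,
   which is where the universal line crosses zero; its residual is then
   ≈ 0 by geometry, and "far below" is only a meaningful statement at
   higher temperature (at T = 0.012, residual ≈ −0.15). The acceptance
   test asserts non-positivity at both temperatures and "far below" at the
   high one.
3. The vertex-model integrator is Euler–Maruyama; observables with O(dt)
   sensitivity (e.g. short-lag MSD curvature) inherit that bias. The
   adaptive halving bounds per-step displacement, not weak-order error.
4. `init_tissue(n_cells)` requires n_cells = nx·ny with ny even (hexagonal
   lattice on a torus); 24, 36, 64 are used throughout.
5. The mean-field sampler's envelope constant is grid-estimated (512
   log-spaced points, 1.1 safety factor); it errors out rather than
   silently degrading if acceptance drops below 1%.
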