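---
title: "Inferring single-cell proton fluxes from pH landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring single-cell proton fluxes from pH landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phfluxnet)
```

## The problem

Cancer cells acidify their microenvironment (the Warburg effect), and the
acid leaves each cell mostly as lactate with a cotransported proton. Given
time-lapse measurements of extracellular pH at a few hundred fixed sensor
locations and the positions of the cells in the same field of view,
`phfluxnet` infers the net proton exchange flux of every cell (import or
export), with credible intervals, and recasts the inferred fluxes as a
weighted directed cell-to-cell exchange network.

## Forward model

Proton diffusion (D ≈ 7×10³ μm²/s) equilibrates over a 500 μm field in
seconds, far faster than the minutes between frames, so each frame is
treated as a stationary snapshot: the concentration field solves the
Laplace equation ∇²c = 0 away from sources. Each cell enters as the
monopole (leading multipole) term of the solution,

c(**r**) = c₀ + Σᵢ uᵢ / (4πD·|**r** − **r**ᵢ|) + (boundary term),

and the measured quantity is pH(**r**) = −log₁₀ c(**r**). Conventions:

* Positions in μm (origin at the lower-left frame corner, y up), D in
  μm²/s, native fluxes uᵢ in mol/s, concentrations in mol/L with an
  explicit 10¹⁵ μm³/L factor inside the kernel. All *reported* fluxes are
  converted to mmol per gram dry weight per hour (mmol/gdw/h) using an
  average dry weight of 0.5 ng per cell, the standard specific-flux unit
  that makes single-cell values comparable with bulk measurements.
  uᵢ > 0 raises the local concentration, i.e. lowers pH (acid export).
* `c0` is the background medium concentration. The monopole sum has no
  constant term of its own, but the far field must match the medium, so a
  per-frame constant is included: fixed by `background_pH` when known,
  otherwise estimated as the concentration at the median probe pH of the
  frame.
* The flux `U` through the frame boundary is one extra unknown per frame.
  Its kernel column is the average of monopole kernels over
  `boundary_points` (default 64) virtual sources equally spaced on the
  frame perimeter — the simplest kernel consistent with a net flux
  through the boundary that reduces to a monopole far away.
* Probe–cell distances below 5 μm (the cell radius scale) are clamped to
  5 μm: the point-source idealization diverges as r → 0 and the clamp
  encodes finite cell size.

## Inference

Writing pĤ_μ(u) for the model pH at probe μ and σ_μ for its experimental
error, each frame contributes a cost

χ²_t(u) = Σ_μ (pH_μ − pĤ_μ(u))²/σ_μ² + λ₁ Σ_{i=1..N} uᵢ²,

where the Tikhonov term (a Gaussian prior on the fluxes) fixes a common
scale for exchange fluxes and prevents multicollinearity; the boundary
flux U is *not* penalized (the sum runs over cells only). Frames are tied
together by

χ²_tot = Σ_t χ²_t + λ₂ Σᵢ Σ_t (uᵢ(t+1) − uᵢ(t))² + λ₃ Σ_t (ū(t) − u_b(t))²,

where the λ₂ term smooths each cell's flux across consecutive frames and
the λ₃ term keeps the per-frame mean flux ū(t) (cells only, averaged over
the cells present in that frame) close to the measured bulk efflux u_b.
Because cells die, divide and migrate, the temporal penalty applies only
within tracks found by greedy mutual-nearest-neighbor matching with a
30 μm-per-frame displacement gate; track ends incur no penalty.

### Posterior temperature

χ²_tot is the minimized cost, exactly as written. For uncertainty
quantification the fluxes are sampled from P(u) ∝ exp(−χ²_tot/2): with
the misfit written as Σ r²/σ², the Gaussian-residual likelihood carries
the factor ½, and only with it do the λ's correspond to Gaussian priors
(λ₁ = 1/τ² for prior variance τ²) and the credible intervals attain
their nominal coverage. The MAP is unaffected by this temperature choice.
Simulation-based calibration over 50 replicates (68% intervals covering
the truth 60–76% of the time, held-out residual calibration) is part of
the test suite.

### Stages

1. **Hyperparameter resolution.** λ₁ defaults to the generalized
   cross-validation minimizer on the per-frame linearization at u = 0
   (the GCV selection penalizes all coefficients including U for
   simplicity; the actual objective never penalizes U); λ₂ defaults to
   λ₁/10; λ₃ is set so the bulk term contributes ~10% of the initial
   data misfit, and 0 when no bulk series is given. All are overridable,
   and when the temporal statistics of the fluxes are known (e.g. on
   synthetic data with an AR(1) ground truth of variance τ² and
   autocorrelation ρ), the matched choices are λ₁ = 1/τ² and
   λ₂ = 1/(τ²(1−ρ²)).
2. **Gauss–Newton warm start.** pĤ(u) is linearized around the current
   expansion point; every penalty is exactly quadratic, so each iteration
   is a ridge regression solved in closed form, with step halving
   whenever the exact cost would increase, iterated to a fixed point.
   An underdetermined frame at λ₁ = 0 raises an error advising λ₁ > 0.
3. **Simulated annealing to the MAP.** Metropolis–Hastings on χ²_tot/T
   with geometric cooling (T: 100 → 1, factor 0.95, 200 full-vector
   proposals per level — chosen to pass a double-well benchmark with
   known global minimum), proposals preconditioned by the Cholesky factor
   of the warm-start Gauss–Newton Hessian, step scale shrinking as √T.
   The lowest-cost state ever visited is kept and polished by a final
   Gauss–Newton pass, so the returned cost never exceeds the warm-start
   cost and matches a brute-force minimizer of the exact cost on small
   instances to well under 1% per component.
4. **Posterior sampling.** A Metropolis–Hastings chain on the
   concatenated flux vector of all frames, with the same preconditioned
   proposals; the step scale adapts toward ~30% acceptance during
   burn-in only and is then frozen, so the recorded chain satisfies
   detailed balance. Acceptance rates below 1% or above 99% are flagged
   as step-size pathologies. Credible intervals are central chain
   quantiles; 1σ errors are chain standard deviations.

A single integer seed governs every stochastic stage and is recorded in
the diagnostics; fixed seeds reproduce chains bit for bit.

## Bulk efflux

When only a bulk pH trace is available, `estimate_bulk_efflux()` converts
it to [H⁺], differentiates by central finite differences (one-sided at
the endpoints), scales by the medium volume per cell and converts to
mmol/gdw/h; this supplies the u_b(t) of the λ₃ term.

## The exchange network

A proton released at a donor cell diffuses until absorbed; the
probability of absorption at each importer also solves the Laplace
equation, decaying with distance. The flux from donor i (uᵢ > 0) to
acceptor j (uⱼ < 0) is taken as

F_ij = uᵢ · (|uⱼ|/d_ij) / Zᵢ,  Zᵢ = Σ_{k: u_k<0} |u_k|/d_ik,

so the out-fluxes of every donor sum exactly to uᵢ. The exponent on
distance is configurable (default 1, the monopole absorption heuristic).
The boundary flux is never a network node; the per-frame difference
between total export and total import is reported as *leakage* — the
bulk acidification is the spill-over of a much more intense exchange
network. Edges are kept when F_ij strictly exceeds the detection
threshold (default 0.5 mmol/gdw/h, the average sensitivity scale), and
node degrees are computed on the undirected projection (in/out degrees
are also exported). Summaries per frame: average degree, maximum degree,
largest-connected-component size, degree histogram with its same-mean
Poisson null. Exact properties guaranteed by construction and verified
as property tests: donor conservation (pre-threshold), monotonicity of
all three summaries in the threshold, and exact covariance under flux
rescaling (s·u at threshold s·τ gives the same topology as u at τ).

## Synthetic experiments

`generate_experiment()` emulates the time-lapse regime of a pH-sensing
scaffold experiment: 100–200 cells and a comparable number of fixed
probes in a 500 μm square, 36 frames at 10 min. Choices, fixed once:

* **Background pH 6.8** — within the 6.2–6.9 extracellular range of
  acidified tumor microenvironments. It also keeps the monopole field
  positive across the frame at the chosen flux scale: at markedly higher
  background pH a ~1 mmol/gdw/h importer would drive the idealized
  point-sink field negative over a large neighborhood.
* **Flux scale**: typical |u| = 1 mmol/gdw/h, hubs at 100×, magnitude
  floor 0.01 — spanning the three orders of magnitude between bulk-like
  and extreme single-cell values without asserting an empirical
  distribution.
* **Scenarios**: `uniform` (zero-mean Gaussian fluxes), `hubs` (5% of
  cells at 100×, exporting, over an importing background), `dipoles`
  (a fraction `dipole_fraction` = 0.15 of cell pairs at ±10 mmol/gdw/h
  separated by 15–25 μm over a weak background — isolated motifs, not a
  spanning network), and `crossover` (hub means decaying linearly into
  dipole means across frames, emulating the networked-to-sparse
  transition).
* **Dynamics**: AR(1) per-cell fluxes with ρ = 0.95 (so the temporal
  smoothness assumption holds), cells random-walking 3 μm per frame with
  reflecting boundaries, probes fixed.
* **Noise**: Gaussian pH noise with σ = 0.02, recorded per probe.
  Probes are placed at least 5 μm from cells; a probe whose noiseless
  field would be non-positive or outside pH 3–11 (inside the near-field
  breakdown of the point-source idealization) is re-placed during
  generation.
* Cell-type labels are assigned at random, independent of flux, mirroring
  the absence of flux differences between tumor and stromal cells.

`make_bulk_series()` integrates the total ground-truth efflux into a
stated medium volume (default 10⁻⁴ L) for a consistent bulk pH trace.

What the generator does *not* emulate: buffering chemistry, probe
photophysics, segmentation errors, 3D geometry, or cell division and
death. Passing the recovery and calibration tests therefore demonstrates
correctness of the inverse machinery under the model's own assumptions,
not robustness to the full complexity of real microscopy data.

## What recovery is achievable

With 1 probe per cell and σ = 0.02 pH at background pH 6.8, a
1 mmol/gdw/h flux moves the nearest probe by ~0.05–0.1 pH. Under these
conditions the MAP fluxes on the `uniform` scenario (50 cells, 50 probes,
10 frames) correlate with ground truth at Pearson r ≈ 0.77–0.88 across
seeds — essentially at the information-theoretic ceiling: an oracle
Gaussian estimator linearized at the truth with the exact AR(1) prior
reaches r ≈ 0.79–0.89 on the same data. Higher recovery requires more
probes per cell, lower noise, or stronger pH gradients, not a better
optimizer. Residual calibration is assessed on held-out probes, since
in-sample residuals of any fitted model are systematically smaller than
the noise level.

## Numerical choices and degenerate inputs

* Gauss–Newton: convergence at relative step < 10⁻¹⁰, at most 60
  iterations, 40 step-halvings; concentrations are floored at 10⁻³·c₀
  inside the linearization only (the exact cost is +∞ for non-positive
  concentrations).
* The proposal Hessian carries a 10⁻⁸-relative ridge for Cholesky
  stability.
* Empty cell tables are valid (boundary-only model); frames with no
  probes, non-positive σ, coincident probe/cell positions, and
  out-of-bounds positions are hard, row-numbered errors.
* Coincident donor/acceptor pairs in the network are clamped to the
  5 μm minimum distance with a warning.
* Degree histograms of edgeless graphs have a single k = 0 bin; isolated
  nodes count as components of size 1.

## Problem sizes in the test suite

The suite exercises the full machinery at desk scale: recovery at
50 cells / 50 probes / 10 frames, calibration over 50 replicates of a
5-cell instance, the crossover pipeline at 60 cells / 12 frames, and
1000 randomized network conservation cases. These sizes were chosen so
the whole suite completes in a few minutes while every statistical check
retains enough replicates for its stated tolerance.

## Limitations

* The monopole truncation measures only the net exchange per cell;
  separate import/export routes or intracellular shuttling would require
  higher multipole terms and denser pH sampling, and the method cannot
  attribute fluxes to specific transport mechanisms (MCT vs NHE vs
  carbonic anhydrase).
* The boundary kernel is a perimeter discretization chosen for
  consistency with a net boundary flux; other boundary parameterizations
  are possible.
* Stationarity is assumed within each frame; fast transients between
  frames are invisible.
* The absorption-probability form of the pairwise flux uses the 1/d
  weighting with per-donor normalization; multi-absorber competition
  beyond the normalization is not modelled.
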