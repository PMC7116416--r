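---
title: "Designing multi-shell diffusion MRI protocols with shellopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-shell diffusion MRI protocols with shellopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellopt)
```

## The model

`shellopt` designs multi-shell diffusion MRI (dMRI) acquisitions by measuring
the information content of pilot data, rather than by optimising the
precision of any particular microstructure model. The design problem is
separated into a radial part (which b-values, how many volumes on each) and
an angular part (how many directions per shell), on the assumption that for
dense, uniform direction sampling the per-shell mean DW signal is
rotationally invariant and can be analysed independently of the angular
content.

**Radial part.** The per-shell, per-voxel mean signals form an
`N_s x N_v` matrix `D`. Its compact SVD `D = U S V'` is read as `D = H W`
with an orthonormal basis `H = U` over b-values and weights `W = S V'`. No
positivity or model constraint is imposed: the basis is ranked purely by the
data. The effect size of component `c`, `eps_c = S_c / sqrt(N_v)`, is the RMS
of that component's weights across the brain — the "signal" against which
measurement noise competes.

With i.i.d. Gaussian noise of standard deviation `sigma` per measurement,
averaging `n_s` volumes gives shell-mean variance `sigma^2 / n_s`, and the
coefficient covariance follows by error propagation through the orthonormal
basis: `Sigma_w = sigma^2 H' diag(1/n_s) H`. Each component's coefficient of
variation is `CV_c = sd(w_c) / eps_c` (reciprocal CNR), and the scalar
objective is the sum of squared CVs (SSCV). Squaring weights the objective
toward the noisiest detectable components without discarding strong ones.

Minimising SSCV over `{n_s}` at fixed `N_total` has a closed-form Lagrange
solution, `n_s* ∝ sqrt(sum_c (H_sc / eps_c)^2)`. The normalised fractions are
independent of both `sigma` and `N_total`; this exact invariance is asserted
bit-for-bit in the tests.

Shell b-values themselves are optimised by resampling the measured means at
candidate b-values with shape-preserving piecewise-cubic (PCHIP)
interpolation — the DW decay is smooth and monotone in b, and PCHIP cannot
introduce spurious oscillation — then recomputing basis, effect sizes,
allocation, and SSCV. A Nelder–Mead simplex in log-b coordinates searches
over the nonzero b-values (b = 0 is always retained).

**Echo-time penalty.** The maximum b-value sets the minimum echo time of a
pulsed-gradient spin-echo sequence and thus the T2 attenuation of everything
measured. The adopted timing skeleton packs square gradients of duration
`delta` tightly around the refocusing window: `Delta = delta + t_refocus`,
`TE = t_pre + 2 delta + t_refocus + t_post`, with
`b = gamma^2 G^2 delta^2 (Delta - delta/3)` solved for `delta` by monotone
root-finding (tolerance 1e-6 ms). Effect sizes are scaled by `exp(-TE/T2)`
before allocation, so high-b protocols pay their SNR cost inside the
objective. This skeleton is the minimal assembly consistent with the four
timing constants; spin-echo symmetry (excitation-to-180 midpoint at TE/2) is
*not* enforced, so the TE values are lower bounds for a given hardware — a
documented limitation, and one reason reported TEs are model-dependent.

**Angular part.** The signal on a shell is band-limited in the spherical
harmonic (SH) domain; an order-`l` band limit requires
`(l+1)(l+2)/2` directions for alias-free sampling. The detectable band limit
is estimated in single-fibre voxels (highest angular content), selected by a
diffusion-tensor FA screen on the b <= 1000 shells plus an SH peak-ratio
screen on the highest shell, realigned so each voxel's principal axis maps
onto z, and averaged. Per-order power is compared against a noise floor
simulated at the same direction set and noise level; the resulting minimum
direction counts can be passed to the allocator as per-shell floors.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tolerance` (shell grouping) | 50 | s/mm^2 | absorbs scanner-reported effective b-values onto nominal shells |
| `sigma` / `snr_b0` | SNR 30 | — | noise level entering every CV; derived from the b=0 mean when given as SNR |
| `n_components` | min(shells, numerical rank) | — | components beyond the data's rank are noise; including them lets junk drive the objective |
| `t_pre`, `t_refocus`, `t_post` | 5, 5, 15 | ms | PGSE timing constants of the assumed sequence |
| `gradient_strength` | 80 | mT/m | peak gradient amplitude |
| `t2` | Inf (off) / 100–200 typical | ms | neonatal tissue T2 presets; Inf disables the penalty |
| `gamma` | 2.6752219e8 | rad/s/T | proton gyromagnetic ratio (standard value) |
| `n_starts` | 8 | — | stratified simplex starts; robustness against local minima |
| `fa_threshold` | 0.25 | — | single-fibre screen, suited to low-anisotropy neonatal data |
| `peak_ratio` | 0.5 | — | maximum second/first SH peak amplitude for "single fibre" |
| noise-floor percentile | 0.95 | — | order is "detectable" above the 95th percentile of pure-noise power |

## Numerical choices

- **SVD sign convention.** Each basis column is flipped so its
  largest-magnitude entry is positive; weights are flipped with it. Exactly
  degenerate singular values keep the solver's ordering, so component order
  within an exact tie is platform-defined.
- **Integerisation.** Largest-remainder rounding of `fraction x N_total`,
  ties to the lower shell index (deterministic and budget-exact); per-shell
  minima are then repaired by taking volumes from the donor shell with the
  smallest SSCV penalty per moved volume.
- **Degenerate candidates.** Duplicate or out-of-range b-values return a
  large finite penalty (1e12, graded with the violation) rather than an
  error, so the simplex can step back into the feasible region.
- **Search coordinates and convergence.** The simplex runs in log-b (b-values
  are positive and span an order of magnitude) with `reltol = 1e-9` and at
  most 500 iterations per start; 8 stratified, seed-jittered starts cover the
  measured range. Cost evaluations are cached on b-values rounded to
  0.1 s/mm^2. A grid search at 1 s/mm^2 resolution serves as the oracle in
  the tests.
- **Peak screen at order 2.** Truncated SH expansions of sharp high-b
  profiles ring, which can split a single fibre's attenuation pattern into a
  spurious ring of peaks at order 4+. Order 2 is monotone in `cos^2` of the
  angle to the fibre, so the screen counts fibre axes without ringing
  artefacts; the realigned fit afterwards uses the requested order.
- **PCHIP implementation.** The interpolant is fitted once per data matrix
  and evaluated as matrix operations over all voxels (the classic
  Fritsch–Carlson slopes with one-sided end conditions); agreement with
  `pracma::pchip` is asserted to 1e-12 in the tests.

## What the phantom generator emulates — and what it does not

The generator produces per-voxel mixtures of isotropic mono-exponential
compartments (optionally exact orientation-averaged axially symmetric
tensors, or per-voxel diffusivities), with smooth spatially varying volume
fractions, on arbitrary shell grids. Noise is added to each simulated volume
*before* shell averaging, so the variance model `sigma^2 / n_s` that the
sensitivity analysis assumes holds by construction. The neonatal-like preset
uses four compartments with diffusivities 0.7, 1.3, 2.2 and
3.0 x 10^-3 mm^2/s — spanning the high-MD, low-anisotropy regime of the
neonatal brain — on the six-shell pilot grid (b = 0, 500, 1000, 2000, 3000,
4000 s/mm^2; 5 + 5x50 volumes), with SNR 30 at b = 0 by default. A Rician
option (magnitude of complex Gaussian) exists to demonstrate noise-floor
bias, but the analytic machinery assumes Gaussian noise and the Rician mode
is never used to validate it.

Passing tests on these phantoms demonstrate the estimator's correctness —
propagation formulas, allocation optimality, search convergence — under the
stated noise model. They do not demonstrate robustness to what real data add:
motion and eddy-current residuals, spatially varying noise, Rician bias at
very low SNR, exchange/kurtosis effects beyond multi-exponential decay, and
cross-subject variability. Effect-size spectra from the preset decay more
steeply than typical in vivo spectra, so CNR values on phantoms are
illustrative, not predictive.

## Problem sizes

The test-suite and acceptance computations run on deliberately small
instances chosen to exercise every code path at high numerical precision:
phantoms of 100–400 voxels (10 000 for the variance checks), budgets of
30–300 volumes, exhaustive allocation enumeration at `N_total = 30` over 2–4
shells, Monte-Carlo checks at 20 000 draws, 60-direction sets for the
angular pipeline, and a 1 s/mm^2 grid oracle for the one-shell search.
Results are invariant to scaling `N_v` up: fractions depend only on `H` and
`eps`, which stabilise quickly with voxel count.

## Design choices where the design was open

- **All-components default, rank-capped.** The number of retained components
  defaults to the candidate shell count, capped at the measured data's
  numerical rank (singular values above 1e-10 of the largest). Without the
  cap, noiseless synthetic data make the objective chase float-level
  components.
- **Raw means, no normalisation.** The matrix `D` enters the SVD in signal
  units, un-normalised by b = 0; an optional normalisation was considered
  and rejected as the default because effect sizes are then no longer in
  acquisition signal units.
- **No Rician-bias correction of shell means**; the analysis assumes the
  Gaussian regime.
- **Angular minima as hard constraints.** Minimum direction counts from the
  angular analysis are applied as floors during integerisation (a repair
  step after b-value optimisation), keeping counts as close to optimal as
  the floors allow.
- **b = 0 is a shell.** b = 0 volumes are grouped and averaged like any
  other shell and take part in the allocation.
- **CLI as thin wrapper.** The `inst/cli/shellopt` script only parses flags
  and calls the exported functions; YAML config files are supported with
  flags taking precedence.

## Known limitations

- The TE model omits slew rates, EPI readout, and spin-echo symmetry;
  absolute TEs (hence attenuations) are approximations specific to this
  skeleton.
- The b-value search optimises the radial objective only; angular
  information enters solely through the minimum-direction floors. For
  high-anisotropy (adult) data a joint radial–angular treatment would be
  preferable.
- Detectability uses a fixed 95th-percentile floor; borderline orders near
  the floor flip with the assumed `sigma`, which is therefore always
  reported alongside the result.
- For exactly degenerate singular spectra the component ordering (and hence
  the sign rule's outcome) follows the LAPACK solver.
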