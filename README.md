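# shellopt

Data-driven design of multi-shell diffusion MRI acquisition protocols.

## The problem

A multi-shell diffusion MRI protocol is defined by the number of b-value
shells, the b-value of each shell, and the number of diffusion-weighted (DW)
directions sampled on each shell. Scan time fixes the total number of volumes
`N_total`, so these choices trade off against each other, and protocols tuned
to one reconstruction model are not guaranteed to suit another. `shellopt`
implements a model-agnostic alternative: measure the information content of
pilot data directly, and pick the acquisition parameters that maximise
sensitivity to the effects actually present in the signal. It was designed
with neonatal imaging in mind (high diffusivity, low anisotropy, strong
spatial variation), but applies to any cohort with suitable pilot data.

## The method

Starting from densely sampled pilot data (many shells, many directions):

1. **Shell means.** For each shell `s`, average the DW signal over directions
   within a brain mask, giving the `N_s x N_v` matrix `D` of per-shell,
   per-voxel means (rotationally invariant for dense uniform sampling).
2. **Signal basis.** Compact SVD, `D = U S V' = H W`, yields an orthonormal
   basis `H` over b-values and per-voxel weights `W = S V'`. The effect size
   of component `c` is `eps_c = S_c / sqrt(N_v)`, the RMS weight across the
   brain.
3. **Error propagation.** With i.i.d. Gaussian measurement noise `sigma`, the
   shell mean has variance `sigma^2 / n_s`, and the coefficient covariance is
   `Sigma_w = sigma^2 H' diag(1/n_s) H`. The coefficient of variation is
   `CV_c = sqrt(Sigma_w(c,c)) / eps_c` (the reciprocal of the component's
   CNR), and the protocol objective is `SSCV = sum_c CV_c^2`.
4. **Volume allocation.** Minimising SSCV subject to `sum n_s = N_total` has
   the closed-form Lagrange solution `n_s* ∝ sqrt(sum_c (H_sc / eps_c)^2)`;
   the resulting per-shell *fractions* are independent of `sigma` and
   `N_total`.
5. **b-value search.** Candidate b-values are evaluated by monotone (PCHIP)
   interpolation of the measured means, re-decomposition, allocation, and
   SSCV; a multi-start Nelder–Mead simplex in log-b finds the optimal shell
   b-values for a fixed shell count.
6. **Echo-time penalty.** The maximum b-value dictates the minimum echo time
   of a PGSE sequence (square gradients packed around a 5 ms refocusing
   window, 5 ms pre-delay, 15 ms post-delay, 80 mT/m); effect sizes are
   attenuated by `exp(-TE/T2)`, penalising needlessly high b-values.
7. **Angular sufficiency.** Independently, spherical-harmonic analysis of
   single-fibre voxels determines the highest detectable angular order `l`
   per shell; `(l+1)(l+2)/2` is the minimum direction count, enforced as a
   per-shell floor when integerising the allocation.

A synthetic phantom generator (multi-compartment b-value decay, spatially
varying fractions, Gaussian/Rician noise, direction-resolved tensor signals)
provides ground truth for every step.

## Worked example

```r
library(shellopt)

# pilot data: neonatal-like phantom on the 6-shell pilot grid, noiseless
cfg <- neonatal_like_preset(n_voxels = 400, sigma = 0)
ph  <- make_shell_means(cfg)

# design a b=0 + 3-shell protocol: 300 volumes, SNR(b=0) = 30, T2 = 150 ms
p <- optimise_protocol(ph$data, n_shells = 3, n_total = 300,
                       snr_b0 = 30, t2 = 150, seed = 1)
print(p)
```

```
Optimised multi-shell protocol: b=0 + 3 shells, 300 volumes
                 shell0 shell1 shell2 shell3
b-value (s/mm^2)      0    411    986   2960
fraction (%)          5     23     33     39
volumes              16     69     98    117
TE = 63.2 ms, T2 attenuation = 0.656 (T2 = 150 ms)
CNR per component: 102, 4.96, 0.884, 0.147
SSCV = 47.8388
```

Reading the output: the search keeps a low shell near `b = 411 s/mm^2` (well
below `1/MD` of the phantom, where the first components separate best),
intermediate and high shells at 986 and 2960 s/mm^2, and allocates the
largest share of volumes to the highest shell, whose low SNR needs the most
averaging. The echo time implied by the maximum b-value attenuates all effect
sizes by 0.656 at T2 = 150 ms; CNR is reported per basis component at the
integer counts. (Exact numbers depend on the phantom's compartments, noise
and seed.)

The angular side:

```r
dwi  <- make_dwi(phantom_config(
  n_voxels = 60,
  compartments = list(list(ad = 1.9e-3, rd = 0.4e-3)),
  bvalues = c(0, 1000, 2500), counts = c(4, 30, 40), sigma = 0))
spec <- cmd_angular(dwi$dataset, sigma = 0.05)
#> detectable order 4 -> minimum 15 directions (sigma = 0.05)
```

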