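---
title: "Low-rank plus sparse reconstruction of dynamic MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank plus sparse reconstruction of dynamic MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktlps)
```

## The model

A dynamic (2D+time) MR acquisition measures, frame by frame, a subset of
the spatial Fourier coefficients of the image series:

$$ Y = R\,F\,X + n, $$

where $X$ is the unknown complex image series, $F$ the per-frame 2D
Fourier transform, $R$ the binary sampling mask, and $n$ complex Gaussian
measurement noise. Stacking each frame as a column gives the Casorati
matrix $X \in \mathbb{C}^{n_x n_y \times n_t}$. Two structural
assumptions make recovery from undersampled data possible:

* **temporal redundancy** — the quasi-static background (anatomy,
  coil shading, slow drift) spans a low-dimensional temporal subspace, so
  the background contribution to the Casorati matrix has low rank;
* **sparse dynamics** — the frame-to-frame changes are confined to a
  small spatial region (the moving heart in a cine), and periodic motion
  becomes sparse after a temporal Fourier transform (x-f space).

The reconstruction model decomposes $X = A + E$ and solves the RPCA
program

$$ \min_{A,E} \; \|A\|_* + \lambda \,\|T E\|_1
   \quad \text{s.t.} \quad X = A + E, $$

with $T$ the sparsifying transform along time. Some formulations weight
the two terms separately ($\lambda_L \|A\|_* + \lambda_S \|TE\|_1$); the
solver exposes the single ratio $\lambda$, absorbing the overall scale
into the penalty schedule, which is equivalent up to reparameterization.

## The IALM solver

`ialm_rpca()` minimizes the augmented Lagrangian

$$ \|A\|_* + \lambda\|TE\|_1 + \langle \mathcal{L},\, X - A - E\rangle
   + \tfrac{\mu}{2}\|X - A - E\|_F^2 $$

by alternating exact proximal steps with an inexact (single-pass) sweep
per penalty value:

1. $A \leftarrow \mathrm{SVT}_{1/\mu}(X - E + \mathcal{L}/\mu)$ —
   singular value soft-thresholding, the proximal operator of the nuclear
   norm;
2. $E \leftarrow T^{-1}\,\Lambda_{\lambda/\mu}\!\big(T(X - A +
   \mathcal{L}/\mu)\big)$ — complex soft-thresholding (magnitude
   shrinkage, phase preserved) in the transform domain;
3. $\mathcal{L} \leftarrow \mathcal{L} + \mu (X - A - E)$;
4. $\mu \leftarrow \rho\,\mu$.

The penalty grows geometrically, $\mu_k = \mu_0 \rho^k$; a nondecreasing,
not-too-fast-growing $\{\mu_k\}$ guarantees convergence of $(A_k, E_k)$
to an optimum, and step 3 makes the identity
$X - A_k - E_k = (\mathcal{L}_k - \mathcal{L}_{k-1})/\mu_{k-1}$ hold
exactly; the implementation records the per-iteration deviation from this
identity (`feasibility_gap`) so tests can assert it at $10^{-10}$.

### Parameters

| parameter | default | units / meaning |
|---|---|---|
| `lambda` | $\max(n_x n_y,\, n_t)^{-1/2}$ | dimensionless sparsity weight; the classic RPCA scaling for an $m \times n$ matrix is $\max(m,n)^{-1/2}$ |
| `mu0` | $1.5 / \|X\|_2$ | initial penalty; inversely proportional to the data scale, so iterations are scale-invariant |
| `rho` | 1.2 | geometric growth of $\mu$; larger is faster but less accurate per sweep |
| `tol` | $10^{-7}$ | stop when $\|X - A - E\|_F / \|X\|_F$ drops below it |
| `max_iter` | 500 | safety cap; exceeding it flags the result instead of erroring |
| `transform` | `temporal_fourier` | unitary FFT along each pixel's time course; `identity` for generic RPCA |

The multiplier is initialized to $X / \max(\|X\|_2,\,
\lambda^{-1}\|X\|_\infty)$ (a dual-feasible scaling of the data, the
standard IALM start) and $E_0 = 0$. Singular values exactly equal to the
threshold shrink to zero — no special-casing. The SVD is computed in full
at double precision; problem sizes in this package (thousands of rows by
tens of columns) make the thin SVD the dominant but entirely tractable
cost.

### From decomposition to reconstruction

Applying RPCA directly to the zero-filled image $X^0 = F^{-1} R^T Y$
("plain" mode) converges to $A + E \to X^0$: feasibility is the
constraint, so a fully converged decomposition returns the zero-filled
image unchanged, merely split into parts. Plain mode is therefore useful
for the background/dynamic separation itself (run `decompose` on fully
sampled data), not for removing aliasing.

The default `data_consistency` mode alternates two operations:

* a **truncated** decomposition of the current iterate — capped at
  `dc_inner_iter = 5` IALM iterations, where $\mu$ is still small and the
  thresholds $1/\mu$, $\lambda/\mu$ still strong, so $A+E$ is a strongly
  regularized (low-rank + sparse) approximation rather than a feasible
  copy;
* a **data-consistency projection** in k-space — the Fourier transform of
  $A+E$ has its sampled entries replaced by the measured values (hard
  replacement for noiseless data; the weighted average
  $(F\hat X + w\,y)/(1+w)$ with `dc_weight` $w$ when noise was recorded,
  so the measurements are trusted but not copied verbatim).

The outer loop stops when the iterate changes by less than `dc_tol`
($10^{-4}$) in relative Frobenius norm, or after `dc_iter = 20` rounds.
The returned reconstruction is the data-consistent iterate, which makes a
fully sampled noiseless acquisition reproduce the ground truth exactly.
The truncation depth is the one genuinely free design choice in this
loop: running the inner solver to convergence provably fixes the loop at
the zero-filled image (both modes are kept precisely so this is
inspectable), while a cap of a few iterations turns the alternation into
a projection-like scheme between the regularized set and the
data-consistent set. Five inner iterations with $\rho = 1.2$ leaves the
effective thresholds within a factor $\rho^5 \approx 2.5$ of their
initial values, and the outer loop re-estimates $\mu_0$ from each new
iterate, so no manual threshold tuning is needed.

## Sampling masks

Two trajectories are generated on the Cartesian k-space grid, both
deterministic given their seed and both guaranteed to contain the DC
sample in every frame:

* **Cartesian variable-density lines** — the readout direction is fully
  sampled; `round(ny / R)` phase-encode lines are kept per frame, a
  central band of `center_fraction` (default 1/32) of the lines always
  included, the rest drawn without replacement with probability
  proportional to a zero-centered Gaussian over $k_y$ of width $n_y/6$.
  No standard variable-density law exists; this Gaussian profile with a
  guaranteed center band is common CS-MRI practice. The sampling ratio is
  exactly `round(ny/R)/ny` regardless of the seed. Note that
  `round(256/6) = 43` lines gives 16.8%, so quoted ratios at odd
  accelerations reflect the rounding of the line count.
* **Pseudo-radial spokes** — `n_spokes` straight lines through the
  k-space center at equally spaced angles over $[0, \pi)$, sampled at
  unit radial steps and rounded to the nearest grid cell. Spokes are
  thereby confined to the inscribed disc of the grid (the usual
  pseudo-radial convention); the alternative — stepping along the
  dominant axis so spokes reach the grid corners — yields noticeably
  higher ratios (0.267 instead of 0.251 for 74 spokes on a 256 grid) and
  was rejected for that reason. 74 spokes on a 256×256 grid sample about
  25% of k-space.

Masks vary per frame by default (`vary_per_frame = TRUE`): temporal
incoherence of the aliasing is what lets the temporal model separate
artifact from signal. Cartesian frames redraw their random lines; radial
frames rotate the spoke set by $(\pi/n_\text{spokes})\,(t-1)/n_t$, with a
golden-angle scheme available.

## Encoding and noise

The Fourier operator is unitary and centered (DC at `floor(n/2)+1`), so
Parseval holds exactly, the adjoint equals the inverse on fully sampled
data, and the noise level has the same meaning in k-space and image
units. Complex Gaussian noise of standard deviation $\sigma$ is added
independently to the real and imaginary parts of **sampled** locations
only — noise models the measurement, and injecting it into never-measured
(zero-filled) entries would be unphysical. With image magnitudes on the
conventional 0–255 scale of 8-bit grayscale, $\sigma = 15$ corresponds to
roughly 6% of peak — the noise condition used in the noisy scenarios.
Whether a quoted $\sigma$ refers to k-space or image units is ambiguous
in general; under the unitary convention the two coincide in energy, and
the convention used is recorded in the data container.

## Quality metrics

`psnr()` implements the energy-normalized form

$$ \mathrm{PSNR} = -10 \log_{10}
   \frac{\|\hat X - X\|_F^2}{\|X\|_F^2}, $$

computed on magnitudes over the whole 2D+t array. This normalizes by
signal energy rather than the squared peak; it is a pure (scale-invariant)
energy ratio, typically several dB below the peak-based value.
`psnr_peak()` provides the conventional peak-based definition so both can
be reported side by side.

`ssim_frame()` computes SSIM with **global** statistics — one mean,
variance and covariance per frame — because the defining formula uses
whole-image moments and no window size; the widespread 11×11
sliding-window variant is available via `method = "window"` for
comparison with other software. Constants are $c_1 = (K_1 L)^2 = 6.5025$
and $c_2 = (K_2 L)^2 = 58.5225$ at the standard $K_1 = 0.01$,
$K_2 = 0.03$, $L = 255$. Variances use the population convention
(denominator $n$). `ssim_series()` rescales both series to $[0, L]$ by
the reference's maximum magnitude before scoring, preserving relative
frame intensities.

## The synthetic phantom

`generate_phantom()` builds ground truth with the exact structure the
model assumes, so every pipeline stage can be tested against a planted
truth:

* the background $A_0$ is a sum of `background_rank` separable terms —
  orthonormalized smooth spatial maps (an elliptical "torso" first, then
  low-pass-filtered random fields) times orthonormalized smooth temporal
  weights (constant first, then low-frequency sinusoids) — so its
  Casorati rank is *exactly* the planted value;
* the dynamic part $E_0$ is a set of ellipses whose centers translate and
  radii pulsate periodically over the cycle (a beating-ventricle
  caricature); its support is recorded and kept under 15% of voxels, and
  `motion_amplitude = 0` freezes an object entirely so a static object
  adds at most one to the total rank;
* magnitudes are scaled to $\max |X_0| = 255$ and an optional linear
  phase roll makes the data genuinely complex.

What the phantom does *not* emulate: anatomical texture, through-plane
motion, coil sensitivities, relaxation effects, aperiodic motion, and the
approximate (rather than exact) low-rankness of real backgrounds. Tests
passing on the phantom therefore demonstrate the correctness of the
operators and solver under the model's assumptions — not clinical image
quality on real cine data, whose background spectrum decays smoothly
instead of truncating at a known rank.

## Problem sizes and reproducibility

The test and demonstration size is 64×64×16 (a few seconds per
end-to-end run), chosen so the full suite exercises every code path at
desk scale; the generators and solver handle the 256×256×25–30 scale of
real cine series unchanged, just more slowly. Planted-recovery
experiments use the standard 100×100, rank 5, 5%-support configuration
with $\lambda = 100^{-1/2}$. Every stochastic component (mask draws,
phantom geometry, noise) takes an explicit integer seed, and the pipeline
derives per-stage seeds from one global seed
(`stage_seed(seed, stage)`), so whole runs are bit-reproducible from
their manifest.

## Known limitations

Single-coil Cartesian-grid data only (no sensitivity maps, no off-grid
trajectories with gridding/NUFFT); the full SVD per iteration, while
exact, is the runtime bottleneck at clinical matrix sizes; the
data-consistency loop's truncation depth is a heuristic — principled but
not adaptive; and the energy-normalized PSNR must not be compared
numerically against peak-based PSNR values from other toolboxes without
the offset `psnr_peak() - psnr()`.
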