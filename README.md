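# ktlps

Low-rank plus sparse reconstruction of dynamic MRI from undersampled
k-t space data.

## The problem

Dynamic MRI acquires a 2D image series frame by frame in k-space (the
spatial-frequency domain), and sampling speed limits the achievable
spatio-temporal resolution. Acquiring only a fraction of k-space per frame
accelerates the scan, but naive (zero-filled) inversion of undersampled
data produces aliasing artifacts. A dynamic series is highly redundant,
though: stacking the frames as columns of a *Casorati matrix*
`X ∈ C^(nx·ny × nt)` exposes the redundancy as (approximate) low rank, and
the frame-to-frame changes — the beating heart in a cardiac cine — as a
spatially sparse component.

`ktlps` models the acquisition as

    Y = R F X + n

with `F` the per-frame (centered, unitary) 2D Fourier transform, `R` the
binary sampling mask, and `n` complex Gaussian noise, and reconstructs `X`
through the robust principal component analysis (RPCA) decomposition

    X = A + E,    minimize  ‖A‖* + λ ‖T E‖₁  subject to  X = A + E

where `‖·‖*` is the nuclear norm (low-rank background `A`), `‖·‖₁` the
elementwise ℓ₁ norm of the sparse dynamic component `E` under a
sparsifying transform `T` (the temporal Fourier transform by default, so
periodic motion is sparse in x-f space), and `λ = max(nx·ny, nt)^(-1/2)`.

The decomposition is solved by inexact augmented Lagrange multipliers
(IALM): with multiplier `ℒ` and growing penalty `μ_k = μ₀ ρ^k`
(`μ₀ = 1.5/‖X‖₂`, `ρ = 1.2`), each iteration applies singular value
thresholding `A ← SVT_{1/μ}(X − E + ℒ/μ)`, complex soft-thresholding
`E ← T⁻¹ Λ_{λ/μ}(T(X − A + ℒ/μ))`, and the multiplier update
`ℒ ← ℒ + μ(X − A − E)`, stopping when `‖X − A − E‖_F/‖X‖_F < 10⁻⁷`.
For undersampled data an outer loop alternates a deliberately truncated
decomposition with a k-space data-consistency step that restores the
measured samples (see the methods vignette for why the truncation is
essential).

The package also provides the two undersampling trajectories used to
simulate accelerated scans (variable-density Cartesian phase-encode lines
and pseudo-radial spokes), the energy-normalized PSNR and global SSIM
quality metrics, a synthetic dynamic phantom with exactly planted rank and
sparsity, and a seeded end-to-end pipeline with a thin command-line front
end (`inst/cli/lps-dmri`). It is aimed at MRI reconstruction researchers
who want a compact, fully testable reference implementation.

## Worked example

```r
library(ktlps)

ph   <- generate_phantom(phantom_config(seed = 7))        # 64x64x16, rank-3 background
mask <- radial_mask(mask_spec("radial", 64, 64, 16, n_spokes = 18, seed = 11))
mask
#> <sampling_mask> radial, 64 x 64 x 16, ratio 0.2479

y   <- forward(ph$X0, mask)                               # simulate acquisition
rec <- reconstruct(y)                                     # L+S with data consistency

psnr(rec$zero_filled,    ph$X0)   #> 18.11 dB
psnr(rec$reconstruction, ph$X0)   #> 27.62 dB
sparse_overlap(rec$E, ph$E0, ph$dynamic_support)  #> 0.99
```

With 18 radial spokes per frame (~25% of k-space, a fourfold
acceleration), the zero-filled baseline scores 18.1 dB while the low-rank
plus sparse reconstruction reaches 27.6 dB — the streaking artifacts are
removed and the recovered sparse component matches the planted moving
objects with correlation 0.99 over their support. Per-frame quality is
available as `ssim_series(rec$reconstruction, ph$X0)` (here ≥ 0.998 in
every frame), convergence diagnostics as `tidy(rec$decomposition)` /
`glance(rec$decomposition)`, and images as
`autoplot(rec$reconstruction)`.

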