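---
title: "Respiratory motion-registered whole-heart 3D T2 mapping: models and methods"
author: "cardiot2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory motion-registered whole-heart 3D T2 mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Myocardial edema and inflammation prolong the T2 relaxation time, so
quantitative T2 maps are used to detect acute myocardial injury. Routine 2D
T2 mapping acquires a few thick breath-held slices; focal disease can be
missed between slices or diluted by partial-volume averaging across an
8 mm slice. A free-breathing, isotropic whole-heart acquisition avoids both
problems, at the cost of having to deal with respiratory motion and heavy
undersampling.

`cardiot2` implements the complete processing chain for such an
acquisition — three ECG-triggered T2-prepared 3D radial bSSFP volumes with
spiral-phyllotaxis readouts and superior–inferior (SI) self-navigation —
together with a Bloch simulator and a dynamic numerical phantom, so every
stage can be exercised and validated without scanner data.

# The acquisition model

## Pulse sequence

Each interleave consists of an ideal T2 preparation (tip-down, refocus,
tip-up: longitudinal magnetization is scaled by $e^{-\tau/T_2}$ and the
transverse remainder is crushed), a $-\alpha/2$, TR/2 catalyzation, and a
49-pulse bSSFP train with alternating $\pm\alpha$ pulses (TR 2.6 ms, TE
1.3 ms, $\alpha = 35^\circ$), preceded by one SI navigator readout.
Interleaves are acquired every other heartbeat; the remaining time of the
two RR intervals is free T1 recovery. The three preparation durations
(0/30/60 ms) are acquired as sequential blocks of 112 interleaves:
112 interleaves × 3 preparations × 2 heartbeats = 672 heartbeats, 11.2 min
at 60 bpm.

`simulate_interleave_signal()` iterates the magnetization through this
schedule with exact per-TR rotation/relaxation operators. The *apparent
signal* of a prepared volume is the mean transverse magnitude over the
readout train (every 3D radial line crosses the k-space center, so image
contrast reflects the train average), averaged over interleaves after
discarding the first 10% (approach to steady state). Both choices are
configurable (`signal_mode`, `discard_fraction`).

A consequence of simulating the *complete* schedule is worth spelling out.
At full T1 recovery the apparent signal is exactly affine in
$e^{-\tau/T_2}$ (the train is a linear operator on the entering
magnetization), so the three-parameter fit recovers T2 exactly — this is
why the offset model is the right fit for this sequence. At realistic
heart rates, however, the magnetization entering each preparation retains
memory of the previous heartbeat: the bSSFP train passes about 70% of its
entering deviation (per-TR transient decay
$E_1\cos^2(\alpha/2) + E_2\sin^2(\alpha/2) \approx 0.9928$, over 49 TRs),
and only part of the loss recovers before the next trigger. The
steady-state magnetization therefore differs across the three preparation
blocks, and the exactly-determined 3-point fit is very sensitive to that
spread: `t2_bias_curve()` predicts an underestimation that grows with
heart rate and reaches roughly −20% at 80–90 bpm for T1/T2 = 1050/50 ms.
A simulation that restarts each preparation from thermal equilibrium (no
cross-heartbeat memory) predicts only a few percent. We deliberately keep
the complete-schedule simulation because it is the physically defensible
model of the *described* sequence; the bias curve should be read as a
property of that model, and the heart-rate dependence it predicts is the
motivation for dictionary-based alternatives discussed in the field.

## Trajectory

`spiral_phyllotaxis()` places $N$ readout directions on the upper
hemisphere with golden-angle azimuths ($\varphi_n = n \cdot 137.508^\circ$)
and a square-root polar profile ($\theta_n = \frac{\pi}{2}\sqrt{n/N}$,
exponent configurable). Interleave $i$ takes every 112th point starting at
$i$, so each interleave spirals pole-to-equator. This profile is
quasi-uniform but not exactly area-uniform: its polar CDF is
$(2\theta/\pi)^2$ rather than $1 - \cos\theta$, i.e. equatorial spokes
carry ~1.6× the solid angle of polar ones. The density compensation
accounts for this (below). Full spokes with an odd number of samples put
one sample exactly at k = 0, which simplifies DC bookkeeping and tests.

## Phantom

`phantom_spec()` describes an axis-aligned geometric thorax: a liver-like
background box (T2 50 ms), an LV blood-pool ellipsoid (T2 250 ms), a
myocardial shell (T2 46 ms, healthy myocardium at 1.5 T), and an optional
septal lesion sphere (T2 60 ms, emulating edema). Respiration is a rigid
translation, SI-dominant with a configurable anterior–posterior fraction;
the default waveform is $A\sin^4(\pi t/T)$ (10 mm, 4 s), which dwells near
end-expiration as real breathing does. Motion is applied as an exact
k-space linear phase, so the forward model commits no interpolation error.
Tissue signals come from the Bloch simulator; coils are smooth complex
Gaussians on the FOV faces normalized to unit root-sum-of-squares; complex
Gaussian noise is seeded and scaled relative to the DC sample
(`noise_sd = 3e-5` by default, which puts the gridded myocardial SNR in
the 10–20 range typical of 1.5 T bSSFP). The default simulated heart rate
is 67 bpm, the healthy-cohort mean for this kind of protocol; it also
keeps the one-interleave-per-2-RR sampling of the breathing waveform away
from rational phase locks that would make motion quartiles ill-defined.

What the phantom does *not* emulate: cardiac contraction (acquisition is
assumed ECG-triggered to quiescence), non-rigid respiratory deformation
(the motion is rigid, although the reconstruction and registration never
see the ground truth), fat signal, off-resonance banding, and flow.
Passing tests on this phantom therefore certify the numerics of the
chain — trajectory, gridding, binning, solver, registration, fitting — not
robustness to every in-vivo confounder.

# Reconstruction

## Gridding and density compensation

The non-uniform Fourier transform is Kaiser–Bessel gridding (oversampling
2, kernel width 5, kernel values from a lookup table) with analytic
deapodization; the adjoint is the exact conjugate transpose of the
implemented forward operator, so adjoint-identity tests hold to rounding
error. Density compensation defaults to Pipe-style fixed-point iteration
($w \leftarrow w / (CC^H w)$ with the gridding kernel), which captures both
the radial $|k|^2$ law and the slight angular nonuniformity of the
phyllotaxis profile, and is normalized analytically (kernel
autocorrelation mass) so the compensated adjoint is amplitude-correct. A
closed-form alternative (`dcf_mode = "radial-analytic"`: shell volumes ×
per-spoke solid angles) is retained; it is cheaper but less accurate on
this trajectory.

## Motion-resolved compressed sensing

SI navigator profiles are PCA-decomposed across interleaves;
the component with the largest spectral-power fraction in the respiratory
band (0.1–0.5 Hz) is the respiratory amplitude. Because the three
preparation blocks have different overall signal levels, the scores are
standardized within each block (breathing statistics are stationary over
the ~4-minute blocks); the sign is set so the densest amplitude cluster —
the end-expiratory plateau — is positive. Interleaves are then split into
four equal-count amplitude bins (balanced undersampling per bin; ties
broken by acquisition order), jointly across preparations.

Each prepared volume is reconstructed per respiratory bin by minimizing

$$\tfrac12 \sum_b \|E_b x_b - y_b\|_2^2
  + \lambda' \sum_{b=1}^{B-1} \|x_{b+1} - x_b\|_{1,\epsilon}$$

with $E_b$ the coil-weighted NUFFT of bin $b$'s lines, a finite-difference
sparsifying transform along the respiratory dimension, and
$\lambda' = \lambda \max|x_0|$ so the printed $\lambda$ (default 0.05) is
data-scale-invariant. Numerical choices, each of which mattered in
practice:

* **Unweighted data term by default, weighted as an option.** Every radial
  spoke crosses DC, so the unweighted normal equations are ill-conditioned
  and conjugate gradients converge slowly in the weakly sampled high
  frequencies — which, with noisy data and a practical iteration budget,
  acts as a benign implicit regularization. `data_weighting = "density"`
  switches to density-weighted least squares ($W^{1/2}E$ and
  $E^H W^{1/2}$, still an exact adjoint pair — the classic iterative-SENSE
  preconditioning): it converges much faster and is the right tool for
  noiseless convergence studies, but on noisy data it emphasizes exactly
  the sparsely sampled frequencies where the noise lives and degrades the
  maps at practical iteration counts. Both behaviors are exercised in the
  tests.
* **Shared pooled initializer.** All bins start from the motion-averaged
  adjoint of the whole prep. A per-bin adjoint start would imprint each
  bin's own undersampling artifacts into weakly determined image
  components that the inter-bin coupling removes only asymptotically.
* **Smoothed l1.** The l1 term uses $\sqrt{|d|^2 + \epsilon^2}$ with
  $\epsilon = 10^{-6} \max|x_0|$, making the objective differentiable for
  the Polak–Ribière+ nonlinear conjugate gradient (Armijo backtracking
  from the exact data-term line minimum; restart on loss of descent;
  15 iterations by default with a $10^{-4}$ relative-objective early
  stop). The objective is asserted non-increasing on every run.
* **In-band evaluation.** Radial trajectories never sample the corners of
  the k-space cube, so reconstruction-accuracy claims in the tests are
  evaluated after masking spectra to the sampled ball $|k| \le k_{max}$;
  out-of-band content is untouched initializer content.

Preparations are reconstructed independently; sharing sparsity along the
relaxation dimension is possible but out of scope here.

## Registration

The registration backend is deliberately self-contained and pluggable:

* **Translation**: whole-volume phase correlation with parabolic sub-voxel
  refinement. The returned field never increases the mean squared
  difference (identity fallback).
* **Non-rigid**: coarse-to-fine block matching (mean-removed,
  Hann-windowed circular correlation per block; low-structure blocks are
  skipped), trilinear interpolation of the coarse field, Gaussian
  smoothing at the control spacing (default 12 mm), followed by a
  demons-style optical-flow refinement. Contract: the warp never increases
  the dissimilarity (identity returned when the improvement is below
  0.1%), and the mean Jacobian determinant is kept within [0.5, 2] by
  scaling the field back if necessary.

Respiratory bins (same contrast) are registered translationally and then
non-rigidly to the end-expiration bin and averaged, recovering the SNR of
the full dataset in one motion-consistent volume per preparation. The
three averaged prepared volumes are then registered to the prep-0 volume
(highest SNR; the choice of reference volume is not uniquely determined,
and prep-0 is the safest anchor). Two precautions matter here:
the transforms are *estimated* on an intensity-scale-matched copy but
*applied* to the original volumes, and the demons stage is disabled across
preparations — an intensity-driven force between volumes of different
contrast trades geometry for brightness and corrupts the decay that the
fit depends on. With plausible inter-prep motion (bulk drift), translation
plus gentle block matching is sufficient and safe.

# Fitting and quality metrics

The voxel-wise model is $S(\tau) = A e^{-\tau/T_2} + B$; the offset $B$
absorbs the T1 recovery during the readout train that makes the apparent
signal affine rather than proportional in $e^{-\tau/T_2}$. With exactly
three preparations the system is exactly determined: T2 solves
$(S_1-S_2)/(S_2-S_3) = (e_1-e_2)/(e_2-e_3)$, a monotone 1D root-finding
problem solved in bulk by vectorized bisection on $T_2 \in [1, 500]$ ms
with $A > 0$ enforced (bounds stabilize the fit; they are the package's
choice, stated here once). Non-decaying or degenerate voxels are masked
invalid rather than raising errors. The two-parameter no-offset model used
by routine 2D mapping is available for comparison. The default validity
mask keeps voxels whose prep-0 magnitude exceeds 5% of the volume maximum.

Quality metrics follow the field's conventions: the regional coefficient
of variation CoV = 100·SD/mean (sample SD), and edge sharpness from
fitting $T_2(x) = a/(1 + e^{-k(b+x)}) + c$ along a line from the
mid-septal myocardium into the LV blood pool, repeated on five adjacent
parallel lines (offsets −2..+2 voxels along the in-plane normal; 0.5-voxel
sampling with trilinear interpolation; lines whose fit fails are dropped,
and fewer than three survivors invalidate the result). k is reported in
mm⁻¹; fits saturating the bound (default 25 mm⁻¹, e.g. on an ideal step
edge) are flagged.

An alternative route — fitting a map inside every respiratory bin and
averaging the aligned maps (`map_bins_then_average()`) — is provided for
comparison with the main register-then-fit route; it trades one fit on
high-SNR volumes for four fits on noisier ones.

# Problem sizes and test design

The package's own studies run at desk scale: unit tests use 16³–32³ grids
with 24–72 interleaves, and the end-to-end phantom study runs at 48³ with
the full 112-interleave, 4-coil protocol — large enough that the
myocardial shell is several voxels thick and the lesion is resolved, small
enough to iterate on. The nominal in-vivo matrix (137³ at 1.6 mm) is a
configuration choice, not a code path: grid size is never hard-coded.
Oracles are kept independent of the implementation (brute-force discrete
Fourier sums, explicit rotation-matrix Bloch composition, Cartesian
k-ball truncation, grid-search fitting).

# Known limitations

* The Bloch model omits slice-profile, off-resonance, B1 inhomogeneity
  and flow; the T2 preparation is ideal (no composite-pulse detail).
* The ECG is perfectly regular; RR variability is out of scope.
* Phantom motion is rigid, so the non-rigid registration is exercised by
  reconstruction-induced differences rather than true tissue deformation.
* The complete-schedule steady-state model predicts a heart-rate-dependent
  T2 underestimation that is substantially larger than what in-vivo
  2D/3D agreement suggests for the physical sequence; see the acquisition
  model section.
* The sharpness metric measures a map gradient; it saturates on ideal
  edges and depends on the interpolation used to sample the line.
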