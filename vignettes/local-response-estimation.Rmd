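---
title: "Joint local response function and ODF estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint local response function and ODF estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loresd)
```

## The model

Diffusion-weighted MRI measures, in every voxel, a signal $S(b, g)$ over
gradient directions $g$ and diffusion weightings $b$. Within the spherical
convolution paradigm the signal is modelled as the convolution of an
axially symmetric *response function* $\mathcal{H}(b, g \cdot n)$ — the
signature of a coherent fibre population — with a *fibre orientation
distribution function* (ODF) $P(n)$. In the real, symmetric, even-order
spherical harmonic (SH) basis of maximum degree $\ell_{\max}$ the
convolution separates per degree into a scaled outer product:

$$ S_\ell = N_\ell \, h_\ell \, p_\ell^\top, \qquad
   N_\ell = \sqrt{4\pi / (2\ell + 1)}, $$

where $h_\ell$ collects the zonal (m = 0) response coefficients per shell
and $p_\ell$ the ODF coefficients of degree $\ell$.

Classical constrained spherical deconvolution fixes a brain-wide response
and solves only for the ODF. This package instead estimates the response
*locally*, in every voxel, as a convex mixture of axially symmetric
Gaussian kernels

$$ G(b, \alpha \mid \lambda_\parallel, \lambda_\perp)
   = e^{-b\lambda_\perp} \, e^{-b(\lambda_\parallel - \lambda_\perp)\cos^2\alpha} $$

placed on a triangular grid of axial and radial diffusivities
($\lambda_\perp \le \lambda_\parallel$, both linearly spaced on
$[0, 4]\,\mu m^2/ms$; 55 nodes at the default 10 per axis). The voxel's
response is $H = S_0 \sum_j f_j G_j$ with fractions $f_j \in [0, 1]$,
$\sum_j f_j = 1$. The mixture spans the standard multi-compartment
building blocks — stick ($\lambda_\perp = 0$), zeppelin
($0 < \lambda_\perp < \lambda_\parallel$), ball
($\lambda_\perp = \lambda_\parallel$) — without fixing the number of
compartments in advance.

The fractions and the ODF are estimated jointly by minimising

$$ \sum_{\ell} w_\ell \bigl\| S_\ell - N_\ell H_\ell(f)\, p_\ell^\top \bigr\|_F^2
   \;+\; \lambda \sum_{\ell > 0} \| H_\ell \|_2^2 $$

subject to simplex constraints on $f$, nonnegative ODF amplitudes
$Qp \ge 0$ on a fixed set of 300 directions, and unit normalisation of
the ODF ($p_{00} = 1/\sqrt{4\pi}$, so $P$ integrates to one). The second
term penalises anisotropic response energy: because an isotropic signal
profile can be explained either by dispersed fibres or by an isotropic
response, the penalty resolves this inherent ambiguity in favour of more
isotropic responses, which indirectly promotes sharp (sparse) ODFs. Unit
ODF normalisation removes the complementary scale ambiguity: the response
carries the signal magnitude, which also makes $\lambda$ independent of
the scanner's intensity scale.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `lmax` | 8 | — | maximum even SH degree (45 coefficients) |
| grid | 10 × 10 on [0, 4] | $\mu m^2/ms$ | kernel dictionary (55 valid nodes) |
| `reg_lambda` | $10^{-3}$ | — | anisotropic-response penalty weight |
| `n_constraint_dirs` | 300 | — | ODF nonnegativity directions (shipped fixture) |
| `rel_ftol` | $10^{-4}$ | — | solver relative function tolerance |
| `d` (intra contrast) | 10 | $ms/\mu m^2$ | radial-diffusivity decay of $W_i$ |
| `fw_threshold` | 2.6 | $\mu m^2/ms$ | free-water indicator cut-off |

## Data-term weighting

The relative scale of the misfit and the penalty depends on how the
coefficient blocks are normalised, and with an orthonormal basis there
are two natural readings. The package weights each $(shell, \ell)$ block
by $w_\ell = 1/(2\ell + 1)$ (its *mean* squared coefficient residual,
`data_weighting = "block_mean"`), so that every degree contributes on the
same footing regardless of block size and the balance against the
per-degree penalty does not change with $\ell_{\max}$ or with the number
of shells — which is what makes a single default $\lambda$ transferable
across acquisition protocols. With this convention, $\lambda = 10^{-3}$
reproduces the reference behaviour of the method on phantoms: the joint
estimator matches or exceeds the fixed-response baseline at moderate and
high SNR, with the rigid baseline becoming competitive at very low SNR. The plain Frobenius reading is available as
`data_weighting = "integral"`; it weights high-degree blocks (which
carry most of the noise) up to 17 times more strongly and consequently
under-regularises noisy fits.

Internally the signal is divided by its mean b = 0 amplitude before
fitting and the scale is restored in the response afterwards; estimates
are therefore exactly equivariant under intensity rescaling.

## Optimisation

The problem is a smooth nonlinear program with linear constraints:
bounds and one equality on $f$, 300 inequalities on $p$. It is solved
with sequential least-squares programming (SLSQP, via \pkg{nloptr}) with
the analytically derived gradient of the objective with respect to all
55 fractions and all 44 degree-$\ge 2$ ODF coefficients ($p_{00}$ is
eliminated by substitution rather than constrained). The solver stops at
a relative function tolerance of $10^{-4}$ by default.

Initialisation is deterministic: uniform fractions ($1/55$ each)
followed by a single constrained-spherical-deconvolution iteration — the
constrained least-squares ODF for the uniform-mixture response, a convex
quadratic program solved exactly (\pkg{quadprog}). Because the per-degree
curvature of that QP is diagonal, it is cheap, and the resulting
ODF/response pair is a stable starting point regardless of the local
microstructure. The full fit is deterministic given its inputs: fits are
reproducible bit-for-bit and independent of thread count or voxel order
in volume fitting.

The nonnegativity directions are a fixed quasi-uniform 300-point set
shipped as a plain-text fixture (generated by deterministic electrostatic
repulsion, antipodally symmetrised, from a Fibonacci-hemisphere start),
so constraint matrices are bit-stable across machines.

## The fixed-response baseline

The comparison method solves the same spherical deconvolution with a
*supplied* (not estimated) white-matter response plus isotropic tissue
compartments (e.g. grey matter and CSF), nonnegative ODF amplitudes and
nonnegative tissue fractions. This is a convex quadratic program, solved
exactly. In the simulation harness the baseline receives the
ground-truth kernel as its white-matter response — the strongest
possible comparator. Its nonnegativity constraint is enforced as a hard
inequality on the same 300 directions as the joint estimator (a
deliberate difference from historical soft-penalty CSD iterations, for
solver uniformity).

## The simulation harness

Phantoms are three-compartment stick/zeppelin/ball voxels. The default
composition uses prototypical white-matter values — fractions
0.45/0.45/0.10, stick axial diffusivity 2.2, zeppelin 2.0/0.7, water 3.0
$\mu m^2/ms$ — and the alternative composition raises the zeppelin
radial diffusivity to 1.4 and the water fraction to 0.3
(fractions 0.3/0.4/0.3). Ground-truth ODFs are apodised deltas: a single
fibre at 0° or an equal-weight 60° crossing. The acquisition scheme
defaults to b = 0, 1000, 2000 s/mm² with 5, 128 and 128 quasi-uniform
directions; Rician noise is applied per volume with
$\sigma = S_0/\mathrm{SNR}$ at SNRs of 50, 20 and 10. Accuracy is
summarised by the angular correlation coefficient (ACC) — the cosine
similarity of the degree-$\ge 2$ SH coefficients — against the
ground-truth ODF, and by the root mean square signal error.

The apodised delta is the antipodally symmetrised square of the
degree-4 Dirichlet kernel, normalised to unit integral: it is exactly
band-limited at $\ell_{\max} = 8$, nonnegative everywhere by
construction, rotation-equivariant, and as sharp as a simple nonnegative
band-limited construction allows. Sharpness matters: the delta's
anisotropic energy sets the effective signal available for ODF
estimation, and a smoothed ground truth makes the phantom conditions
measurably harder than intended (to the point that even a baseline
handed the true response falls short of its reference accuracy).
Smoother tapers (raised cosine in $\ell$, heat-kernel) either fail
nonnegativity outright or trade away sharpness.

What the harness does *not* emulate: spatial structure (every voxel is
independent — no partial voluming, no spatial regularisation to
exploit), preprocessing residuals (motion, eddy currents, Gibbs
ringing), multi-fibre populations with distinct responses within one
voxel (the single-convolution assumption), or exchange and non-Gaussian
diffusion. Passing the simulation suite therefore demonstrates correct
estimation under the model's own assumptions, not robustness to all
in vivo effects.

Problem sizes in the shipped tests and acceptance script — 100 noise
realisations per configuration at SNR 20, and 50 per condition for the
SNR-trend checks — were chosen to keep Monte-Carlo error on mean ACC
below about 0.005 while remaining comfortable to re-run; the reference
experiments use 500.

## Numerical choices

* Zonal projections use 64-node Gauss–Legendre quadrature on
  $\cos\alpha \in [-1, 1]$; exact for polynomial integrands far beyond
  degree 8.
* Sharp kernels (sticks at high b) are not exactly band-limited; their
  degree-8 truncation undershoots zero by up to ~2% of peak amplitude.
  This is a property of the representation, shared by any spherical
  deconvolution at finite $\ell_{\max}$.
* Convex QPs receive a relative ridge of $10^{-12}$–$10^{-8}$ on the
  curvature diagonal for strict positive definiteness.
* Shell grouping merges b-values within 0.1 ms/µm² (100 s/mm²) of a
  shell centre; b below 0.05 ms/µm² counts as b = 0. Inputs with maximum
  b above 50 are interpreted as s/mm² and converted.
* The free-water indicator requires *both* diffusivities at or above the
  threshold (on the triangular grid this reduces to the radial
  condition); the `fw_both` flag exposes the axial-only reading.
* The fractional anisotropy weight at the degenerate node (0, 0) is
  defined as 0, its limiting value, so the anisotropy contrast is total
  on the grid.
* Extra-axonal contrast weights are clipped at zero only when materially
  negative (possible with custom parameters); round-off-scale negatives
  are kept so the intra/extra/free-water partition of unity stays exact.

## Known limitations

* **Regularised noiseless floor.** At the default $\lambda$ the
  objective trades data fit against anisotropic response energy, so even
  noiseless on-model phantoms are not reproduced exactly: the optimum
  keeps a small residual (of order $10^{-3} S_0$, growing with the
  phantom's anisotropic energy) and an ODF slightly sharper than the
  truth. With $\lambda = 0$ recovery is exact to solver precision. This
  is the price of the ambiguity resolution discussed above, not an
  optimisation failure: for on-grid phantoms the fitted objective is
  verifiably below the objective at the exact ground truth.
* At SNR 10 the joint estimator's extra flexibility costs accuracy
  relative to a baseline handed the true response, most visibly for
  crossing fibres and nearly isotropic compositions.
* The mixture representation is degenerate by design (neighbouring
  kernels are highly correlated); individual fractions are not
  interpretable one by one, only through smooth functionals such as the
  contrast maps.
* Contrast maps are qualitative feature maps, not quantitative
  compartment fractions; validating them biophysically would require
  richer acquisitions (multiple diffusion times or echo times).

## A worked fit

```{r example, eval = FALSE}
scheme <- simulation_scheme()                  # b = 0/1/2, 5/128/128 dirs
truth <- ground_truth_config()                 # default WM composition
H <- ground_truth_response(truth, scheme)
p <- ground_truth_odf(60)                      # 60 degree crossing
signal <- add_rician_noise(simulate_signal(H, p, scheme), snr = 20,
                           seed = 1)

fit <- loresd(signal, scheme)
summary(fit)
acc(coef(fit)$odf, p)

baseline <- msmt_csd(signal, tissue_responses(H), scheme)
acc(coef(baseline)$odf, p)
```
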