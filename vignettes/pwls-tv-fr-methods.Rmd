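---
title: "Statistical fan-beam CT reconstruction with feature refinement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical fan-beam CT reconstruction with feature refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwlsfr)
```

## The reconstruction problem

Lowering CT dose by acquiring fewer projection views (sparse-view sampling)
or a reduced angular arc (limited-angle sampling) leaves the linear system
relating the attenuation image $\mu$ to the measured log-transformed line
integrals $y = G\mu + \varepsilon$ badly underdetermined, and filtered
back-projection (FBP) then produces severe streak artifacts. `pwlsfr`
implements a statistical iterative reconstruction for 2-D fan-beam data
that addresses this with three ingredients:

1. a **penalized weighted least-squares (PWLS)** data term
   $\tfrac12 (G\mu - y)^T \Sigma^{-1} (G\mu - y)$, where the diagonal
   $\Sigma$ holds per-ray variance estimates so noisy rays count less;
2. a smoothed **total-variation (TV)** penalty
   $\mathrm{TV}(\mu) = \sum_{s,t}
   \sqrt{(\mu_{s,t}-\mu_{s-1,t})^2 + (\mu_{s,t}-\mu_{s,t-1})^2 + \alpha}$,
   minimized by steepest descent; and
3. a per-iteration **feature-refinement (FR)** step that inspects the
   residual between successive iterates with an SSIM-style local structure
   descriptor and blends back the part of it that looks like structure,
   counteracting the "patchy" staircase artifacts of the
   piecewise-constant TV prior.

One outer iteration is
$$\mu^{n+1} = \mu^n - \tau^n H - \beta_{step}\,\nabla\mathrm{TV}(\mu^n),
\qquad H = G^T\!\left(\Sigma^{-1}(G\mu^n - y)\right),$$
with the exact line-search step
$\tau^n = H^T H \,/\, (GH)^T \Sigma^{-1} (GH)$, followed (for the full
method) by
$$\mu_{new}^{n+1} = P\!\left[\mu^{n+1} + f_t \odot (\mu^n -
\mu^{n+1})\right],$$
where $P$ clamps negative attenuation to zero and $f_t \in [0,1]$ is the
structure descriptor
$$f_t = 1 - \left|\frac{2\sigma_{qp} + C}
{\sigma_p^2 + \sigma_q^2 + C}\right|$$
built from unbiased patch statistics ($\sigma_p$, $\sigma_q$ standard
deviations, $\sigma_{qp}$ covariance) of the fresh iterate $\mu^{n+1}$ and
its Gaussian-blurred copy $\mu_d$. Where blurring changes nothing (flat
regions), $\sigma_{qp} \approx \sigma_p\sigma_q$ and $f_t \approx 0$: the
TV-smoothed value stands. Where blurring destroys detail, $f_t \to 1$ and
the pre-update value is partially restored. The bound
$|2\sigma_{qp} + C| \le \sigma_p^2 + \sigma_q^2 + C$ (Cauchy–Schwarz plus
AM–GM) guarantees $f_t \in [0,1]$; the implementation asserts it on every
call. The first iterate is initialized with FBP.

## The projector pair

`forwardProject()` traces one ray per detector bin through the pixel grid
and accumulates exact intersection lengths (Siddon weights, computed by an
Amanatides–Woo traversal in C++). `backProject()` scatters with the
identical weights from the identical traversal, so the pair is an exact
matrix transpose — the adjoint identity
$\langle Gx, y\rangle = \langle x, G^T y\rangle$ holds to machine
precision (tested at 1e-10 relative). This matters: the line-search
formula for $\tau^n$ is the exact quadratic minimizer only for a true
transpose pair, and the descent guarantee tested in the suite would
silently degrade with an unmatched back projector.

Ray geometry is generated once per scan (`rayTable`, shared with the
analytic ellipse sinogram, so discrete and analytic integrals use
identical rays): the source rotates at the source-to-isocenter distance,
view angle 0 on the +x axis, counter-clockwise, with detector bins either
equiangular on a curved detector (default) or equispaced on a flat one.
Pixel (0, 0) sits at the top-left of a grid centered on the rotation axis.

## Scan presets and grids

Two acquisition families are built in (`makeGeometry`):

* **xcat_sparse / xcat_dense** — a head protocol: 120 (dense: 1160) views
  over 360°, 672 bins, source-to-detector 1040 mm, isocenter-to-detector
  570 mm, curved detector. The protocol does not pin a detector length;
  the preset sizes the arc ($2\,\mathrm{asin}(200/470) \cdot 1040$ mm) so
  the fan inscribes a 200 mm-radius field of view, a typical head FOV.
* **micro_sparse / micro_dense / micro_limited** — a small-animal
  scanner: 225 / 450 / 291 views, 4000 bins on a 50.12 mm curved arc,
  object-to-source 121 mm, object-to-detector 165 mm; the limited-angle
  variant covers 197.88°.

View angles are uniform with spacing `angularRange / nViews` starting at
0, so a full circle has no duplicated view; the same rule is applied to
partial arcs. Default grids (`defaultGrid`) inscribe the fan: 256×256 for
the head system, 512×512 for the micro system, pixel size
$2\,r_{fov}/n$. All experiment scales in the tests (128×128 grids, reduced
bin counts for the limited-angle runs) are chosen as desk-scale versions
of these protocols that exercise every code path.

## The simulator

`makeHeadPhantom()` rasterizes additive ellipse compositions (a
skull-like 10-ellipse head with attenuation in [0, 0.019] mm⁻¹, and an
asymmetric object for limited-angle studies where left-right symmetry
would mask the missing wedge), anti-aliased by 3×3 subpixel averaging.
`analyticSinogram()` integrates the same ellipses in closed form
(ray–ellipse quadratic), giving noise-free data that are *not* the forward
projection of the rasterized image — the 0.5 % discrepancy between the two
at 256×256/672 bins is the discretization the reconstruction honestly
faces, and is itself a tested quantity.

`addTransmissionNoise()` models photon counting: counts
$N_i \sim \mathrm{Poisson}(I_0 e^{-y_i})$, clipped below at an electronic
floor $\varepsilon \ge 1$, give noisy integrals $y_i = \ln(I_0/N_i)$ and
delta-method variance estimates $\sigma_i^2 = e^{y_i}/I_0$ — exactly the
$\Sigma$ the PWLS term expects, with a $10^{-12}$ floor keeping
$\Sigma^{-1}$ bounded. For count means above $10^7$ the Poisson draw uses
a rounded Gaussian (indistinguishable at that scale); this supports
high-flux sanity checks up to $I_0 = 10^{10}$. What the simulator does
*not* model: scatter, beam hardening, detector blur and crosstalk, or the
full nonlinear mean–variance relationship of real low-mA scans. Passing
tests therefore demonstrate correctness of the algorithm under its own
statistical assumptions, not robustness to real-detector physics.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1e-8 | TV smoothing constant (units of $\mu^2$, mm⁻²); keeps the functional differentiable at zero gradient |
| `beta` | $e^{-2} \approx 0.135$ | TV step weight, relative to the data step (see below) |
| `patchSide` | 3 | FR patch, 3×3 balances detection against cost |
| `C` | 1.25e-5 | descriptor stability constant, guards $\sigma_p^2 + \sigma_q^2 \to 0$ |
| `kernelSize`, `sigma` | 3, 1 px | Gaussian degradation; matches the 3×3 patch scale |
| `maxIterations` | 100 | outer budget; runs also stop at relative change < 1e-6 or a zero gradient |
| `I0` | — | incident photons/ray; $10^5$ is the low-dose test condition |

## Numerical and design choices

**TV step scaling.** The update subtracts $\beta_{step}\nabla\mathrm{TV}$
with, by default, $\beta_{step} = \beta\,\lVert\tau^n H\rVert /
\lVert\nabla\mathrm{TV}\rVert$ (`tvStepMode = "scaled"`), i.e. $\beta$ is
the *length of the TV step relative to the data step*, in the style of
adaptive-steepest-descent TV solvers. The alternative reading — $\beta$
multiplying the gradient directly (`"raw"`) — makes the TV step's physical
size $\sim \beta \cdot O(1)$ mm⁻¹ regardless of image scale, because the
TV gradient's entries are bounded ratios of differences. For attenuation
images of magnitude ~0.02 mm⁻¹ a raw step of 0.135 overwhelms the image
and the iteration diverges (measured: RMSE ~0.17 mm⁻¹ after 50
iterations, versus 0.0008 for the scaled form under identical
conditions). Only the relative-step reading makes $e^{-2}$ a sensible,
unit-free smoothing weight, so it is the default; the raw form is kept
selectable and is what the compositional-contract tests pin down.

**TV boundary convention.** The TV sum runs over pixels whose upper and
left neighbors both exist ($(R-1)(C-1)$ terms for an $R\times C$ image);
the gradient is the exact derivative of that sum, each pixel appearing in
up to three terms. This one-sided convention is declared rather than
derived — the functional itself is boundary-agnostic — and the
finite-difference oracle in the tests checks the pair to 1e-5.

**Patch and convolution borders.** Mirror (symmetric) padding everywhere
in the FR step, chosen so constant images are exact fixed points of both
the Gaussian degradation and the patch means. Patch moments use unit-sum
box accumulation with a final division, so constants give exactly zero
variances (and $f_t \equiv 0$) with no floating-point residue.

**Descriptor as printed.** The numerator constant of $f_t$ is the same
$C$ as the denominator's, even though SSIM-family formulas often use a
separate constant in each; no silent correction is applied. With both
images at the same scale the bound argument above goes through unchanged.

**Non-negativity.** Only the FR step clamps ($P$ operator); PWLS-TV
iterates may go negative. The `pwls-tv` method therefore reports possibly
negative backgrounds, exactly as the update rule dictates.

**FBP details.** Equiangular fan-beam FBP: $D\cos\gamma$ pre-weighting,
band-limited ramp kernel modified by $(\gamma/\sin\gamma)^2/2$, FFT
convolution, and $1/L^2$-weighted pixel-driven back projection with the
angular increment as quadrature weight (flat-detector variant with the
$1/U^2$ weight included). Default filter: Hamming-windowed ramp at full
cutoff; pure ram-lak selectable and used by the disk-recovery oracle
tests. Limited-angle data get no Parker weighting or missing-wedge
compensation — FBP is deliberately the naive baseline there.

**PSNR convention.** `psnr()` divides the error sum by $Q-1$ rather than
$Q$ by default (with `convention = "q"` as the documented override).
This nonstandard denominator is kept deliberately for continuity with the
evaluation convention this implementation follows; at the image sizes
involved the difference is below 0.001 dB.

**Storage.** Sinograms (+ variance maps, geometry, seed) are stored as a
self-describing plain-text format (YAML comment header + TSV, exact
double round-trip). Images go to 32-bit TIFF with an affine offset/scale
and the pixel size in a YAML sidecar; values round-trip to better than
1e-5 of the image range.

## What the tests establish

At desk scale (128×128 grids, 50 iterations, defaults above) the suite
and `scripts/acceptance.R` re-derive the method's headline behavior: on a
120-view sparse scan of the head phantom, final RMSE orders as
PWLS-TV-FR < PWLS-TV < FBP and PSNR the reverse, both noise-free and at
$I_0 = 10^5$ Poisson noise with estimated weights; the same ordering
holds on a 197.88°/64-view limited-angle scan of the asymmetric phantom.
The descriptor's edge selectivity, the exact-line-search descent of the
weighted cost, step-size optimality against a golden-section oracle, and
the adjoint exactness of the projector pair are each tested directly.
These are correctness and qualitative-behavior guarantees on synthetic
ellipse data; no claim is made about reconstruction quality on real
scanner data, which would additionally face the physics the simulator
omits.

## Known limitations

* 2-D fan-beam only; no cone-beam, helical or 3-D TV.
* One ray per bin (no detector aperture integration); the analytic
  oracle quantifies, but cannot remove, rasterization bias at edges.
* Steepest descent with exact line search is robust but not fast;
  no ordered subsets or preconditioning.
* The iteration-count and stopping defaults are budget choices, not
  convergence proofs; the cost history in the returned report is the
  tool for judging a given run.
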