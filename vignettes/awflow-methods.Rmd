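---
title: "Pixel-super-resolution phase retrieval with accelerated Wirtinger flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-super-resolution phase retrieval with accelerated Wirtinger flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awflow)
```

## The imaging problem

A lensless on-chip microscope places a sample directly above a pixelated
intensity sensor under coherent illumination. Two things are lost in each
exposure: the phase of the diffracted wavefield (sensors record only
intensity) and the sub-pixel detail (the physical pixels integrate the
intensity over an area much larger than the diffraction-limited feature
size). Both can be recovered computationally from a stack of *diversity
measurements* — here, K exposures taken while a phase-only spatial light
modulator (SLM), optically conjugate to the sample plane, displays K
different known phase patterns.

The forward model for the k-th exposure is

$$ y_k^2 \;=\; S\,\lvert A_k x \rvert^2, \qquad A_k = C\,H\,M_k, $$

where

* $x \in \mathbb{C}^n$ is the complex transmittance of the sample on the
  fine reconstruction grid ($n = N_1 N_2$ samples of pitch $\Delta$);
* $M_k$ is the diagonal phase-only modulation $e^{i\varphi_k}$;
* $H$ is free-space propagation over the sample-to-sensor distance $z$,
  computed by the angular spectrum method as a circular convolution;
* $C$ restricts the field to the $m$-sample sensor window;
* $S \in \mathbb{R}^{d \times m}$, $m = \sigma d$, bins each block of
  $\sigma_1 \times \sigma_2$ sub-pixels into one sensor pixel with
  non-negative weights (all ones by default).

Reconstruction solves the regularized inverse problem

$$ \hat x = \arg\min_x \underbrace{\frac{1}{2K}\sum_{k=1}^{K}
   \bigl\lVert \sqrt{S\lvert A_k x\rvert^2} - y_k \bigr\rVert_2^2}_{F(x)}
   \;+\; \underbrace{\lambda \lVert D x \rVert_1}_{R(x)}, $$

with $D$ the horizontal/vertical finite-difference operator (anisotropic
complex total variation). The amplitude-based (lower-order) fidelity is
used rather than the intensity residual; it is empirically much better
conditioned for gradient methods on this problem class.

## The solver

`awfReconstruct()` runs proximal-gradient iterations with Nesterov
momentum:

$$ v^{(t)} = u^{(t-1)} - \gamma\,\nabla F(u^{(t-1)}), \qquad
   x^{(t)} = \mathrm{prox}_{\gamma R}(v^{(t)}), \qquad
   u^{(t)} = x^{(t)} + \beta_t\,(x^{(t)} - x^{(t-1)}), $$

with $u^{(0)} = x^{(0)}$ and $\beta_t = t/(t+3)$ (`schedule = "nesterov"`;
`"none"` gives plain Wirtinger flow, $\beta_t \equiv 0$). The gradient is
the Wirtinger (conjugate-coordinate) gradient

$$ \nabla F(x) = \frac{1}{2K}\sum_k A_k^H \Bigl[(A_k x) \odot
   S^T\bigl(\mathbf{1} - y_k \oslash \sqrt{S\lvert A_k x\rvert^2}\bigr)\Bigr], $$

implemented matrix-free with FFTs; the real-calculus directional
derivative along $e$ is $2\,\mathrm{Re}\langle \nabla F, e\rangle$, which
is where the factor of two in the admissible step comes from. At
measurement entries where $S\lvert A_k x\rvert^2 = 0$ the fidelity is not
differentiable; we take the bounded subgradient choice $y_k/\sqrt{\cdot}
:= 0$ there, so the residual factor becomes 1. This keeps every iterate
finite and is exact wherever the model intensity is positive (the generic
case for random modulations).

### Step size

Plain Wirtinger flow converges to a stationary point for any fixed

$$ \gamma \;\le\; \frac{2K}{\sum_{k=1}^K \rho\!\left(A_k^H\,
   \mathrm{diag}(s)\,A_k\right)}, \qquad s = S^T \mathbf{1}. $$

`stepSizeBound()` estimates each spectral radius by power iteration on the
Hermitian composition $x \mapsto A_k^H(s \odot A_k x)$. Under the default
unit weights each factor of $A_k$ is non-expansive — $M_k$ is unitary, the
angular-spectrum kernel has modulus $\le 1$ once evanescent frequencies
are zeroed, and $C$ is a restriction — so every $\rho_k \le 1$ and the
bound is at least 2. The solver default `gamma = "auto"` uses
$\min(\text{bound}, 2)$: this reproduces the canonical $\gamma = 2$ for
the modulation-diversity system while remaining safe if a user supplies an
expansive custom operator (e.g. weights rescaled upward). Momentum is used
with the same step; no restart scheme is applied (`awfReconstruct` has no
restart option on purpose — the plain $t/(t+3)$ schedule is the method).

### The TV proximal step

$\mathrm{prox}_{\gamma R}$ is evaluated by projected gradient ascent on
the dual problem (FGP-style): the two dual fields are clipped
componentwise to the complex unit disk and the primal iterate is
$x = v - \gamma\lambda\,D^H p$. Two conventions had to be fixed because
"anisotropic complex TV" admits several readings:

* the $\ell_1$ norm is taken on complex difference *moduli* (magnitude
  shrinkage), not on real and imaginary parts independently — the natural
  complex extension of the real algorithm and the one that is invariant
  to the global phase ambiguity of the problem;
* the boundary rule for $D$ is Neumann (last difference zero), standard
  in the proximal TV literature.

The default is a *single* dual iteration per outer step
(`innerIterations = 1`) with the dual variables warm-started across outer
iterations (`warmStart = TRUE`): at the small $\lambda$ values useful
here, accuracy accumulates across the outer loop at almost no cost. The
dual step size is $1/(8\gamma\lambda)$, from the operator-norm bound
$\lVert D D^H\rVert \le 8$.

### Initialization, stopping, logging

The paperless defaults are deterministic: `init = "flat"` starts from a
constant field of amplitude $\sqrt{\bar{y^2}/\sigma}$ (the mean measured
intensity per sub-pixel), which is scale-matched to the data;
`init = "random"` (seeded) and `init = "backprop"` (mean back-propagated
measured amplitude) are available. The solver runs a fixed budget of
`iterations` steps — convergence curves are the object of interest, and a
fixed budget keeps runs bitwise reproducible. Each iteration logs the
amplitude fidelity and, with `logObjective = TRUE`, the full objective
$F + \lambda\lVert Dx\rVert_1$ at $x^{(t)}$ (one extra forward pass per
iteration; with `logObjective = FALSE` the fidelity at the gradient point
$u^{(t-1)}$ is logged instead, which is free and identical to the $x$
path for plain Wirtinger flow).

## What the synthetic generator emulates

`simulationConfig()` fixes the study conditions; its defaults describe a
realistic modulation-diversity acquisition:

| parameter | default | why |
|---|---|---|
| grid | 256 x 256 | desk-scale working size; all operators are $O(n \log n)$, so larger grids only cost time |
| sigma | 4 x 4 (ratio 16) | severe, realistic under-sampling: a 3.8 um sensor pixel over a ~0.95 um reconstruction pitch |
| K | 8 | the few-measurement regime where regularization matters |
| wavelength | 0.532 um | green laser illumination |
| z | 500 um | on-chip sample-to-sensor distance |
| amplitude, phase | [0.2, 1], [0, pi] | passive, optically thin stained-tissue-like sample |
| modulationSigmaPx | 4 px | anti-crosstalk smoothing at the modulator-pixel scale: one SLM pixel conjugated onto the sample grid spans about 4 reconstruction samples at this binning |
| noise | none / gaussian 40 dB | noiseless for theorem-facing checks; 40 dB intensity SNR for robustness-flavoured comparisons |

The modulation patterns are i.i.d. uniform phase fields, Gaussian-filtered
(circular convolution, matching the periodic boundary model) and rescaled
to span $[0, 2\pi)$. The procedural sample (blobs + bar targets + smooth
phase ramp) stands in for the classical grayscale test images so that the
repository ships no external assets; `makeSample()` equally accepts any
user-supplied image pair. Gaussian noise is additive on *intensity* at a
stated SNR and clipped at zero; Poisson noise scales intensities so the
mean pixel receives a stated photon count.

What the generator does **not** emulate: partial coherence, SLM phase
non-linearity and crosstalk, sensor fill-factor structure (the weight map
is configurable but uniform by default), read noise and dark current, or
model mismatch between the assumed and true $z$/wavelength. Tests passing
on these simulations therefore validate the *algorithmic* claims
(operator correctness, step-size rule, acceleration, measurement
reduction), not end-to-end robustness on experimental data, where
modeling errors typically make all algorithms converge earlier and less
deeply.

## Numerical choices

* FFT convention: unnormalized forward / normalized inverse, DC at index
  (1,1), frequencies $f = j/(N\Delta)$; the kernel semigroup property
  $H_{z_1} H_{z_2} = H_{z_1+z_2}$ is pinned by a test, which fixes the
  convention observably.
* Circular boundaries throughout (unpadded FFTs), matching the stated
  circular-convolution model; reconstruction metrics exclude a border
  margin (default: the binning factors) so wrap-around does not dominate
  error reports.
* Power iteration uses a seeded complex Gaussian start and returns
  $\lVert T v\rVert / \lVert v\rVert$, which approaches the spectral
  radius from below and is monotone up to round-off — so the step-size
  rule errs on the safe side of the bound.
* Degenerate inputs: zero model intensity (subgradient choice above), an
  all-zero measurement stack (valid; fidelity is then the pushed-through
  energy), $z = 0$ and $\sigma = 1$ (identity propagation/binning) are
  all exercised by tests.
* Non-finite iterates raise an error naming the iteration rather than
  silently producing NaN histories.

## Study sizes used by the test suite

The slow end-to-end checks run at the benchmark scale (256 x 256, K = 8
and K = 32, several hundred iterations) and take a few minutes together;
operator-level checks run on 8 x 8 to 16 x 16 grids against dense-matrix
oracles built independently from DFT matrices and explicit selection and
binning rows. Convergence in the acceleration study is declared at a
relative fidelity of $10^{-5}$ — deep enough that the asymptotic rate,
not the initial transient shared by both algorithms, is what is measured.
The regularized measurement-reduction study uses $\lambda = 2\times
10^{-3}$ (the package default after a coarse sweep at 40 dB; useful
values for these conditions span roughly $10^{-3}$ to $10^{-2}$).

## Known limitations

* Only modulation diversity is implemented. The operator interface
  (modulate, propagate, crop, bin, with exact adjoints) admits defocus,
  wavelength or ptychographic diversity, but no such operators ship.
* The TV prox with a single warm-started inner iteration is an
  approximation; at large $\lambda$ raise `innerIterations`.
* No line search, restarting, or preconditioning; no GPU path; the
  propagation kernel assumes a homogeneous medium of unit refractive
  index between sample and sensor.
* The sensor weight map is accepted but not calibrated by this package;
  calibrated non-uniform weights change the step-size bound and
  `stepSizeBound()` accounts for that automatically.
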