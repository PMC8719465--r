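---
title: "Methods: Ogden/QLV forward modelling and multi-rate calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ogden/QLV forward modelling and multi-rate calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdenqlv)
```

## The constitutive model and its assumptions

Soft neural and vascular tissue in this package is treated as
incompressible, isotropic, hyperelastic with linear (quasi-linear)
viscoelasticity. The deviatoric backbone is an N-term Ogden energy in
principal stretches,

$$W = \sum_i \frac{2\mu_i}{\alpha_i^2}\left(\lambda_1^{\alpha_i} +
\lambda_2^{\alpha_i} + \lambda_3^{\alpha_i} - 3\right),$$

written in the convention used by the explicit-FE solver families, under
which the small-strain shear modulus is $\sum_i \mu_i$ — that is why
tabulated $\mu$ columns for this model family can be labelled "shear
modulus". The form is singular at $\alpha_i = 0$, so the package enforces
$|\alpha_i| \ge 0.1$ along with $\mu_i > 0$.

Two homogeneous test modes are supported, each with the hydrostatic
pressure eliminated by its traction-free boundary condition:

* **Simple shear** at engineering shear strain $\gamma$ (plate
  displacement over sample thickness). Its stretch spectrum is
  $(\lambda, 1/\lambda, 1)$ with $\lambda - 1/\lambda = \gamma$, and the
  Cauchy shear stress — identical to the plate shear traction —
  is $\sigma_{12} = \sum_i (2\mu_i/\alpha_i)(\lambda^{\alpha_i} -
  \lambda^{-\alpha_i})/(\lambda + \lambda^{-1})$.
* **Uniaxial tension** at stretch $\lambda \ge 1$, spectrum
  $(\lambda, \lambda^{-1/2}, \lambda^{-1/2})$, with Cauchy stress
  $\sigma_{11} = \sum_i (2\mu_i/\alpha_i)(\lambda^{\alpha_i} -
  \lambda^{-\alpha_i/2})$ and nominal stress $P_{11} = \sigma_{11}/\lambda$.

Both stress formulas equal the derivative of $W$ along their deformation
path ($\sigma_{12} = dW/d\gamma$; $\sigma_{11} = \lambda\, dW/d\lambda$),
a consistency the test suite checks numerically over a parameter grid.

Because the test stresses of homogeneous incompressible deformations do
not depend on the volumetric response, the bulk modulus is carried as
material metadata only (it matters to an FE solver, not to calibration).
Compression, anisotropy, damage and failure are out of scope: high-rate
tests that run to failure inform the fit only through their loading ramp.

## Rate dependence: quasi-linear viscoelasticity

The measured stress under a loading history is the convolution of the
instantaneous elastic stress $\sigma^e$ with the reduced relaxation
function of a Prony series:

$$\sigma(t) = \int_0^t g_R(t-s)\,\frac{d\sigma^e}{ds}\,ds, \qquad
g_R(t) = 1 - \sum_i g_i\left(1 - e^{-t/\tau_i}\right),$$

with $g_i \ge 0$, $\sum_i g_i < 1$ (positive long-term modulus) and
$\tau_i > 0$. Material tables often report decay constants
$\beta_i = 1/\tau_i$; the `prony_series()` constructor accepts either and
stores $\tau$, and reports print both. QLV is applied as a scalar
convolution on the measured stress component of each homogeneous test —
the standard identification idealization; a full tensorial deviatoric
convolution adds nothing for these two modes.

**Integration.** Splitting the kernel as
$g_R(u) = (1 - \sum_i g_i) + \sum_i g_i e^{-u/\tau_i}$ gives
$\sigma(t) = (1-\sum_i g_i)\sigma^e(t) + \sum_i h_i(t)$ with one
exponential internal variable per term,
$h_i(t) = g_i \int_0^t e^{-(t-s)/\tau_i} \dot\sigma^e ds$. On a uniform
grid $h_i$ admits the exact update for piecewise-linear $\sigma^e$,

$$h_i^{n+1} = e^{-\Delta t/\tau_i} h_i^n + g_i\frac{\tau_i}{\Delta t}
\left(1 - e^{-\Delta t/\tau_i}\right)\left(\sigma^e_{n+1} -
\sigma^e_n\right),$$

so the only discretization error on a constant-rate ramp comes from
$\sigma^e(\gamma(t))$ being nonlinear in $t$ within a step. The default of
1,000 uniform steps per ramp makes that error negligible for the strain
levels used here. An independent trapezoidal quadrature of the hereditary
integral (`qlv_stress_quadrature()`) serves as the oracle: the test suite
requires the two to agree within 0.5% of peak stress across all reference
materials and rates, and checks first-order-or-better self-convergence,
the exact elastic limit (empty Prony series), the closed-form solution for
a linear backbone, and causality under history truncation.

## Calibration

`fit_multirate()` fits all rate curves simultaneously by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the stacked residuals

$$r_{c,k} = w_c\left(\sigma_{\text{model}}(\varepsilon_{c,k};\theta,
\text{rate}_c) - \bar\sigma_{c,k}\right), \qquad
w_c = 1/\max_k |\bar\sigma_{c,k}|,$$

where $\bar\sigma$ is the replicate mean curve. The fit target is the mean
curve rather than pooled replicates, matching how averaged test data are
reported; per-curve peak normalization prevents the stiff high-rate curves
(orders of magnitude larger stresses) from dominating the objective.
Optional pointwise inverse-SEM weighting is available but not the default,
since reported SEM bars describe between-sample spread rather than a
trusted error model.

Numerical choices:

* the optimizer works internally in $\log\mu$ and $\log\beta$ (with
  $\alpha$ and $g$ raw) so the search is well-conditioned across the
  roughly ten decades the bounds allow; user-facing bounds are
  $\mu \in [10^{-4}, 10^6]$ kPa, $|\alpha| \in [0.1, 50]$,
  $g \in [0, 0.999]$, $\beta \in [10^{-4}, 10^4]$ 1/s;
* $\alpha$ is restricted to positive values by default (all one-term
  reference materials have positive exponents); a signed switch exists for
  multi-term fits such as two-term muscle-like tissue, where published
  tables can be ambiguous about the $(\mu_i, \alpha_i)$ pairing — that
  mapping is left to the user;
* multi-start (default 16 starts, seed 0): initial points are drawn
  log-uniformly in $\mu$ and $\beta$ and uniformly in $\alpha$ and $g$
  within the bounds, deterministically from the seed; the converged start
  with the lowest residual sum wins, ties broken by lowest start index;
* the model curve is interpolated linearly onto the data strain grid; data
  strains outside the simulated ramp raise an error naming the curve
  rather than extrapolating;
* degenerate inputs fail loudly: constant (all-zero) stress curves cannot
  be peak-normalized, single-rate data with Prony terms warn about weak
  identifiability, and a fit where no start converges raises an error
  carrying per-start diagnostics.

Identifiability at the reference conditions is good: the two fast rates
(durations of milliseconds, far below $\tau$) pin the instantaneous
backbone $(\mu, \alpha)$, while the slow ramp — where the response is
dominated by the quasi-steady term $g\tau\dot\sigma^e$ once $t \gg \tau$ —
pins $g$ and $\tau$. Noiseless round trips on all four viscoelastic
reference materials recover every parameter to well below 0.1%
(machine-precision residuals), and `bootstrap_uncertainty()` provides
percentile intervals by resampling replicates within each rate.

## The synthetic-data generator

`generate_replicates()` emulates the statistical structure of replicated
ramp-test campaigns: per rate, the true QLV curve is computed on a fine
grid and subsampled to a shared 101-point strain grid, and $n$ replicates
are drawn with Gaussian noise of standard deviation $a|\sigma| + b$. The
reference designs are three rates (0.01, 150, 300 1/s) with $n = 6$
replicates for brain shear to $\gamma_{max} = 8/7 \approx 1.14$ (an 8 mm
displacement on a 7 mm sample — the only displacement printed for the
campaign, applied at all rates) and $n = 12$ for vessel tension to
$\lambda_{max} = 1.3$ (a default; failure stretches are not modelled).
Noise defaults are $a = 0.05$ and $b$ equal to 1% of each curve's peak
stress, chosen once as a visually plausible match to published SEM-bar
scales; the defaults are recorded in the generated objects.

The generator reproduces mean/SEM reporting honestly (SEM shrinks as
$1/\sqrt{n}$; the 3-SEM band around the mean covers the truth at the
$t_{n-1}$ rate, about 97% for $n = 6$), but it does not emulate
sample-to-sample geometry variation, heteroscedastic or correlated
replicate noise, preconditioning history, or failure-point scatter.
Passing recovery tests on these data therefore demonstrates that the
pipeline is correct and well-identified at realistic noise — not that any
particular laboratory dataset would yield the same parameters.

## Problem sizes and reproducibility

Forward simulations default to 1,000 integration steps per ramp; fits use
the same forward model, and generated curves carry 101 strain points —
sizes at which the discretization error is orders of magnitude below the
parameter tolerances of interest while a full four-material noiseless
round-trip study runs in seconds. Everything stochastic (replicate noise,
multi-start draws, bootstrap resampling) flows from explicit integer
seeds with the global RNG state restored afterwards, so identical inputs
and seeds give identical results byte for byte.

## Known limitations

* One-term QLV with a single relaxation time cannot represent the broad
  relaxation spectra real brain tissue exhibits; the model family is
  deliberately the one used in the downstream FE context.
* Stress relaxation, creep, cyclic loading and frequency-domain
  conversions are not implemented; only constant-rate ramps are.
* Whether published fitted stresses are Cauchy or nominal is often
  unstated; this package defaults to Cauchy for both modes and exposes a
  `measure = "nominal"` switch, and the choice is recorded in fit
  configurations.
* The material-card dialect is generic and documented, not byte-compatible
  with any specific commercial solver.
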