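---
title: "Simulating NIR spectra of composite samples: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating NIR spectra of composite samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsim)
```

## The problem

In the short-wave infrared (900--2400 nm) the absorbance of a composite
biological sample such as minced meat is dominated by three chromophores —
water, protein and fat — through the overtones and combination bands of
their O–H, N–H and C–H bonds.  If the pure-constituent absorption
coefficient curves $\mu_w(\lambda), \mu_p(\lambda), \mu_f(\lambda)$
(cm$^{-1}$) and the sample's mass fractions $f_w, f_p, f_f$ are known, a
forward model can approximate the sample's spectral signature without
measuring it.  `nirsim` implements two such forward models, the calibration
chain that turns raw hyperspectral camera counts into the reflectance and
pseudoabsorbance the models are compared against, and the agreement
statistics used to judge the approximation.

Both models start from the homogeneous-mixing assumption: the bulk
absorption coefficient is the mass-fraction-weighted sum

$$\mu_a(\lambda) = f_w\,\mu_w(\lambda) + f_p\,\mu_p(\lambda) + f_f\,\mu_f(\lambda),$$

which presumes the chromophores are uniformly distributed (reasonable for a
mince, not for intact muscle) and that each constituent's intrinsic
absorption is unchanged by being mixed.

## Model 1: Beer–Lambert mixing with an exponential scale map

With a known path length $l$, Beer–Lambert absorbance is
$A = \log_{10}(e)\,\mu_a\,l$; stacked over wavelengths and samples this is a
matrix product of the curve matrix with the composition matrix
(`model1_matrix()`).  In reflectance-mode spectroscopy, however, $l$ cannot
be measured, so the matrix is evaluated at an effective unit path and the
absolute absorbance scale is supplied by a map fitted against the measured
spectrum of **one** designated calibration sample (`fit_exp_map()`).

The functional form of that map is a genuine design choice: the source
procedure says only that an "exponential relationship" links computed
$\mu_a$ to measured $A$.  We chose the saturating exponential
$A = a\,(1 - e^{-b\,\mu_a})$ as the default because reflectance-mode
absorbance is bounded (light that cannot penetrate is not registered as
unbounded absorbance), the map must be monotone in $\mu_a$, and it must pass
through the origin.  The unbounded growth form $A = a\,e^{b\,\mu_a}$ is
selectable via `form = "growing"` for comparison.  The fit is ordinary least
squares on the absorbance residuals (not log-absorbance), with positive
bounds on both parameters and starting values $a_0 = \max A$,
$b_0 = 1/\mathrm{median}(\mu_a)$.  `fit_exp_map()` returns a classed model
object with the usual `coef`/`predict`/`fitted`/`residuals`/`plot` methods.

## Model 2: the N-layer plate (Stokes) model

Model 2 accounts for scattering structurally: the sample is idealized as a
pile of $N$ identical homogeneous plates separated by air gaps, lit at
incidence angle $\alpha$, with diffuse, isotropic flux inside each plate.
Per wavelength the chain is:

1. **Refractive index** $n(\lambda) = 1.3696 + 3916.8/\lambda^2 +
   2558.8/\lambda^4$ ($\lambda$ in nm) — an empirical dispersion for
   water-dominated tissue that reproduces reported muscle indices (1.38 at
   632.8 nm, 1.37 at 1341.4 nm).  The nm unit convention is fixed; it is
   validated by those two worked values.
2. **Average transmissivity** `tav(alpha, n)`: the Fresnel transmittance of
   an air/medium interface averaged over both polarizations and over the
   incidence cone $[0, \alpha]$ with projected-solid-angle weighting,
   $t_{av}(\alpha, n) = \sin^{-2}\alpha \int_0^\alpha T(\theta)\sin
   2\theta\, d\theta$, evaluated by 64-node Gauss–Legendre quadrature.  The
   quadrature *is* the definition here (the leaf-optics closed-form
   expression is not used); an index-matched interface ($n = 1$) is
   short-circuited to exactly 1.
3. **Plate transmission** $\theta(k) = (1 - k)e^{-k} + k^2 E_1(k)$, the
   fraction of isotropic diffuse flux crossing one plate of optical depth
   $k$, with $E_1$ the first exponential integral;
   equivalently $2\int_0^1 \mu e^{-k/\mu} d\mu$.  $\theta(0) = 1$ by an
   explicit branch.
4. **Single plate** reflectance/transmittance in closed form from
   $t_{av}(\alpha, n)$, $t_{av}(90, n)$ and $\theta$, identical to composing
   the four interface quantities through the internal multiple-reflection
   geometric series.
5. **Stokes stack**: the closed-form total $R_{N,90}, T_{N,90}$ of $N$
   identical plates, mapped back to incidence $\alpha$ by
   $R_{N,\alpha} = x R_{N,90} + y$, $T_{N,\alpha} = x T_{N,90}$ with
   $x = t_{av}(\alpha,n)/t_{av}(90,n)$, $y = 1 - x$.
6. **Pseudoabsorbance** $A = \log_{10}(1/R_{N,\alpha})$.

Defaults are $N = 25$ layers and $\alpha = 45^\circ$, the assumptions under
which the model family is normally run for granular biological samples;
both are plain tunable parameters of `plate_params()`.

### Numerical choices

- The Stokes ratios involve $b^{N}$ with $b > 1$; they are evaluated with
  numerator and denominator rescaled by $b^{-N}$, so there is no overflow
  even at $N = 10^4$ (the $N \to \infty$ limit $R = 1/a$ emerges
  naturally).
- The conservative case $\rho_{90} + \tau_{90} = 1$ (zero absorption,
  $\theta = 1$) makes the generic ratios $0/0$; it is handled by the exact
  limit $R_N = N\rho/(1 + (N-1)\rho)$, $T_N = 1 - R_N$, which is where the
  energy balance $R + T = 1$ holds with equality.  $\rho_{90} = 0$ (then
  $R = 0$, $T = \tau^N$) and $\tau_{90} = 0$ (then $T = 0$, $R = \rho$)
  have explicit branches too.
- $x = t_{av}(\alpha,n)/t_{av}(90,n) \ge 1$ for $n > 1$, because averaging
  over the narrower cone gives the higher transmissivity; consequently
  $y \le 0$.  This is the correct behaviour of the closed form: at $N = 1$
  the $\alpha$-mapping returns exactly the single-plate $\rho_\alpha$, and
  $R_{N,\alpha}$ stays inside $[0,1]$ for all $N$.
- A reflectance floor of $10^{-6}$ guards the final log; flooring is never
  silent (a warning reports how many wavelengths were affected).
- The per-layer optical depth is $k = s \cdot \mu_a$ with $s$ defaulting to
  1, i.e. the bulk absorption coefficient in cm$^{-1}$ is fed directly into
  $\theta(k)$ as a dimensionless depth.  That is the literal procedure of
  the source method; it amounts to an implicit 1 cm-equivalent effective
  layer thickness with no stated physical justification, so `s` is exposed
  as an explicit scale parameter rather than hidden.

### Verification strategy

Each closed form is tested against an independent oracle rather than
against itself: $\theta(k)$ against adaptive quadrature of the defining
flux integral; the single-plate equations against the Fresnel
interface-composition route; the Stokes closed form against the
adding-doubling recursion that stacks one layer at a time; `tav` against
adaptive quadrature of the polarization-averaged Fresnel transmittance.
The index-matched limit ($n = 1 \Rightarrow \rho = 0, \tau = \theta$),
$N = 1$ identity, monotonicity in $N$ and the energy bound
$R + T \le 1$ close the reconstruction argument for the plate equations,
whose flattened published rendering is typographically ambiguous.

## Hyperspectral calibration

Raw camera digital values (DV) relate to reflectance through per-band gain
and offset; recording white and dark reference images cancels both exactly,
giving $R = (DV_{sample} - DV_{dark})/(DV_{white} - DV_{dark})$
(`calibrate()`), then pseudoabsorbance $A = \log_{10}(1/R)$
(`pseudoabsorbance()`).  The gain/offset cancellation is asserted as an
affine-invariance property test, which stands in for the algebraic
derivation.  Design choices: references recorded as a single line-scan row
broadcast across sample rows; reflectance excursions outside $[0,1]$
(routine under sensor noise) are clipped and counted, never fatal, whereas
a white count not exceeding the dark count is a hard error naming the first
offending voxel; the pipeline order is calibrate → log-transform → average
over the region of interest (the reverse averaging order is available by
calling `mean_spectrum()` before `pseudoabsorbance()` on a reflectance
cube — the two differ only under noise, by Jensen's inequality).
`trim_range()` drops the noisy spectral edges, e.g. keeping 950--1650 nm of
a 900--1700 nm scan.

## Evaluation statistics

For a predicted spectrum $\hat y$ against a measured $y$ over $n$
wavelengths: RMSE with the $n$ denominator; RPD $= \mathrm{SD}(y)/\mathrm{RMSE}$
with the sample SD ($n-1$ denominator) — the denominator inconsistency
between the two formulas is deliberate, because that is how the two
statistics are conventionally defined; and Willmott's index of agreement
$d = 1 - \sum(\hat y_k - y_k)^2 / \sum(|\hat y_k - \bar y| + |y_k - \bar
y|)^2$, with $\bar y$ the *measured* mean in both deviation terms (the
standard Willmott 1981 convention).  The RPD robustness rule is: above 2.0
robust, 1.4--2.0 (inclusive at both ends) intermediate, below 1.4
unreliable.  A perfect prediction has RMSE 0 and is reported with an
infinite-RPD flag rather than an error; a constant measured spectrum is a
degeneracy error since its SD carries no information.

## Synthetic fixtures: what they emulate and what they do not

Real pure-constituent optical constants are not shipped; the generators
build Gaussian-band stand-ins at the canonical NIR band centers — water at
970, 1440, 1920 nm; fat at 930, 1040, 1200, 1715, 1750, 2125, 2300,
2340 nm; protein at 1187, 1510, 1690, 2265 nm — with amplitudes that keep
the realistic ordering (water's 1920 and 1440 nm bands dominating, the
970 nm band weak, fat bands of order 1--10 cm$^{-1}$, protein weakest).
Band widths (18--70 nm) were picked once to look like smoothed NIR
constituent curves.  Compositions default to the fat span 2.49%--80.60%
with protein capped at 22% of mass and water the remainder.  Measurement
noise is additive i.i.d. Gaussian — a stand-in, since no noise model is
prescribed for the instruments — and DV cubes are synthesized at a 12-bit
range with white ≈ 3800 and dark ≈ 120 counts.

Passing tests on these fixtures therefore demonstrate the *mechanics*:
correct closed forms, correct calibration algebra, peak positions inherited
from whichever chromophore dominates, and a full loop (plate-model truth →
1% noise → evaluation) that stays in the robust category.  They do not
demonstrate agreement with measured meat spectra, which depends on real
optical constants, temperature/humidity state, particle size and
compactness — none of which the fixtures model.

## Problem sizes

The default working grid is 900--2400 nm at 5 nm (301 bands; the
hyperspectral fixtures use 950--1650 nm), test cubes are a few hundred
voxels, oracle scans cover $N \in \{1, \dots, 50\}$ layers and ~50 optical
depths, and the fuzz suites use 100--200 replicates — sizes at which the
whole suite runs in seconds while still exercising every branch.

## Known limitations

- Scattering enters only through the structural $N$-plate idealization; no
  phase function, no Monte-Carlo transport, no explicit scattering
  coefficient.
- Inverse retrieval of concentrations from spectra is out of scope.
- Visible-range chromophores (hemoglobin, myoglobin, melanin) are ignored,
  so nothing below ~900 nm should be simulated with these models.
- The molar-extinction form of Beer–Lambert ($A = \varepsilon c l$) is
  documented but not a computation path: no $\varepsilon$ values or
  effective concentrations are available in reflectance mode.
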