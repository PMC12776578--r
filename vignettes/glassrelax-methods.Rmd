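---
title: "Models and methods in glassrelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in glassrelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassrelax)
```

`glassrelax` analyzes the molecular mobility and crystallization
stability of pharmaceutical glasses from broadband dielectric
spectroscopy (BDS), differential scanning calorimetry (DSC),
enthalpy-recovery annealing, and polarized-light-microscopy growth
tracks. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Dielectric relaxation models

A loss spectrum at one temperature is modeled as a sum of
Havriliak–Negami (HN) modes plus a dc-conductivity term,
$$\varepsilon^*(\omega) = \varepsilon_\infty + \sum_k
\frac{\Delta\varepsilon_k}{[1 + (i\omega\tau_{HN,k})^{a_k}]^{b_k}}
- i\frac{\sigma_{dc}}{\varepsilon_0\,\omega^{s}},$$
with $0 < a \le 1$ (symmetric broadening) and $0 < b \le 1$ (asymmetry).
Secondary relaxations (β, γ, δ — in celecoxib: the Johari–Goldstein
process and the two phenyl-ring rotations) are constrained to Cole–Cole
form, $b = 1$, as is standard for local processes; only the structural α
mode may be asymmetric. The conductivity exponent $s$ defaults to 1
(pure ohmic conduction) and is only meaningful when a conductivity term
is explicitly enabled. Every fitted mode is converted to the model-free
time at the loss maximum,
$$\tau_\alpha = \tau_{HN}\,
[\sin(\tfrac{\pi a b}{2+2b})]^{1/a}\,[\sin(\tfrac{\pi a}{2+2b})]^{-1/a},$$
which reduces to $\tau_{HN}$ for Debye and Cole–Cole modes.

**Fit objective.** `fit_spectrum()` minimizes residuals of
$\log_{10}\varepsilon''$ over $\log_{10} f$ by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`), with $\Delta\varepsilon$ and
$\tau$ optimized in log space. Logarithmic residuals are essential here:
the measurement window spans nine decades in frequency and several in
amplitude, and linear-space fitting would let the α peak drown the weak
secondary modes. Consequences: nonpositive loss points are dropped
before fitting, and $\varepsilon_\infty$ (which does not enter
$\varepsilon''$ away from the conductivity term) is recorded from the
template rather than fitted. One $\varepsilon_\infty$ is shared per
spectrum. Nonconvergence is reported through the `converged` flag with
best-effort parameters — never as an exception — so that
temperature-series loops survive individual difficult spectra.

**Continuation across temperature.** Spectra are fitted from a template
that can be the previous temperature's fit, which is the reliable way to
keep mode identities stable as processes shift through the window.
`track_modes()` then associates modes purely by their declared label:
label continuity wins over τ proximity, so two processes crossing in τ
are not swapped. Adjacent-temperature modes of different labels closer
than 0.3 in $\log_{10}\tau$ set an `ambiguous` flag for the analyst; a
label present at fewer than half of the temperatures is dropped with a
warning.

## Temperature laws, fragility, and the Coupling Model

Secondary processes follow the Arrhenius law; `arrhenius_fit()` is
ordinary least squares of $\ln q$ on $1/T$ with $E_a = R\cdot$slope
(kJ/mol). Unit changes of $q$ move only the intercept, so activation
energies are unit-safe. The α process follows
Vogel–Fulcher–Tammann,
$\tau_\alpha = \tau_\infty \exp[D T_0/(T - T_0)]$, fitted on
$\log_{10}\tau$ vs $T$. Two options reflect a genuine ambiguity in the
field: the pre-exponential can be fixed at the conventional
$\log_{10}\tau_\infty = -14$ (keeping $D$ and $T_0$ interpretable), or
left free, in which case it tends to drift to unphysically small values
(around $-16$) while changing the fitted curve little inside the data
range; both modes are supported and neither is canonical. A glass
transition constraint $\tau_\alpha(T_g) = \tau_g$ (default 100 s) is
enforced exactly by eliminating $D = \ln(\tau_g/\tau_\infty)(T_g -
T_0)/T_0$ rather than by penalty.

The Coupling Model links the α process to the Johari–Goldstein
precursor: $\tau_{JG} \approx \tau_0 = t_c^{\,n}\tau_\alpha^{1-n}$ with
$n = 1 - \beta_{KWW}$ and crossover time $t_c = 2$ ps (the accepted
value for small organic glass-formers). The computation runs in the log
domain so extreme $\tau_\alpha$ values cannot overflow.

## KWW shape analysis and the numeric transform

The α-peak shape carries the relaxation-time distribution through the
stretching exponent $\beta_{KWW}$ of $\Phi(t) = \exp[-(t/\tau)^\beta]$.
The loss spectrum of a KWW decay has no closed form, so the one-sided
Fourier transform
$\chi''(\omega) = \int_0^\infty (-\dot\Phi)\sin(\omega t)\,dt$
is computed numerically. Two choices make this robust:

1. **Integration by parts first.** $-\dot\Phi \propto t^{\beta-1}$
   diverges at $t \to 0$ for $\beta < 1$; rewriting
   $\chi''(x) = x\int_0^\infty e^{-u^\beta}\cos(xu)\,du$ (reduced
   frequency $x = \omega\tau$) leaves a smooth, bounded integrand.
2. **Piecewise-linear Filon quadrature on a log grid.** Within each of
   4096 log-spaced intervals the decay is linearized and its product
   with $\cos(xu)$ integrated in closed form. Unlike plain trapezoid
   rules on log grids, this stays accurate when many oscillation periods
   fall inside one interval, i.e. uniformly in $x$. Where
   $x\,\Delta u < 10^{-5}$ the closed form is numerically degenerate and
   an ordinary trapezoid step substitutes.

The implementation is validated against the exact Debye limit
($\beta = 1$: $\chi'' = x/(1+x^2)$, relative error below $10^{-5}$
across the fit window) and against the convergent high-frequency series
$\sum_k \frac{(-1)^{k+1}}{k!}\Gamma(\beta k + 1)\sin(\pi\beta k/2)
x^{-\beta k}$ in the test suite.

`kww_shape_fit()` fits the normalized measured peak
($\varepsilon''/\varepsilon''_{max}$ vs $f/f_{max}$) to the normalized
transform with $\beta$ as the only free parameter — both axes are
anchored by the peak maximum, so no time-scale nuisance parameter is
needed. A peak whose maximum sits on the window edge is refused
(truncated peaks bias $\beta$ downward). Because the transform is fast
(milliseconds per curve), no inter-call caching is required; the fit is a
one-dimensional golden-section search on $\beta \in [0.2, 1]$.

## Master-plot extrapolation below Tg

Below $T_g$ the α peak leaves the measurable window; its time is
extrapolated by time–temperature superposition. The exact published
shifting procedure for this class of experiment is not publicly
documented, so `masterplot_extrapolate()` implements the standard,
clearly-specified variant: normalize each below-$T_g$ loss curve to its
window maximum, shift it in $\log_{10} f$ against the reference model
curve, and minimize the mean squared difference on the shared support
(grid search at 0.01 decade, then parabolic refinement). A shift of $s$
decades gives $\tau_\alpha = \tau_{\alpha,ref}\cdot 10^{s}$. This is a
documented stand-in: it reproduces constructed shifts exactly in the
tests, but its behavior on real spectra whose *shape* changes below
$T_g$ (where superposition itself fails) is necessarily approximate.

## Calorimetric analysis

**Units.** Internally: seconds, Kelvin, SI heat capacities. Laboratory
units (°C, J/(g K), g/cm³, minutes) are converted only at the interface
functions. One deliberate exception: the Arrhenius quantity
$\tau_\alpha^{\beta_{KWW}}$ from enthalpy-recovery fits is computed with
τ in **minutes**. Because $\beta$ varies with temperature, the power
$\tau^\beta$ is not unit-covariant — changing the τ unit changes the
fitted activation energy — and minutes is the convention of the
published tables this package reproduces. The unit is recorded in every
`kww_fit`.

**Glass transition.** `detect_glass_transition()` uses the tangent
construction: linear baselines on the leading/trailing 25% of the
slice, the tangent at maximum derivative, onset/end at the
intersections, midpoint where the signal crosses halfway between
baselines, $\Delta C_p$ as the baseline gap at the midpoint. A step
below $5\times$ the pre-transition noise is rejected. On a noiseless
logistic step of scale $w$ the construction returns width $4w$ and the
exact midpoint; this fixes the generator convention (`width` = tangent
width).

**Donth CRR size.** With onset $T_g$ (not midpoint — the onset is the
temperature at which cooperativity is probed), half the transition width
$\Delta_d T_g$, density ρ and the glass/liquid specific heats,
$$L = \left\{\frac{3 k T_g^2}{4\pi\rho\,\Delta_d T_g^2}
\left(\frac{1}{C_{pg}} - \frac{1}{C_{pl}}\right)\right\}^{1/3}.$$
`crr_size()` converts from laboratory units and reports nm; organic
glasses typically give $L \approx 2$ nm, a plausibility check rather
than a target. The Donth picture itself carries known systematic
uncertainty; trends across compositions are more trustworthy than
absolute sizes.

**Enthalpy recovery.** $\Delta H_\infty = \Delta C_p (T_g - T_a)$ with
$\Delta C_p = C_{pl} - C_{pg}$ unless a sample-specific value is given;
$\Phi = 1 - \Delta H_t/\Delta H_\infty$, fitted by unweighted least
squares (the published experiments give no per-point uncertainties that
would justify weights). Φ values below 0 (over-recovery) abort the fit
with the offending times listed — they indicate an inconsistent
$\Delta H_\infty$, not a fittable data set. Values are never silently
clipped.

**Peaks.** Cold crystallization: feet found where the baseline-corrected
signal falls into the noise ($\max(2\sigma_{noise},\ 0.2\%$ of peak)),
a linear baseline fitted through the slice ends, onset by the
steepest-tangent/baseline intersection, enthalpy by trapezoidal
integration divided by the scan rate (heat flow in W/g, rate in °C/s,
enthalpy in J/g). Absence of a detectable peak returns an empty result,
not an error — a stabilized glass legitimately shows no cold
crystallization. Integration is exactly invariant to adding a linear
ramp. Melting: two Lorentzians
$A w^2/((T-c)^2 + w^2)$ (area $\pi A w$) on a baseline-subtracted
endotherm; the higher-melting component's area share is the Form I
fraction, so Form I and Form III shares sum to one by construction.
Centers collapsing within 0.2 °C flag a degenerate fit and assign the
fraction 0/1 by position. Exothermic sign convention is configurable
(default exo-up) and recorded in each `thermogram`.

## Stability kinetics

Nucleation assays report the exact fraction $k/n$ with a
Clopper–Pearson 95% interval (`stats::binom.test`), and feature
statistics over crystallized replicates only. Growth tracks contribute
least-squares slopes of radius vs time — invariant to time-origin
shifts — summarized by mean and sample (n−1) standard deviation, the
common reporting convention. A two-population split (partial polymer
poisoning of the growth front) uses a one-dimensional equal-variance
Gaussian mixture fitted by EM via `mclust` (model "E"), reported only
when BIC prefers two components over one; `mclust`'s deterministic
hierarchical initialization replaces random restarts. The two-sample
Welch test (`growth_rate_test`) is provided as a descriptive utility
only.

## Synthetic data: what the generators emulate, and what they do not

The generators reproduce the statistical structure the fitters assume:
HN/CC spectra with Arrhenius/VFT temperature laws and multiplicative
Gaussian noise (default 2%, instrument-like constant relative error);
KWW recovery curves with additive noise scaled to $\Delta H_\infty$
(default 3%), floored at 0 and capped at $\Delta H_\infty$ since a
recovery cannot exceed the thermodynamic maximum; thermograms as
logistic step + Gaussian exotherm + Lorentzian endotherms on a linear
baseline with additive noise; linear growth tracks with radius jitter
floored to nondecreasing. Defaults mirror the celecoxib/PVPVA study
conditions (`cel_preset()`: VFT parameters, stretching exponents,
secondary activation energies, KWW tables, melting centers 162/164 °C,
measurement grids), e.g. the standard broadband window $10^{-2}$–$10^7$
Hz and the 4 °C sub-zero temperature spacing.

Passing parameter-recovery tests on these fixtures demonstrates that
the estimators are consistent and correctly implemented *under the
assumed noise model*. It does not demonstrate robustness to what real
instruments add: electrode polarization and Maxwell–Wagner interfacial
contributions at low frequency, baseline curvature and thermal-lag
asymmetry in DSC, drift between repeated runs, or α/β peak shapes that
deviate from HN/KWW. Those effects must be handled upstream (cleaning,
windowing) or judged by the analyst from the residuals the fitters
report.

## Problem sizes and determinism

Every stochastic fixture takes an explicit seed (default 1), and every
generator is bit-reproducible given one. The shipped tests and the
acceptance script use 10 replicate seeds per recovery study,
21-temperature dielectric series at 8 points/decade, thermogram grids of
0.02–0.1 °C, and 8-point recovery curves — sizes chosen to match the
corresponding experiments while keeping a full run in the
tens-of-seconds range. Ten replicates estimate a mean recovery to well
within the tolerances asserted, which are the quantities of interest
here.

## Known limitations

- The master-plot procedure is a documented stand-in (above); shape
  change below $T_g$ is not modeled.
- $\varepsilon_\infty$ is not estimable from loss-only fits; analyses
  needing it must supply it.
- Melting deconvolution assumes exactly two components and a linear
  baseline; melt-recrystallization between the forms would violate the
  independent-melting assumption behind the area-fraction reading.
- The growth-rate mixture split assumes equal variances; with 16
  directions, BIC has limited power to resolve closely spaced
  populations.
- No instrument corrections (calibration, pan effects, electrode
  polarization) are attempted; inputs are assumed pre-cleaned.
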