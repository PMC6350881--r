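---
title: "Modelling protein-bridged nanoparticle aggregation from time-resolved SAXS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein-bridged nanoparticle aggregation from time-resolved SAXS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup, message = FALSE}
library(stickysaxs)
library(ggplot2)
```

## The system and the measurement

Small silica nanoparticles (radii of a few nanometres) are negatively
charged over a wide pH range, while lysozyme — a compact, roughly
ellipsoidal 14.3 kDa protein — is positively charged below pH ≈ 10.  Mixed
in solution, the protein bridges the particles and the suspension
flocculates into large composite aggregates within fractions of a second.
Synchrotron SAXS at millisecond frame rates resolves this process: each
frame is a reduced one-dimensional curve, intensity $I(q)$ in absolute
units (cm$^{-1}$) against momentum transfer $q$ (nm$^{-1}$), usable here
over $0.04 < q < 4.5$ nm$^{-1}$.

When particle and protein are of comparable size, the protein leaves a
measurable imprint on the *structure factor* — the interparticle
correlation peak near $q \approx 1$ nm$^{-1}$ — even though its own
scattering contrast is negligible next to silica.  This package implements
a quantitative model for that situation and the machinery to fit it to
single frames and to long frame series.

## The intensity model

For a discrete size distribution with bin radii $r_i$ and volume fractions
$\phi_i$, the model intensity is a local monodisperse approximation (LMA):
each size class carries its own effective structure factor,

$$ I(q) \;=\; (\Delta\rho)^2 \sum_i \phi_i\, V(r_i)\, P(q, r_i)\,
   S_\mathrm{eff}(q, r_i), $$

with $V(r) = \tfrac{4}{3}\pi r^3$, $P(q,r) = [3(\sin qr - qr\cos qr) /
(qr)^3]^2$ the homogeneous-sphere form factor, and $\Delta\rho$ the
particle–solvent scattering-length-density contrast.  The LMA is exact for
one bin and linear over bins; `model_intensity()` reduces to
`dilute_intensity()` when all structure contributions are switched off.
The treatment deliberately uses two electron densities only (particle and
solvent): at typical concentrations the protein is near contrast-matched
relative to silica, and its effect enters through the structure factor
instead.

Default contrasts are the Thomson SLDs of amorphous silica at
2.2 g/cm$^3$ against water (`contrast_config()`), appropriate for a
10 keV experiment.  Any absolute volume fraction derived from measured
intensities inherits this choice, which is why it is user-overridable.

## Adhesive hard spheres with a protein spacer

Inside an aggregate, particles behave like *sticky hard spheres*: hard
cores of radius $R_\mathrm{HS}$ with a narrow attractive square well of
depth $U$ and width $\Delta$.  The classical Baxter solution in the
Percus–Yevick closure gives a closed-form structure factor
$S_\mathrm{SHS}(q; R_\mathrm{HS}, \nu, \tau)$, implemented in `s_shs()`:

* $\nu$ is the *local* packing fraction of particles within the aggregate
  (not the suspension volume fraction).  For random packing of
  polydisperse spheres it cannot exceed 0.65, which is the hard upper
  bound used everywhere.
* $\tau$ is the stickiness (smaller = stickier).  It is not fitted but
  derived from the well: $\tau = e^{U/k_BT} (2R_\mathrm{HS} + \Delta) /
  (12\Delta)$ with $U = -2.5\,k_BT$ and $\Delta = 0.1 \cdot
  2R_\mathrm{HS}$, floored at $\Delta_\mathrm{min} = 0.15$ nm (an average
  hydrogen-bond length).  With the floor inactive this gives $\tau
  \approx 0.0752$ independent of radius.  Within the physically plausible
  range (wells no deeper than about $-3\,k_BT$) the exact depth barely
  moves the fits, which is why it is frozen.
* The finite well width rescales the packing fraction, $\eta = \nu
  \left((2R_\mathrm{HS}+\Delta)/2R_\mathrm{HS}\right)^3$, before the
  Baxter auxiliaries are evaluated.

Two numerical points deserve mention.  First, the adhesion parameter
$\lambda$ is the *minus* root of the Baxter quadratic,
$\lambda = (6/\eta)\left(\varepsilon - \sqrt{\varepsilon^2-\gamma}\right)$
with $\varepsilon = \tau + \eta/(1-\eta)$: the plus root diverges in the
non-sticky limit.  In that limit ($\tau \to \infty$, $\lambda \to 0$) the
expression collapses to the Percus–Yevick hard-sphere structure factor,
which the test suite checks against an independently coded closed form.
Second, the auxiliary $\gamma = \nu (1 + \eta/2) / (3 (1-\eta)^2)$ is kept
with the *unrescaled* $\nu$ in its numerator, the convention of the
formulation this model follows for finite well widths; for $\Delta \to 0$
it coincides with the textbook $\eta$-form.  Parameter sets for which
$\varepsilon^2 < \gamma$ have no real Baxter solution; the package
pre-screens for this and raises a typed error (the fitter sees a penalty
instead, so optimisation never touches complex arithmetic or silent NaNs).

### The spacer radius and its distribution

With the particle size distribution fixed, the measured correlation-peak
position can only be reproduced if the effective hard-sphere radius
exceeds the particle radius: a bridging protein molecule acts as a spacer,

$$ R_{\mathrm{HS},i} = r_i + aR_\mathrm{eHS}. $$

A single spacer value still leaves the peak too sharp.  Proteins adsorb in
different orientations and deform under local forces, so the spacer is
given a Gaussian distribution with mean $\langle aR_\mathrm{eHS}\rangle$
and standard deviation $\sigma$, and the structure factor is averaged:

$$ \langle S_\mathrm{SHS}\rangle(q, r_i) =
   \frac{\int_0^{\langle aR\rangle + 8\sigma} D_G(R)\,
         S_\mathrm{SHS}(q;\, r_i + R,\, \nu,\, \tau(R))\, dR}
        {\int_0^{\langle aR\rangle + 8\sigma} D_G(R)\, dR}. $$

The well width and the stickiness are recomputed at every integration node
from that node's $R_\mathrm{HS} = r_i + R$, because the width rule is tied
to the hard-sphere diameter.  Smearing lowers and broadens the peak at
constant $\nu$ — which is exactly the shape observed in aggregated frames
and cannot be mimicked by lowering $\nu$ (that would also suppress the
peak intensity).

```{r smearing, fig.alt = "Smeared versus unsmeared structure factor"}
plot_smearing_effect(seq(0.2, 3, length.out = 400), r_i = 2.53,
                     aR_mean = 0.93, aR_sd = 0.53, nu = 0.454)
```

The integral is evaluated with 64-node Gauss–Legendre quadrature
(`n_nodes`, configurable).  The nodes are placed on
$[\max(0, \langle aR\rangle - 8\sigma),\, \langle aR\rangle + 8\sigma]$:
below $\langle aR\rangle - 8\sigma$ the Gaussian is zero to machine
precision, so the integral is unchanged, while the restriction lets the
quadrature resolve arbitrarily narrow distributions — the $\sigma \to 0$
limit reproduces the unsmeared factor to better than $10^{-6}$, against
$\sim 10^{-3}$ if the nodes were spread from zero.

### The aggregate term

The sticky-hard-sphere factor describes correlations of effectively
infinite extent and cannot produce the steep low-$q$ rise of finite
mass-fractal aggregates.  That rise is carried by a power law added per
size class:

$$ S_\mathrm{eff}(q, r_i) = \langle S_\mathrm{SHS}\rangle(q, r_i) +
   A\, q^{-D}, $$

where $D$ is the mass-fractal dimension ($1 \le D < 4$; diffusion-limited
particle–cluster aggregation typically gives 1.8–2.5) and $A$ is a single
collective amplitude proportional to the product of aggregate number
density and specific surface area.  The individual factors behind $A$
(aggregate volume, contrast fluctuation, surface area, number density)
cannot be separated with this $q$ range, which is why they are not
modelled individually.  No finite-size cut-off is included because the
data this model targets do not level off at low $q$.  **Unit convention:**
$A$ absorbs the dimension of $q^{-D}$ with $q$ in nm$^{-1}$; values of $A$
are only comparable under that convention.

## Monte Carlo size-distribution inversion

Before aggregation is triggered, the suspension is dilute and
structure-free, and the curve determines the size distribution.
`mcsas_fit()` implements a form-free accept/reject Monte Carlo in the
spirit of McSAS-type analyses: a population of `n_contributions` sphere
radii (default 200) starts uniform over a prior range (default 0.5–6 nm);
each step proposes replacing one randomly chosen radius with a fresh
uniform draw, re-derives the single overall scale factor analytically by
weighted linear least squares, and accepts the move if and only if the
reduced $\chi^2$ decreases.  Repetitions (default 10) with sub-seeds
`seed + k` give per-bin uncertainties.  Volume fractions follow from the
fitted scale and the contrast; the histogram total equals the fitted scale
exactly by construction.  Bin positions are the $\phi$-weighted means of
the accepted radii within each bin, so the summary statistics of the
binned histogram equal those of the raw chain.

Two practical notes.  The stopping rule is reduced $\chi^2 \le$
`chi2_target` (default 1, the usual convention); on data whose noise model
is slightly imperfect the attainable floor may sit marginally above 1, in
which case the result carries an honest convergence flag in its metadata
rather than an error.  And because acceptance requires a strict decrease,
noiseless curves with tight targets need large proposal budgets (the
proposal acceptance rate decays as the fit sharpens) — `max_iterations` is
the relevant dial.

## Fitting frames and series

`fit_frame()` fits $\theta = (\nu, \langle aR_\mathrm{eHS}\rangle, \sigma,
A, D)$ by bounded Levenberg–Marquardt least squares with the size
distribution held fixed.  Defaults:

| parameter | bounds | units | role |
|---|---|---|---|
| $\nu$ | (0, 0.65] | — | local packing fraction |
| $\langle aR_\mathrm{eHS}\rangle$ | [0, 3] | nm | mean spacer radius |
| $\sigma$ | [0.02, 1.5] | nm | spacer spread |
| $A$ | [0, 10] | (nm$^{-1}$)$^D$ | aggregate amplitude |
| $D$ | [1, 4) | — | fractal dimension |

Residuals use experimental $\sigma_I$ when present and log-intensity
residuals otherwise (they balance a three-decade dynamic range; the choice
is explicit in `fit_config()`).  The default initial point $(0.3, 1.0,
0.4, A_0, 2.4)$ sits mid-trajectory for this class of kinetics, with $A_0$
estimated from the low-$q$ excess over the dilute model.  The optimiser is
deterministic, so fits are exactly reproducible.  An optional global
intensity scale (default frozen at 1) can be freed for data without
absolute calibration; with it, fits are invariant under uniform rescaling
of intensity and uncertainties.

Parameter uncertainties come from the inverse Gauss–Newton normal matrix
at the optimum scaled by the reduced $\chi^2$ — quick and adequate for
well-conditioned fits, approximate in general (replicate studies in the
test suite put the 1-$\sigma$ coverage near, but not exactly at, the
nominal 68 %).  `profile_uncertainty()` offers the robust alternative:
one parameter is stepped while the rest are re-optimised, bounding the
interval at $\Delta\chi^2 = 1$.  On a window that excludes the
correlation peak the packing and spacer parameters become nearly flat
directions and the profile widens accordingly — a useful diagnostic.

`fit_series()` walks a frame series in time order, initialising each frame
at the previous optimum.  Warm starts make per-frame fits of slowly
varying kinetics fast and stable; a stationary series gives the same
answer as independent fits.  Frames before an annotated injection time are
treated as pure form factor ($\nu = 0$, $A = 0$ frozen, no structure
parameters reported).  Individual frame failures are flagged and skipped,
never fatal for the series.  When $\nu$ is very small (the first seconds
after mixing) the structure factor contributes almost nothing and the
spacer parameters are reported with honestly inflated uncertainties — they
become meaningful once $\nu$ exceeds roughly 0.1.

## The synthetic-data generator

`synth_distribution()`, `synth_curve()` and `synth_timeseries()` emulate
the study conditions this model targets and serve as the ground-truth test
bed:

* a narrow lognormal sphere population, volume-weighted mean radius
  2.53 nm (geometric SD 1.15), total volume fraction $4.0\times10^{-4}$
  (0.040 %) — a freshly polymerised sol from a 1000 ppm solution;
* a 400-point logarithmic $q$ grid over 0.04–4.5 nm$^{-1}$;
* counting-statistics-like noise $I_\mathrm{noisy} = I(1 + f\epsilon_1) +
  b\epsilon_2$ with defaults $f = 0.01$, $b = 10^{-4}$ cm$^{-1}$, and
  $\sigma_I = \sqrt{(fI)^2 + b^2}$ — self-consistent in the sense that the
  true model scores reduced $\chi^2 \approx 1$;
* the `composite_trajectory()` preset: $\nu$ rising logistically to a
  0.45 plateau (midpoint 40 s), the spacer mean climbing 0.7 → 0.9 nm
  rapidly and on towards 1.1 nm, its spread 0.35 → 0.5 nm, a
  bound-exponential 4.5-fold rise of $A$ over the first ~20 s followed by
  a slow linear term, and $D$ ramping 1.9 → 2.4.

```{r trajectory, fig.alt = "Kinetic parameter trajectories"}
tr <- composite_trajectory(seq(25, 175, by = 1))
tidyr::pivot_longer(tr, -t) |>
  ggplot(aes(t, value)) + geom_line() +
  facet_wrap(~name, scales = "free_y") + labs(x = "t (s)", y = NULL)
```

Everything is bitwise-reproducible under a seed.  What the generator does
*not* emulate: instrumental resolution smearing, detector artefacts and
dead time, background-subtraction residuals, and the late-stage regime in
which the primary particles themselves grow (there the fixed size
distribution — and with it this model — stops being self-consistent, so
fitted trends for $\nu$ and the spacer parameters lose meaning; only the
aggregate term remains interpretable).  Passing recovery tests on
synthetic data therefore demonstrates the correctness and identifiability
of the estimator under the stated noise model, not immunity to those
instrument-level effects.

## Validation problem sizes

The test suite validates the stack at sizes chosen to keep a full run in
minutes: exact recovery of all five parameters from one noiseless frame;
a 50-replicate study at 1 % noise for bias and coverage of $\nu$ and $D$;
and a kinetic run scaled down to 50 frames sampling the 25–175 s
trajectory window every 3 s (a full-rate experiment at 50 ms per frame
with thousands of frames is the same computation, frame count apart — the
warm-start scheme is what makes it linear in the number of frames).  The
structure-factor kernel is verified against an independently coded
Percus–Yevick closed form in the non-sticky limit, and the sphere form
factor against a Bessel-function formulation.

## Known limitations

* The two-density contrast treatment needs the protein contribution to be
  genuinely negligible; for strongly scattering proteins or much larger
  particles a three-density model would be required.
* $A$ is a collective amplitude; it tracks relative changes in aggregate
  number and surface area but cannot be decomposed further.
* The sticky-hard-sphere solution has a genuine no-real-solution region at
  low stickiness/moderate packing; fits that keep running into the
  penalty region (the `n_invalid` counter on fit objects) signal that the
  frozen interaction is wrong for the data.
* Curvature-based uncertainties understate error near bounds and in flat
  directions; use the profile intervals there.
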