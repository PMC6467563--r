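---
title: "Methods: the multi-phase folding model and section morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-phase folding model and section morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cerefold)
```

## The biological problem

The mouse cerebellum folds during late embryogenesis while its outer layer —
the external granule layer (EGL) of proliferating granule cell precursors —
still behaves like a fluid: its cells are motile, exchange neighbours, and
show no pre-pattern in proliferation, shape, size or fiber density. On a
midsagittal section the unfolded cerebellum approximates a semicircle capped
by the EGL; folds initiate at anchoring centers (ACs), which appear first as
*inward thickenings* of the EGL at the positions where fissures later form.
This package implements the quantitative machinery for studying that
process: morphometrics of section contours, a multi-phase variational model
of a constrained fluid layer, the elastic-wrinkling baseline that the tissue
data contradict, window-based cell and fiber quantification, and seeded
generators of synthetic data with known ground truth.

## The multi-phase model

The model describes a midsagittal section in polar coordinates: the outer
(pial) surface sits at radius $r(\theta)$ and the EGL has thickness
$t(\theta)$, both single-valued in the angle $\theta$. The energy functional

$$E[r, t] = \int d\theta \left\{ k_r (r - r_0)^2 - k_t (t - t_0)^2 +
\beta \left( \tfrac{dt}{d\theta} \right)^2 \right\}$$

combines a radial elastic constraint of stiffness $k_r$ (radial glia and the
pial membrane, preferring radius $r_0$), a growth potential $k_t$ that
*rewards* thickening (proliferation pushes the layer away from the preferred
thickness $t_0$, hence the negative sign), and a resistance $\beta$ to
thickness gradients (Bergmann glial fibers spanning the layer). The core is
incompressible, which is imposed as the area constraint
$\tfrac12 \int d\theta \, (r - t)^2 = A_0$ with Lagrange multiplier $\mu$.
The control parameter is $\varepsilon = \mu / k_r$.

Stationarity yields a driven-harmonic-oscillator equation for $t(\theta)$
with sinusoidal solutions

$$t(\theta) = A_t \sin(q\theta + \phi) + C_1, \qquad
r(\theta) = -\frac{\varepsilon}{1 - \varepsilon} A_t \sin(q\theta + \phi) + C_3 .$$

Two structural predictions follow. The surface-to-thickness amplitude ratio
is $A_r / A_t = \varepsilon / (1 - \varepsilon)$, which is small for small
$\varepsilon$ — unlike elastic wrinkling, where surface undulations dominate.
And the two oscillations are exactly out of phase: the EGL is thickest where
the surface is lowest, i.e. at the ACs, which matches the tissue and is the
opposite of what an elastic bilayer requires.

```{r out-of-phase}
s <- model_shape(params_from_epsilon(0.3))
cor(s$t, s$r)
```

### Integration constants

The printed forms of $C_1$, $C_2$ and the amplitude relation are corrupted in
the source text, so the package anchors the constants in two explicit
conventions, both validated against the numerical minimizer below:

* $C_1 = t_0$: the *mean* thickness equals the preferred thickness. This is
  a growth convention, not a stationarity condition — the mean-thickness
  direction of the functional is unstable whenever $k_t > k_r$ (which holds
  throughout the calibrated family), so the functional cannot pin it.
  Consequently the Euler–Lagrange relation
  $\beta t'' + k_t (t - t_0) - \mu (r - t) = 0$ holds exactly for the
  oscillatory components but not for the $\theta$-independent mean; the
  radial relation $k_r (r - r_0) = \mu(r - t)$ holds in full and fixes
  $C_3 = (r_0 - \varepsilon t_0)/(1 - \varepsilon)$.
* The amplitude $A_t$ is taken directly from the calibrated parameter
  family rather than from the corrupted closed form.

### The wavenumber relation

Substituting the sinusoid into the Euler–Lagrange equation gives

$$q^2 = \frac{k_t}{\beta} \cdot \frac{(1 - \varepsilon) + \mu / k_t}{1 - \varepsilon},$$

whereas the published display has numerator $1 + \mu/k_t$. The package
implements both (`beta_for_q(params, variant = c("derived", "printed"))`,
`fold_count_formula()`) and lets the independent constrained minimizer
arbitrate: with $\beta$ chosen from the *derived* relation the minimizer
reproduces the analytic mode-6 sinusoid and its amplitude to better than
1 %, so `"derived"` is the default; with the printed $\beta$ the stationary
wavenumber shifts away from $q$. Neither form is silently discarded.

### Calibrated parameter family

All dimensionless parameters are slaved to $\varepsilon$, which acts as
developmental time:

| parameter | value | meaning |
|---|---|---|
| $c = k_r/k_t$ | $0.06/\varepsilon$ | radial constraint weakens as radial glia transform |
| $A_t/r_0$ | $\varepsilon/9.6$ | oscillation amplitude grows linearly |
| $t_0/r_0$ | $\varepsilon/4.8$ | preferred thickness |
| $q$ | 6 | wavenumber (3 folds on the half section) |
| $\varepsilon(T)$ | $0.3\,(T - 15.5)$ | embryonic day $T$; E16.5 $\mapsto$ 0.3 |

At $\varepsilon = 0.3$ this reproduces the E16.5 measurements
$A_t/t_0 = 0.5$ and $r_0/t_0 = 16$. The family is valid for
$\varepsilon < 1$, i.e. strictly before $T \approx 18.83$; the model cannot
produce self-contacting folds or hierarchical folding and makes no claim
beyond that range. The default is the dimensionless choice $r_0 = 1$;
everything scales linearly in $r_0$ (areas quadratically), and shape factor
and fold count are scale-free.

On the half domain $\theta \in [0, \pi]$ the package fixes the phase to
$-\pi/2$ (a $-\cos$ profile) so that the thickness slope vanishes at both
ends. This Neumann choice is what makes exactly $q/2 = 3$ interior
thickness maxima — three ACs, one at the apex — fit on the semicircular
section; a generic phase would cut a crest at the boundary.

## The constrained numerical minimizer

`minimize_fold_energy()` is an independent check of the analytic solution:
it minimizes the energy over truncated Fourier series of $r$ and $t$ subject
to the area constraint, with no knowledge of the closed-form amplitudes.
Three numerical choices matter:

* **Stable band.** The quadratic functional is unbounded below along
  thickness modes with $\beta m^2 \le k_t$ and along the mean-thickness
  direction. The minimizer therefore pins $\bar t = t_0$ (the same
  convention as $C_1$) and retains only modes with $\beta m^2 > k_t$;
  requesting an empty band raises an error naming the stability condition.
* **Exact constraint elimination.** The energy separation between the
  folded minimizer and the unfolded circle is parts in $10^6$ to $10^9$ of
  the total energy, far below what a penalty or augmented-Lagrangian
  constraint loop resolves reliably (a penalty solver stalls at the
  zero-amplitude saddle). Instead the mean gap $\overline{r - t}$ is solved
  from the constraint in closed form, making every iterate feasible to
  machine precision, and the reduced problem is minimized by BFGS with
  analytic gradients.
* **Multi-start.** One warm start per stable mode plus an unfolded and a
  random start; the lowest-energy solution wins. The effective multiplier is
  recovered from mean-mode stationarity and satisfies $\lambda = 2\mu$.

```{r oracle}
p <- params_from_epsilon(0.3)
s <- model_shape(p)
fit <- minimize_fold_energy(p$k_r, p$k_t, beta_for_q(p), p$r0, p$t0,
                            A0 = attr(s, "A0"), seed = 1)
glance(fit)
c(analytic_At = p$At)
```

## The elastic bilayer baseline

For a stiff film on a soft substrate the wrinkling wavelength is
$\lambda = 2\pi t \, (E_o / 3 E_i)^{1/3}$ and the fold count on a circle of
radius $R$ is $n = 2\pi R / \lambda$. Inverting for the E16.5 geometry
($n = 6$, $R/t = 16$) demands $E_o/E_i = 3 (16/6)^3 \approx 57$, an order of
magnitude beyond the measured near-unity modulus contrast
(`bulk_modulus_from_acoustics()` implements the acoustic route to that
contrast, $K = Z c$). The planar relation is applied to the circle through
$l = 2\pi R$ with no curvature correction; finite-element treatments of the
curved geometry land near 50, consistent with this closed form at the
fidelity needed for the order-of-magnitude argument.

## Morphometrics

* **Lengths and areas** are polyline arc lengths and shoelace areas of
  traced contours in µm. With a smoothing scale of 0 the raw polyline is
  measured; any smoothing first resamples to uniform arc-length spacing
  (default 1 µm) and convolves with a Gaussian of the given scale.
* **Curvature and folding index.** The source of "positive curvature" is
  under-specified in histology practice, so both knobs are explicit: the
  curvature is computed on a Gaussian-smoothed resampled contour (default
  scale 10 µm) and arcs count as convex when the signed curvature is above
  `-curvature_tolerance` (default $10^{-4}\,\mu m^{-1}$). The folding index
  is $100\,(1 - \text{convex length}/\text{total length})$, zero for any
  convex outline.
* **Thickness profiles** sample the inner EGL boundary every 12.5 µm of arc
  length and take the shortest distance to the outer boundary. Samples whose
  nearest point falls beyond the end of an open outer boundary are dropped
  and counted. The shortest-distance reading coincides with the model's
  radial thickness at oscillation crests and troughs but runs slightly above
  the radial amplitude on steep flanks; at $\varepsilon = 0.3$ the
  amplitude-over-mean recovery is within 2 %.
* **Shape factor** is (half perimeter)$/\sqrt{\text{half area}}$, equal to
  $\sqrt{2\pi} \approx 2.5066$ for a semicircle and increasing with folding.
* **Sphericity** of 3-D cell masks is $\pi^{1/3}(6V)^{2/3}/A$. The surface
  area is estimated by a coarea (smoothed-indicator) estimator — Gaussian
  smoothing of the binary mask (default $\sigma = 1.5$ voxels) followed by
  integration of the gradient magnitude. For convex bodies with radii of 15
  voxels and up this is accurate to about 1 %, well inside the 2 %
  tolerance used in the tests; the volume term uses the raw voxel count.

## Cell and fiber quantification

Proliferation is scored as EdU$^+$/(DAPI$^+$, P27$^-$) inside polygonal
windows: 50 µm wide along the outer surface, 50 µm deep, centered at the AC
and at every 25 µm out to ±250 µm (21 windows, overlapping by half). An
empty denominator is reported as missing, never as a zero rate.

The fiber pipeline fits a 4th/5th-order polynomial to the outer EGL edge,
lays five scan lines parallel to it at 12.2 µm depth intervals (starting one
spacing beneath the surface, reading "beneath" literally), normalizes the
image to its mean intensity, smooths with a Gaussian ($\sigma = 2$ px), and
counts peaks per 50 µm bin with min/max filters, averaging over scan lines.
The filter constants the original procedure left unstated are fixed here as:
neighborhood 7 px, prominence threshold 0.2 in mean-normalized units. The
threshold is deliberately *absolute* (relative to the mean level) rather
than relative to the per-line range: a range-relative rule counts noise
maxima on fiber-free images, while the absolute rule yields zero peaks on
pure noise at SNR-5 settings and recovers 1–8 fibers per bin within ±1.
These constants are calibrated on the synthetic generator only.

## Synthetic data and what passing tests mean

Every generator is a pure function of its parameters and a seed, and writes
its generating parameters and derived true values (fold count, per-bin
crossing counts, analytic sphericity, AC positions) as machine-readable
ground truth. Defaults are chosen to emulate the E16.5 study conditions: a
section scale of $r_0 = 400$ µm (so $t_0 = 25$ µm), cell density 20 nuclei
per 1000 µm² of EGL, EdU rate 0.35 among P27$^-$ cells, P27 rate 0.3, fiber
SNR 5 at 0.5 µm/px. At $\varepsilon = 0$ the preferred thickness is frozen
at its E16.5 ratio $t_0/r_0 = 1/16$ (the calibrated family would send it to
zero with $\varepsilon$).

The generators emulate the *statistical structure* the measurements assume —
sinusoidal boundary oscillations, Bernoulli labels, Poisson cell placement,
Gaussian image noise, jittered-grid fiber positions. They do not emulate
segmentation error, anisotropic staining, out-of-plane fibers, or real
hierarchical folding; recovery of ground truth within the documented
tolerances therefore validates the measurement pipeline, not the difficulty
of real histology.

Problem sizes used throughout the examples and tests — 720–2000 contour
points, 12 Fourier modes, ~800 × 350 px fiber tiles, 40–50-voxel masks —
were chosen as the smallest sizes at which discretization error sits an
order of magnitude below every tolerance quoted above.

## Known limitations

* The model is quasi-static and 2-D; no self-contact, no hierarchy, no
  fitting of $k_r, k_t, \beta$ to tissue.
* Open-boundary curvature uses one-sided stencils at arc ends; folding
  indices of very short arcs depend on the smoothing scale.
* The E18.5 AC definition ("everything proximal to the centroid under the
  AC midpoint") is under-specified in 2-D; `ac_sector_polygon()` realizes it
  as an angular sector from the section centroid and is flagged
  experimental. The arc-length windows match the E16.5–17.5 procedure and
  are the validated path.
* `fiber_density_profile()` assumes the outer edge is single-valued over
  the tile's x-range (enforced by the edge-fit residual check), so deeply
  folded stages need per-fold tiles.
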