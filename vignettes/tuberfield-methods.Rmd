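---
title: "Methods: field modelling, synthetic staining, and area recovery in the potato electroporation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field modelling, synthetic staining, and area recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberfield)
```

# Scope and model

Irreversible electroporation (IRE) experiments in the potato tuber model
read out the ablated area from stained slice photographs: tissue that stays
white under 2,3,5-triphenyltetrazolium chloride (TTC) is dead (no
dehydrogenase activity reduces the dye to red formazan), while the
conventional readout waits for damaged tissue to blacken by melanin
accumulation. `tuberfield` provides the computational side of such a study
end to end: the electrostatic field model that predicts the treated zones, a
synthetic photograph generator with exact ground truth, a colour-threshold
segmentation stage, an emulation of the electrical observables, and the
statistics connecting them. Because the original raw data of such
experiments (photographs, oscilloscope traces, impedance readings) are
generally unpublished, the synthetic generator doubles as the test bed: it
defines conditions under which every downstream stage can be validated
quantitatively.

## Electrostatic field model

Two parallel needle electrodes (radius $a = 0.5$ mm, i.e. 1-mm outer
diameter; centre spacing $d = 10$ mm; exposed length 10 mm) are driven at a
potential difference $V_0$. Protocols are labelled by their
voltage-to-distance ratio, so the "1500 V/cm" condition applies
$V_0 = 1500$ V across the 1-cm gap. With constant tissue conductivity the
steady-state potential obeys the Laplace equation
$\nabla^2 \phi = 0$, with Dirichlet values $\phi = V_0$ and $\phi = 0$ on
the electrode surfaces and an insulating outer boundary
($\partial\phi/\partial n = 0$); note that under pure Dirichlet drive the
potential solution is independent of the conductivity value, so no
conductivity constant is needed. The field magnitude is
$E = |\nabla\phi|$, reported in V/cm. The model is two-dimensional — the
mid-exposure cross-section — which is justified when the exposed electrode
length exceeds the electrode spacing; the exposure length is carried in the
configuration but unused.

The domain defaults to a $60 \times 60$ mm square (the nominal width of a
large tuber) discretized at $h = 0.1$ mm. The 5-point stencil, closed with
mirror ghosts at the outer boundary, is assembled as a sparse symmetric
positive-definite system (boundary rows scaled by their cell-volume
fraction) and solved by sparse Cholesky factorization; the interior 5-point
residual is verified against `tol` (default $10^{-6} V_0$) after the solve.
A node belongs to an electrode when its centre lies inside the disk — no
anti-aliasing — so node counts, and hence areas, are exactly reproducible.
Because the problem is linear in $V_0$, a voltage sweep re-uses one solved
reference field, rescaled exactly (`scale_field_map()`); this is an identity
of the model, not an approximation.

Ablation zones are super-level sets of $E$: the predicted IRE core is
$E \ge 250$ V/cm and the presumed reversible-electroporation (RE) annulus is
$100 \le E < 250$ V/cm. These defaults follow the contour levels
conventionally drawn against ablation boundaries in this model system; both
are configuration, not claims. Enclosed areas are node counts times $h^2$;
contour polylines for rendering come from marching squares
(`grDevices::contourLines`).

### Validation against the two-wire closed form — and a caveat about walls

The independent oracle is the image-line-charge solution for two cylinders
in an *unbounded* medium: with $c = d/2$, $b = \sqrt{c^2 - a^2}$ and
$K = V_0 / (2\,\mathrm{acosh}(c/a))$,
$\phi = V_0/2 + K \ln(r_-/r_+)$. Its gradient at the midpoint,
$V_0/(b\,\mathrm{acosh}(c/a)) \approx 671.5$ V/cm at $V_0 = 1000$ V, was
confirmed by central differencing of the oracle itself before it was
trusted.

The comparison has a physical subtlety worth stating plainly: the oracle is
an unbounded-medium solution, while the solver imposes insulating walls on
the tuber-sized domain. On the $60\times60$ mm domain the wall effect is
*not* negligible — it perturbs the potential by roughly 4–4.5% of $V_0$
near the walls (and about 2% of $V_0$ at 15 mm from the centre), as an
image-charge estimate predicts and the solver reproduces; the perturbation
decays only like the inverse domain size. The package therefore validates
solver-vs-oracle agreement to better than 1% of $V_0$ on an enlarged
$120\times120$ mm domain in the central region, where the wall term
genuinely is sub-1%; on the production domain the wall deviation is
reported as a quantity of interest rather than asserted away. The
iso-areas of interest (100–500 V/cm levels) live within ~15 mm of the
centre, where the *field* (gradient) perturbation is far smaller than the
potential offset.

Other numerical checks: the discrete maximum principle
($0 \le \phi \le V_0$), mirror symmetry of $|E|$ in both axes, the
voltage-threshold scaling identity $A(st; sV_0) = A(t; V_0)$, strict growth
of the IRE area with voltage, and grid convergence (iso-areas at $h = 0.1$
and $0.05$ mm agree within 1% for thresholds 100–500 V/cm; a frozen
brute-force count at $h = 0.025$ mm anchors the absolute value). At
$h = 0.2$ mm the electrode disk is only 2.5 cells across and iso-areas are
3–4% from converged, which is why $h = 0.1$ mm is the default and coarser
grids are used only where speed matters more than the third digit.

## Synthetic staining images

The generator emulates the photographs this field actually analyses, not
their photographic realism (no texture, lighting, or lens model — a stated
non-goal). Each bundle carries an RGB image, boolean ground-truth masks of
the same dimensions, the exact truth areas, the scale, and its seed. The
default palette — tan flesh (210,190,150), near-white core (245,243,238),
deep-red annulus (150,30,40), near-black melanin (40,35,30) — was chosen
for unambiguous colour segmentation, with a minimum pairwise channel
separation enforced. Per-channel i.i.d. Gaussian noise (default sd 8 of
255) is added after the truth is recorded, and a ruler with 1-mm ticks is
drawn outside the tissue region for the calibration stage.

Masks are built by taking the $k$ strongest-field pixels for a target area
(bilinear field sampling at pixel centres), so a stored truth area equals
its mask pixel count divided by $(\text{px/mm})^2 \cdot 100$ *exactly*;
electrode punctures are not rendered and their pixels are folded into the
core. Replicate-to-replicate biological variability is a multiplicative
lognormal jitter (mean 1, cv 0.08) on the zone areas — areas remain
positive by construction. The TTC and melanin bundles of one (voltage,
replicate) share the same jittered base area, as the two stains are applied
to two sections of the same pulsed tuber; their readouts then differ by
kinetics and, downstream, by independent segmentation error.

Time kinetics use the simplest monotone forms consistent with the observed
behaviour. Melanin area follows a saturating exponential with onset 2 h and
time constant 12 h: invisible in the first hours, about 57% of the final
area at the conventional 12-h read, and 97.8% at 48 h, where it converges
to the TTC white area. Its darkness ramps with the same kinetics, which
makes very early melanin (below about 7 h) undetectable to value
thresholding — deliberately mirroring practice. The deep-red annulus decays
exponentially with *staining delay* (time constant 6 h): staining within 5
minutes shows essentially the full annulus, while by a 21-h delay only
$e^{-3.5} \approx 3\%$ remains, emulating its disappearance as membranes
reseal. The parameters are configuration; the source observations are bar
charts, so no printed numbers exist to anchor amplitudes.

The star-shaped distortion of melanin areas by the heterogeneous inner
medullar zone is modelled as a boundary-radius modulation
$r(\theta)(1 + A\cos(\ell\theta + \varphi))$ (default $A = 0.15$,
$\ell = 5$, phase from the seed), renormalized by
$\sqrt{1 + A^2/2}$ so the area is preserved to within a few percent. In the
generator the distortion is applied as a coordinate warp of the field
sampling before the top-$k$ selection, so truth areas stay exact while the
shape distorts; `apply_star_distortion()` offers the same operation on a
plain mask. TTC white areas, empirically much less affected by the inner
tissue, are rendered undistorted by default.

## Electrical observables

Both observables are generative emulations coupled to the field setting
(hardware measurement is out of scope). Per-pulse current follows
$I_k = I_\infty - (I_\infty - I_1)e^{-(k-1)/\kappa}$ with the 1500 V/cm
anchors $I_1 = 12.5$ A and $I_\infty = 15.0$ A and linear (ohmic) scaling to
other settings — an acknowledged simplification of genuinely nonlinear
tissue. $\kappa = 5.5$ pulses makes the 17th pulse the first to exceed 99%
of saturation. The 10-Hz conductivity change ratio is
$1 + sE$ with $s = 1/1500$ per V/cm, anchoring the 1500 V/cm ratio at 2 —
an invented anchor, clearly configuration, as only the increasing trend is
documented. Both carry seeded multiplicative lognormal measurement noise
(cv 0.05, mean 1, so noisy means converge to the closed forms).

## Segmentation

The interactive classifier workflow this stage replaces (manual scale
setting plus a trained pixel classifier) is not reproducible from any
published description, so segmentation is deterministic colour
classification in hue/saturation/value space, with every threshold exposed
in `seg_thresholds()`: white is low saturation and high value; deep red is
red-band hue with saturation above the background; melanin is low value.
Each class mask is cleaned by morphological opening then closing (disc,
radius 3 px = 0.3 mm at the default scale — below the resolution of any
area claim), which also removes the 1-px ruler ticks from the melanin
class.

One departure from a strict largest-component rule deserves its rationale:
at 300 V/cm the 250 V/cm super-level set genuinely splits into two lobes
around the electrodes (the mid-gap field is only ~201 V/cm), so keeping
only the single largest component would halve the measured area at the
lowest voltage. The rule implemented keeps every component of at least 5%
of the largest (and at least 64 px), drops true speckle, and raises a
`multiple-components` QC flag. Red pixels are kept only within a 5-px
dilation of the white component, and a red class without any white core is
zeroed with a QC flag.

Scale calibration estimates pixels-per-mm from the ruler: rows containing
many short dark runs are tick rows; the pitch is estimated from the run
midpoints, with gaps rounded to integer multiples of the median pitch so a
missed tick cannot bias the estimate. The generator's known scale is the
oracle: detection is accurate to well under 1%. A user-supplied scale
bypasses detection; an image with neither is a declared calibration
failure.

What passing these tests shows — and does not show: recovery to within a
few percent on images whose palette, noise, and geometry match the
generator's model. Real photographs with uncontrolled lighting, shadows, or
stain variability are supported only through threshold reconfiguration, and
no accuracy claim transfers to them.

## Statistics

The statistics layer mirrors standard practice in this literature:
replicate summaries as mean ± sample standard deviation, Pearson
correlation with two-tailed p-values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, and two-tailed paired Student's t tests
annotated `*`/`**`/`***` at 0.05/0.01/0.001. Implementations wrap
`stats::cor.test()` and `stats::t.test()`; the test suite checks them
against first-principles sum formulas to $10^{-10}$ relative. Correlations
default to replicate-level rows (n = 15 for five voltages in triplicate)
with a condition-mean option — replicate-level is the default because
p-values below $10^{-4}$ at $r \approx 0.92$ are implausible at n = 5. No
multiple-testing correction is applied, matching the practice the layer
reproduces. Degenerate inputs (zero-variance differences, single
replicates) are declared errors or missing values, never silent numbers.

## Pipeline, seeds, and determinism

`run_full()` chains generation, writing, calibration, segmentation, and
statistics into one run directory with a manifest (every file with its MD5)
and returns the tables. Every random draw uses a per-item seed hashed from
the master seed and the item's identity, so re-running a configuration
reproduces every output byte-identically and adding conditions never
perturbs existing items. The problem sizes used throughout —
$h = 0.1$ mm production grids, $h = 0.05$ mm for convergence checks, 30
images per default experiment, 100 master seeds for the correlation-recovery
property — were chosen to exercise the full design at interactive
turnaround.

## Known limitations

* The 2-D constant-conductivity model omits field-dependent conductivity,
  Joule heating, 3-D end effects, and pulse-train transients (all stated
  non-goals); measured ablation areas in real tissue reflect all of these.
* On the tuber-sized insulated domain, absolute potentials near the walls
  deviate by several percent of $V_0$ from the unbounded ideal; conclusions
  drawn from near-wall potentials should use an enlarged domain.
* The deep-red annulus is rendered with a sharp boundary; real formazan
  gradients are soft, so real-image red-area recovery will be worse than
  the synthetic figures suggest.
* Electrical emulations are trend-faithful, not circuit-faithful: linear
  current-voltage scaling and an invented conductivity-ratio anchor.
* The paper-style correlation coefficients reported by the pipeline are
  properties of the synthetic generator's coupling, not reproductions of
  any measured dataset.
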