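---
title: "Quantitative phase imaging morphometry and migrastatic screening: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase imaging morphometry and migrastatic screening: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pamp` implements a 2-D screening pipeline for candidate *migrastatics* —
drugs meant to inhibit tumour-cell migration rather than proliferation — on
quantitative phase imaging (QPI) time-lapse recordings. The screening logic
has three steps: (1) quality control of the untreated control (cell numbers
should rise, mass/area and migration speed should stay roughly stable);
(2) per-condition morphology and speed statistics against the batch control,
split into two equal analysis periods because drugs may act early or late;
(3) invasive-phenotype calling per cell from a displacement/directionality
quadrant rule. Every stage is exercised on synthetic phase movies with known
ground truth, so the whole pipeline is testable without a microscope.

# From phase to dry mass

QPI measures the optical path delay through the specimen. For a cell in
medium the phase delay is proportional to the dry (non-aqueous) mass per
area,

$$M(x, y) = \frac{\varphi(x, y)\,\lambda}{2\pi\alpha},$$

with $\varphi$ the reconstructed phase (radians), $\lambda$ the illumination
wavelength and $\alpha$ the specific refraction increment. The package
defaults, matching a red-LED holographic microscope, are $\lambda = 0.66$ µm
and $\alpha = 0.18$ µm³/pg, so $\varphi = 2\pi$ corresponds to
$\lambda/\alpha \approx 3.67$ pg/µm². Per cell and frame the pipeline then
reports

* **Mass** $= \sum_i w\,h\,M(i)$ over the $N$ pixels of the cell (pg),
* **Area** $= N\,w\,h$ (µm²),
* **Perimeter** from boundary tracing (µm; below),
* **Circularity** $= 100\cdot 4\pi\,\mathrm{Area}/\mathrm{Perimeter}^2$ (%),
* **density** $=$ Mass/Area (pg/µm²),
* **WCG**, the dry-mass-weighted centre of gravity (µm), whose frame-to-frame
  displacement defines speed, path length, Euclidean displacement and the
  meandering index (net displacement over path length).

The WCG is the standard mass-normalised centroid,
$\mathrm{WCG} = \sum_i w h M(i)\,(x_i, y_i)/\mathrm{Mass}$.

## Perimeter estimation

The cell boundary is traced with a clockwise Moore-neighbour walk and
measured as the polygon through boundary pixel centres, axial steps counting
1 pixel and diagonal steps $\sqrt 2$. That raw chain length is exact for
axis-aligned rectangles but systematically overestimates smooth digitised
contours: across digital discs of radius 10–40 px we measure a uniform
+4.95% error, which would push disc circularity down to ~91%. The default
therefore applies the standard isotropic chain-length correction
$\pi(1+\sqrt 2)/8 \approx 0.948$ (Kulpa's coefficient), giving −0.5%
perimeter error and clamped circularity 100 on digital discs, at the price
of underestimating truly polygonal outlines; `correction = FALSE` restores
the raw chain. Since near-circular masks can then exceed 100% circularity,
values are clamped to 100 — the classification bins end there. A single
pixel is assigned the minimal 4-step contour.

# The synthetic movie generator

`simulate_movie()` emulates the study's acquisition: 20 h at 5-minute
intervals (241 frames), 0.65 µm pixels (a plumbing default — the camera
pixel pitch in the sample plane is configurable), one field of view. It is
the package's ground-truth instrument, so its design favours analytic
recoverability:

* **Shape.** Each cell is an anisotropic 2-D Gaussian dry-mass profile
  truncated at 3σ, axis ratio `elongation` (default 2), long axis aligned
  with the instantaneous velocity. The rasterised footprint is rescaled so
  its integral equals the cell's nominal mass *exactly*; ground-truth mass
  is therefore exact by construction, and the mass-conservation tests have a
  well-defined target.
* **Motility.** Velocities follow a stationary Ornstein–Uhlenbeck process
  (persistent random walk) with Euler position updates
  $x_{t+\Delta t} = x_t + v_t\,\Delta t$. Because each sampled step is
  $v\,\Delta t$ with $v$ stationary Rayleigh, the scale
  $\sigma = \bar v / \sqrt{\pi/2}$ makes the *mean sampled step speed* equal
  `speed_mean * drug_effect` with no discretisation bias — the quantity the
  pipeline recovers. `persistence_time` (default 60 min, mid-range for
  adherent mesenchymal cells; chosen so untreated populations show
  invasive fractions of the order reported for real control recordings,
  ~20–40% at 20 h) sets directional memory: the meandering index rises from
  ~0.1 at 5 min persistence towards 1 in the ballistic limit.
* **Interactions.** Cells keep a minimum centre distance of
  0.75 × the sum of their radii. Pairs that would end a step closer and are
  approaching exchange the radial components of their velocities (equal-mass
  elastic exchange, akin to contact inhibition of locomotion); a residual
  positional clamp handles multi-body contacts. Pure position clamping was
  measured to bias mean step speed by −7% to −20% at realistic densities
  because contacts persist for many frames; the elastic exchange preserves
  the population speed distribution (the nominal-speed Monte-Carlo is
  unbiased within 3 SEM of seeds).
* **Boundaries.** Cells reflect at the field edges with a margin of their
  own radius, so tracks never clip and every simulated cell is recoverable.
  The flip side is *confinement*: in a 512-px (333 µm) field a 20-hour
  recording saturates Euclidean displacements, equalising invasive fractions
  across fast and slow arms; the 10 h snapshot is the discriminating one at
  this scale. Free-field properties (e.g. the near-total invasiveness of a
  fast, highly persistent population) are checked on large sparse fields.
* **Division** (off by default, `division_rate` per cell per hour): a
  dividing cell rounds up over the 3 frames before the split — mirroring the
  association of high circularity with division — then two half-mass
  daughters with radius reduced by $\sqrt 2$ start their own tracks; lineage
  is recorded, and daughters restart the meandering-index origin at the
  split frame.
* **Drug action.** `drug_effect` multiplies the target speed;
  `drug_circ_shift` moves the axis ratio towards 1 (rounder cells).
* The generator is deterministic given `seed`, and ground truth is stored in
  physical units; pixels appear only at rasterisation.

What the generator does **not** emulate: optical aberrations and coherence
effects, uneven illumination backgrounds (these are exercised separately via
`detrend_background()`), cell death, mass growth along the cycle,
sub-cellular mass structure, and 3-D environments. Tests passing on this
generator therefore validate the *measurement pipeline*, not biological
realism of any particular cell line.

# Segmentation and tracking

Segmentation operates on the dry-mass density map. The core threshold is
Otsu's method on the density histogram, floored at 3× the robust background
noise sd (1.4826·MAD of the frame); the core mask is then extended by
*hysteresis* down to that noise floor, keeping those low-mask connected
components that contain core pixels. The extension matters quantitatively:
an Otsu cut alone discards the faint Gaussian tails and was measured to lose
~30% of total dry mass, while the hysteresis mask recovers it essentially
completely (the mass-conservation criterion is 5%). Touching cells are split
by a watershed on the Gaussian-smoothed density map (tolerance 0.05 of the
frame maximum — saddles shallower than that do not split); components
smaller than `min_area` (default 50 µm²) are discarded, which also removes
isolated noise pixels in cell-free frames; labels are post-processed to
single 8-connected objects. Border-touching cells are flagged and excluded
from morphology statistics (their area and perimeter are clipped) but kept
for counts and tracking.

Frame-to-frame linking is an optimal bipartite matching on WCG distances
(maximum-weight matching with weight $K - d$, so match count dominates and
total distance is minimised among maximal matchings), gated at
`max_link_distance` (default 15 µm ≈ 5× the expected 5-min displacement at
paper-scale speeds) scaled by the gap length; tracks may disappear for up to
`max_gap` frames. An unmatched detection adjacent to a track whose successor
was already claimed closes that track and opens two daughters — a geometric
division rule, deliberately independent of mass.

# Statistics

Per-cell period mean speeds (steps whose interval ends inside the period;
tracks with under 12 steps ≈ 1 h of coverage are excluded) are compared
treated-vs-control *within the acquisition batch only*. The two-sample
F-test for variance gates the t-test variant: F-test p < 0.05 selects the
unequal-variance (Welch–Satterthwaite) t-test, otherwise the pooled test;
the two-tailed t p-value is starred at 0.05/0.01/0.001. The gate keeps the
empirical type-I error at the nominal 5% for Gaussian populations (checked
by simulation at n = 30, 5000 replicates). Percent speed change is computed
from means, `100 (mean_t − mean_c)/mean_c`. No multiple-testing correction
is applied — stars are per-comparison, as is conventional for this kind of
screening table; raw p-values are always reported alongside. Whether
population "mean ± sd" should pool steps or per-cell means is not fixed by
convention; per-cell means are used (each cell is the experimental unit) and
the choice is recorded in the run metadata.

Two further conventions: the first analysis period is `(0, 10]` h and the
second `(10, 20]` h at 5-minute sampling; speeds are raw 5-minute
displacements with no smoothing (an optional 3-frame median of the WCG path
exists but is off by default, since smoothing deflates speeds and screening
tables conventionally report raw 5-minute steps).

# Invasive phenotype

A cell is *invasive* at evaluation time $T$ (10 h and 20 h by default) when
its Euclidean displacement from the track origin exceeds 100 µm **and** its
meandering index exceeds 25%, both strictly. Eligibility requires the track
to be alive at $T$; daughters evaluate from their own origin. Circularity
classes (Very elongated 0–25, Elongated 25–50, Oval 50–75, Rounded 75–100,
with upward boundary assignment and 100 in Rounded) annotate the morphology
side of the screen.

# Numerical choices and degenerate inputs

* Hologram reconstruction selects the +1 sideband in the Fourier plane
  first — there the DC term is an exact delta and is excluded cleanly even
  for carriers that are not integer cycles per field — then removes the
  carrier pointwise. The low-pass is a raised-cosine disc of radius half the
  carrier magnitude. Phase unwrapping is unweighted least-squares
  (Ghiglia–Romero) via a mirrored FFT Poisson solve; it is exact while true
  gradients stay below π/pixel, which the sideband low-pass guarantees for
  smooth specimens. Carriers below 0.05 cycles/pixel are rejected.
* Background flattening fits a degree-2 polynomial over cell-free pixels
  (subsampled to 20 000); under 10% background it degrades to global median
  subtraction with a warning.
* Stationary tracks have meandering index 0 by convention; zero perimeter,
  empty masks, zero control means and zero variances are errors, not NaNs.
* Phase TIFFs are written as 32-bit float scaled to [0, 1] with the affine
  scale recorded in the JSON sidecar (the writer's float range); labels are
  16-bit.

# Problem sizes

The validation suite runs the study geometry at full temporal length —
20 cells (recovery) and 3 × 30 cells (discrimination) for 241 frames on a
512-px field — and scales spatial size down elsewhere; free-field motility
properties use sparse kilopixel fields without rasterisation. These sizes
were chosen so the whole suite completes on a laptop-class single core while
keeping the statistical checks (3-SEM Monte-Carlo bands, binomial bands on
type-I error) meaningful.

# Known limitations

* Segmentation parity with any particular commercial QPI software cannot be
  claimed; its algorithms are unpublished. Cell-count-level agreement with
  published screens is therefore out of scope.
* The invasive-fraction contrast between arms is evaluated at 10 h at
  single-FOV scale (see the confinement note above).
* The division rule is geometric; a mass-conservation-based rule would be
  more specific but needs calibrated mass splitting.
* Published per-period speed tables round their inputs; recomputing their
  percent columns from rounded means does not always reproduce the printed
  value, so only self-consistent rows serve as arithmetic checks.
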