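---
title: "Methods: geometry, calibration and azimuthal integration in azir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, calibration and azimuthal integration in azir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azir)
```

# The problem

A powder or amorphous sample illuminated by a monochromatic X-ray beam
scatters onto concentric Debye–Scherrer cones; a flat area detector records
their conic sections ("rings").  Two data-reduction tasks dominate such
experiments:

1. **Calibration** — recover the detector's position in space from the rings
   of a reference compound with known lattice spacings, and
2. **Azimuthal integration** — average the 2-D image over the azimuth
   $\chi$ at fixed radial coordinate ($2\theta$, $q$ or $r$) to produce a
   1-D scattering pattern.

`azir` implements both, plus the inverse projection (regenerating a 2-D
image from a 1-D pattern) and a percentile-filter decomposition of an image
into an azimuthally isotropic component and residual Bragg spots.

# Detector and geometry model

A detector is a field of pixel corner coordinates $(N_y, N_x, 4, 3)$ in its
own frame: axis 1 is the slow (row) direction, axis 2 the fast (column)
direction, origin at the lower-left pixel corner seen from the sample, all
lengths in metres.  Regular detectors imply their corners from the pixel
size; multi-module layouts store them explicitly.  Binning merges corner
envelopes and uses the conservative any-masked-then-masked rule, and does
not touch the geometry, which is expressed in metres, not pixels.

The experiment geometry uses the **PONI parametrisation**: the point of
normal incidence is the orthogonal projection of the sample onto the
detector plane.  Six parameters place a rigid flat detector: `dist` (m),
`poni1`, `poni2` (m), and rotations `rot1`, `rot2`, `rot3` (rad) about the
vertical, horizontal and beam axes, in that order.  A beam-center
parametrisation is deliberately absent — it degenerates for tilted
detectors, while the PONI stays well defined.

The source material fixes the rotation axes and order but not the sign
convention or matrix form.  We freeze: right-handed lab frame, axis 3 along
the beam, axis 1 vertical; right-hand-rule matrices composed as
$R = R_3 R_2 R_1$; a detector point $(p_1, p_2)$ maps to
$R\,(p_1 - \mathrm{poni}_1,\; p_2 - \mathrm{poni}_2,\; \mathrm{dist})^T$.
Any self-consistent choice passes the same invariants (zero-rotation closed
form, composition against a scalar oracle); ours is pinned by regression
tests.  Azimuth $\chi = \operatorname{atan2}(v_1, v_2) \in (-\pi, \pi]$ is
zero along the horizontal transverse axis, again a frozen free choice.
Derived quantities: $2\theta$ is the angle to the beam axis,
$r = \mathrm{dist}\tan 2\theta$, and
$q = 4\pi\sin(2\theta/2)/\lambda$ (nm$^{-1}$; an Å$^{-1}$ option exists).

PONI text files carry `Distance`, `Poni1`, `Poni2`, `Rot1..3`, `Wavelength`
(SI units) plus a JSON `Detector_config`; `#` lines are comments.  Detector
persistence uses the same dataset names a NeXus/HDF5 container would
(`pixel_corners`, `mask`, `pixel1`, `pixel2`, `format_version`) but stores
them as JSON text: no HDF5 binding is available in the supported R
environment, and the save/load contract (exact round-trip, errors naming
the missing dataset) is format-independent.

# Calibration

## Calibrant

A calibrant is a list of d-spacings in ångströms (any text file, one value
per line); Bragg's law $2\theta_n = 2\arcsin(\lambda/2d_n)$ gives the ring
apertures, silently skipping rings with $\lambda > 2d$.  Only d-values are
stored, so synthetic images give every ring the same integrated intensity.
Three fixture files ship with the package (LaB6-like, ceria-like,
silver-behenate-like) built from standard lattice constants.

## Peak picking

Three extractors, used at different stages:

* **Massif extraction** (`massif_extract`): the image minus a Gaussian-blurred
  copy of itself is positive on ring crests; 8-connected positive regions
  group peaks of one ring.  The blur width must sit between the peak-to-peak
  distance along a ring and the ring spacing; the default heuristic is
  $\sigma = \max(3, \min(N_y, N_x)/100)$ px, overridable (`--gaussian` on
  the command line).  A relative floor of $10^{-8}\max|I|$ on the
  difference keeps kernel rounding from fabricating regions on flat images.
* **Subpixel refinement** (`refine_subpixel`): a second-order Taylor
  expansion on the 3×3 neighbourhood gives the displacement
  $\delta = -H^{-1} g$ with central-difference gradient and Hessian
  (exact for quadratic surfaces).  When $H$ is singular or any component of
  $\delta$ exceeds one pixel — the quadratic model failed on noise — the
  intensity-weighted centre of mass of the patch is used instead.  Negative
  patch values (possible on DoG stacks) are clipped to zero in the
  centre-of-mass weights.
* **Blob detection** (`blob_detect`): difference-of-Gaussians scale space
  with blur levels $1, \sqrt2, 2, 2\sqrt2, 4$ per octave (ratio $\sqrt2$),
  separable real-space kernels truncated at $\pm4\sigma$ with reflect
  boundaries, and a pyramid that 2×2-mean bins the level blurred at
  $\sigma = 2$ to seed the next octave, keeping kernels small.  Keypoints
  are strict 3×3×3 maxima of the DoG stack (finer minus coarser, so bright
  blobs are maxima), refined by the 3-D analogue of the Taylor step with
  the same fallback rule, and mapped back through the pyramid.  A DoG value
  of $\sqrt{s_k s_{k+1}}$ is reported as the keypoint scale.  With two
  interior scales per octave the smallest detectable peak width is
  ≈ 3–4 px FWHM; the acceptance suite measures the floor at 3.5 px.
  Plateau ties break toward the lexicographically smallest position, so
  plateaus yield exactly one maximum.

Masked pixels are replaced by the unmasked median before blurring and
keypoints within 2 px of a masked pixel are discarded.  Because the raw
detector has no intensity prior, `blob_detect` accepts an absolute DoG
threshold; ring extraction (`extract_for_rings`) defaults it to
$10^{-3}\max I$, which on the synthetic fixtures keeps Poisson-noise maxima
out without touching ring peaks.  That constant is an algorithm default, not
a physical statement; extremely faint rings may need it lowered.

## Refinement

`extract_for_rings` assigns each keypoint to the nearest ring within a
$2\theta$ tolerance and discards the rest.  The cost is
$\sum_i \big(2\theta(y_i, x_i;\; p) - 2\theta_{n_i}\big)^2$, evaluated by
running the exact geometry transform at each fractional pixel position
(never by interpolating a precomputed angle map).  Minimisation uses
bounded L-BFGS-B — the contract asks for an SLSQP-class bounded
least-squares minimiser and any bounded quasi-Newton reaching the same
optimum conforms.  Defaults: wavelength fixed (known from the
monochromator; freeing it with a single ring is a pure $d/\lambda$ scaling
and is rejected), `dist` ∈ (0, 10 m], PONI within ±1 detector extent,
rotations ∈ [−π/2, π/2]; convergence when the cost change falls below
$10^{-12}$ of its initial value or 500 iterations.  `recalibrate` runs two
rounds (extract, refine, re-extract at tol/2, refine), which the tests show
is enough to reach hundredths of a pixel on the stated fixtures.

# Azimuthal integration

Per-bin intensity is the coefficient-weighted mean
$I_b = \sum_p c_{pb} s_p / \sum_p c_{pb}$ of the corrected signal
$s = (I - \mathrm{dark}) / (\mathrm{flat}\,\Omega\,P)$, with
$\Omega = \cos^3\alpha$ the relative solid angle (unity at the PONI) and
$P = \tfrac12(1 + \cos^2 2\theta - f\cos 2\chi\,\sin^2 2\theta)$ the
Kahn-style polarization factor — the source names these corrections without
formulas, so the standard forms above are frozen here.  Pixels equal to a
user "dummy" value are masked dynamically.

## Splitting schemes and the two execution paths

* `nosplit`: the full pixel intensity lands in the bin containing the pixel
  centre.
* `bbox`: the pixel becomes the bounding box of its corner coordinates in
  (radial, azimuth) space; fractions are separable products of 1-D
  overlaps.
* `fullsplit`: only pixel edges are assumed straight; fractions are
  polygon-clipping areas (Sutherland–Hodgman against each candidate bin
  rectangle) divided by the quad area.

Every scheme runs through two algebraically identical paths: **direct**
histogramming (scatter, one pass over pixels) and a precomputed **CSR**
sparse matrix applied as matrix–vector products (gather).  Their agreement
to $10^{-10}$ is an acceptance criterion and a standing property test.
Corner azimuths are unwrapped to within π of their circular mean, and
contributions crossing the ±π cut re-enter through ±2π-shifted copies, so
coefficients still sum to one.  Bins are half-open $[lo, hi)$ except the
last; empty bins report `NaN` with zero weight so "no data" is
distinguishable from "zero signal".  The default radial range spans the
corner coordinates (centre coordinates for `nosplit`) of unmasked pixels.

Pixels containing or adjacent to the beam axis have near-degenerate
(radial, azimuth) quads spanning wide azimuth ranges; their coefficients
remain conservative but azimuthal statistics within a few pixels of the
PONI are intrinsically meaningless (see the separation notes below).

## Error models

With per-pixel variance $v_p$ (supplied, or $v_p = \max(I_p, 0)$ under the
Poisson model), $\sigma_b^2 = \sum c^2 v / (\sum c)^2$.  The azimuthal
model instead postulates isotropy:
$\sigma_b^2 = \mathrm{Var}_w(s) / n_\mathrm{eff}$ with the weighted sample
variance of contributing pixels and $n_\mathrm{eff} = (\sum c)^2/\sum c^2$.
Pixel splitting correlates neighbouring bins, so split-scheme sigmas are
mild overestimates; the ASCII output header repeats this caveat.

# Synthetic data: what it emulates, what it does not

`fake_calibration_image` builds a 1-D pattern of unit-area Gaussians at the
ring apertures, with FWHM$^2 = U\tan^2\theta + V\tan\theta + W$ (Caglioti;
the FWHM applies in the unit of the radial axis, radians of $2\theta$ here —
the source leaves the unit open), rescales so the tallest peak hits `Imax`,
projects it through `calcfrom1d`, and optionally Poisson-resamples with a
stated seed.  `spotty_rings_image` instead places isotropic Gaussian spots
at seeded random azimuths on each ring, returning ground-truth centers.

Stated-world defaults used by the acceptance run: 1024×1024 detector of
100 µm pixels at 0.1 m, λ = 1 Å, LaB6-like d-spacings (six rings on the
detector), ring FWHM $W = (4\,\mathrm{mrad})^2$ — four pixels at this
geometry, safely above the blob floor — `Imax` $= 10^4$ counts (a
realistic well-exposed calibration frame), small tilts
(rot1 = 0.01, rot2 = 0.02 rad), perturbed starts within ±3% distance,
±3 px PONI, ±0.01 rad tilt.

The generator emulates ring geometry, resolution broadening, counting
noise, module gaps (via masks or the gapped fixture) and spotty rings.  It
does **not** emulate detector point-spread, optical distortion, structure
factors (rings are equal-area by construction), preferred orientation,
polarization of the source, parasitic scattering or beam-stop shadows.  A
green calibration test therefore establishes correctness of the geometry
and optimisation machinery, not robustness to every beamline artefact.

Peak shape is Gaussian: the source names only Caglioti widths, and a
Gaussian keeps area bookkeeping exact, which the equal-ring-intensity
contract tests rely on.  `calcfrom1d` samples pixel centres (not
corner-averaged), matching the adjoint of the no-split scheme and keeping
round-trip tests interpretable.

# Isotropic/Bragg separation and validation

`separate` runs a 2-D (fullsplit) integration, takes a percentile (default
the median, linear-interpolation definition, over nonempty azimuthal bins
only) per radial bin, re-projects the filtered pattern through
`calcfrom1d`, and defines `bragg = img − isotropic`.  A re-subtraction step
makes `isotropic + bragg == img` bit-exact on unmasked pixels.  Defaults
`npt_rad = 1024`, `npt_azim = 512` suit megapixel frames; match the grid to
smaller detectors.  Radial bins with no azimuthal coverage are interpolated
from neighbours with a warning.  Two documented limits: within a few pixels
of the PONI a "ring" holds fewer pixels than azimuthal bins, so order
statistics there are unsupported; and because `calcfrom1d` interpolates
linearly between bin centres, feeding a *smooth* isotropic image back
through `separate` leaves an $O(\mathrm{bin})$ interpolation residual
(~$10^{-3}$ relative) rather than zero — the exact-idempotence property
holds on radially flat inputs, where the median-of-constants argument
applies.

The frame score for serial-crystallography triage — the sum of Bragg
intensity above $k = 4$ azimuthal MADs of the isotropic level — is this
package's own statistic; the source names the use case without defining
one.

`measure_offset` implements phase correlation: the normalised cross-power
spectrum, magnitude-thresholded at $10^{-6}$ of its maximum (frequencies
below that carry rounding-noise phase only) and weighted by a Gaussian of
σ = 0.06 cycles/px.  Without the weight the whitened spectrum of sharp
images produces a Dirichlet-kernel correlation peak on which the 3×3
quadratic refinement systematically underestimates subpixel shifts; the
weight smooths the peak without moving it.  Integer shifts come back exact
to ~$10^{-8}$ and quarter-pixel shifts within 0.05 px (both tested).
`validate_calibration` integrates, re-projects, and reports the phase
offset between the image and its regeneration — a direct, paper-style check
on PONI precision.

# Numerical choices (summary table)

| Choice | Value | Why |
|---|---|---|
| Gaussian kernel truncation | ±4σ, reflect boundary | error < 3e-5 of mass; no FFT needed |
| Scale series | ratio √2, levels 1…4 per octave | geometric series bracketing 1 and 2 |
| Pyramid trigger | downsample at σ = 2 | keeps kernels ≤ ~12 px |
| Massif positive floor | 1e-8 · max image | kernel rounding immunity |
| Blob threshold (ring extraction) | 1e-3 · max image | suppress Poisson flat-field maxima |
| Refinement stop | Δcost < 1e-12 · initial or 500 iters | reproducibility |
| Bin edges | half-open, last closed | deterministic ties |
| Empty bins | NaN + zero weight | "no data" ≠ "zero" |
| χ cut handling | unwrap to circular mean ± 2π copies | coefficient conservation |
| Phase correlation | magnitude floor 1e-6, spectral σ 0.06 /px | unbiased subpixel peak |

# Known limitations

Flat detectors only are exercised (corner arrays with a third coordinate
are accepted but untested beyond construction); hexagonal pixels
($N_c \ne 4$) are out of scope; no GPU path; no vendor detector catalogue;
geometry import/export to other packages' dialects is not provided.  Image
I/O is EDF and whitespace-separated text — TIFF and HDF5 would require
bindings unavailable in the supported environment.
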