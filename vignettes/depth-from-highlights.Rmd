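---
title: "Depth maps from specular highlights: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth maps from specular highlights: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodepth)
```

## The problem

A capsule endoscope carries one camera and a ring of LEDs; there is no room
for a second lens. Shape-from-shading on a single image recovers shape only
up to an unknown scale tied to the surface albedo, and classical photometric
stereo needs an external depth measurement to anchor the reconstruction.
The wet digestive-tract surface offers a way out: it is *not* Lambertian.
Wherever the mirror condition between one LED, the surface and the camera is
met, a specular highlight appears. That highlight is usually treated as
contamination to be removed; here it is the anchor. Its geometry pins the
surface gradient at one pixel, and combining that constraint with Lambertian
image ratios from the other LEDs yields the pixel's *metric* depth, which
then seeds the integration of the full depth map.

## Model and conventions

All pixel coordinates $(x, y)$ are continuous offsets from the principal
point and, with the focal length $f$, are measured in pixels; light
positions $(\xi_i, \eta_i, \zeta_i)$ and depths $z$ are in mm, with visible
points at $z < 0$. The perspective parameterisation is
$M(x,y) = (-xz/f,\; -yz/f,\; z)$, under which the mixed expressions
$\xi_i f/z + x$ (pixels) and $\xi_i + xz/f$ (mm) are both well-formed; this
mixed-unit convention is asserted once in the geometry module and relied on
everywhere.

Under $z<0$ the natural algebraic forms of the illumination vector
$\bar l_i = (\xi_i f/z + x,\ \eta_i f/z + y,\ \zeta_i f/z - f)$ and of the
surface normal
$\bar n = (z/f)^2 (f z_x,\ f z_y,\ z + x z_x + y z_y)$ are both *flipped*
relative to their physical directions (a fronto-parallel plane has
$n = (0,0,-1)$). The two flips cancel: every shading dot product
($l\!\cdot\!n$, $h\!\cdot\!n$, the radial-attenuation cosine) is positive
for illuminated geometry. We keep the flipped frame exactly and clamp
cosines into $[0,1]$ where noise could push them out.

Each LED is a near-point source with inverse-square distance attenuation
$a_d = f^2/(z^2 q_i^2)$ and a cosine radial fall-off about its principal
direction (default $(0,0,-1)$); for a source in the camera plane the product
is $a_i = f^3/(z^2 q_i^3)$, an identity the tests check to machine
precision.

**Lambertian ratios.** For two images lit by sources $\delta_1, \delta_2$,
the irradiance ratio cancels albedo, exposure, and the common
$f^3\rho/ (z^2\lVert\bar n\rVert)$ factor, leaving
$F_\xi z_x + F_\eta z_y = z F_\zeta$ with
$F_\xi = I_{\delta_1} q_{\delta_1}^4(\xi_{\delta_2} f + \zeta_{\delta_2}x)
 - I_{\delta_2} q_{\delta_2}^4(\xi_{\delta_1} f + \zeta_{\delta_1}x)$,
its $\eta$ analogue, and
$F_\zeta = I_{\delta_2} q_{\delta_2}^4(\zeta_{\delta_1} - z)
 - I_{\delta_1} q_{\delta_1}^4(\zeta_{\delta_2} - z)$. Swapping the pair
negates all three components — an antisymmetry the tests assert, and one
with numerical consequences for the upwind scheme below.

**Mirror constraint.** At the highlight of source $\sigma$, equal incidence
and reflection angles force the unit view and illumination vectors to sum to
a multiple of the normal. Eliminating the multiplier gives the gradient in
closed form, $z_x = -z\,G_\xi/G_\zeta$ and $z_y = -z\,G_\eta/G_\zeta$, with
$G_\xi = xzq_\sigma + (xz+\xi_\sigma f)b$,
$G_\eta = yzq_\sigma + (yz+\eta_\sigma f)b$,
$G_\zeta = zq_\sigma b^2 + zb^3 + f(x\xi_\sigma + y\eta_\sigma -
f\zeta_\sigma)b$, and $b = \sqrt{x^2+y^2+f^2}$. (Re-deriving the $2\times2$
elimination shows the denominator carries a factor $b$ that is sometimes
dropped in derivations of the separate $z_x, z_y$ formulas; the $G$-terms as
used in the energy are the consistent set, and the retroreflection,
plane-mirror and sphere oracles in the tests pin the implementation.)

**Seed energy.** Substituting the mirror gradient into the ratio PDE yields
$E(z) = F_\xi G_\xi + F_\eta G_\eta + F_\zeta G_\zeta$, zero exactly at the
highlight depth. With three Lambertian images there are three pairs; the
default objective is the sum of squared per-pair energies. This matters in
practice: for a highlight on a symmetry axis of the rig, the pair of lights
mirrored across that axis is *identically degenerate* (all its terms vanish
at every depth), and a single-pair estimator that happens to select it
returns garbage. The combined objective keeps the degenerate pair harmless.
A `pair_mode = "single"` (two brightest Lambertian images) is retained for
comparison.

The scalar minimisation is a 512-point grid scan over the camera's working
range $[-100, -3]$ mm followed by local refinement to $10^{-4}$ mm
(`stats::optimize`), deterministic throughout. Pixels whose minimum sits on
the interval edge are flagged `edge`; pixels with two well-separated grid
minima of comparable squared energy are flagged `ambiguous`; both are
excluded from region statistics rather than guessed.

## The synthetic world

The reference scene emulates the simulated capsule rig: a 640×480 camera
with $f = 565$ px, four LEDs in the camera plane at 5.5 mm from the axis,
principal directions along $-z$, equal intensities, and a polyp-shaped
surface — a plane at $-21.37$ mm carrying a spherical cap whose apex is 4 mm
proud of it, Blinn–Phong reflectance, dark environment, no shadows or
interreflection. Defaults that the reference configuration does not pin
down, chosen once:

* **Principal point** $(w/2, h/2)$ — a pixel centre for even sizes, the
  common computer-vision convention. With the symmetric rig this places the
  mirror points on pixel rows/columns; at a half-pixel offset the seed error
  is an order of magnitude larger, which is incompatible with the reference
  results.
* **Cap sphere radius 10.17 mm** (height fixed at 4 mm, so the apex is at
  $-17.37$ mm). The radius is calibrated so the ideal mirror point of a
  5.5 mm light sits at $-17.4188$ mm, the reference ground-truth value; a
  full hemisphere (radius 4) would put it at $-17.40$ mm and, worse, meets
  the plane vertically, a square-root singularity in $z(x,y)$ that no
  first-order scheme crosses accurately. The calibrated cap is a 16 mm wide
  sessile-polyp-like bump with a finite (53°) rim slope. A hemisphere
  remains available via `cap_radius = cap_height`.
* **Blinn–Phong** $k_d = 0.8$, $k_s = 0.4$, shininess 300 — a compact
  highlight of ~270 px at full resolution. The specular lobe carries the
  illuminant colour (dichromatic behaviour of a wet dielectric surface);
  tinting it by the albedo would give highlights the same saturation as the
  background and make saturation-gated detection impossible.
* **Albedo** $(0.80, 0.52, 0.48)$, a mucosa pink with saturation 0.40 —
  above the detector's saturation gate while the white highlight falls
  below it.
* **Noise** additive zero-mean Gaussian in linear radiometry, seedable,
  default off (the reference simulation is noiseless).

The renderer shares the light/normal model with the reconstruction, so on
noiseless matte renders the irradiance equations hold to machine precision —
the renderer doubles as the oracle for the ratio-PDE tests. What a green
test does *not* establish: real mucosa has texture, interreflection,
non-dichromatic colour, calibration error and sensor noise; the synthetic
world validates the mathematics and the numerics, not robustness to those.

## Detection and the exclusion masks

Highlight pixels have low saturation and high intensity; the detector gates
on HSV saturation $< 0.3$ and value $> 0.9$ of the image maximum (both
relative, hence exposure-invariant), groups candidates by 8-connectivity and
drops regions under 5 px. Two consequences of those gates drove design
choices:

* **Centroid weighting.** The intensity peak of a rendered highlight is not
  the mirror point: the diffuse baseline and the attenuation tilt the total
  intensity by a fraction of a pixel, and at ~0.3 mm of depth error per
  pixel of offset that is the budget. On RGB input the diffuse component of
  a homogeneous surface is proportional to $V - \min(\text{channel})$ (the
  illuminant-coloured lobe cancels in the difference), so the detector
  estimates the proportionality from a diffuse ring outside the region and
  weights the centroid by the *specular excess*, gated at the same relative
  level as the detector. Grayscale input falls back to intensity-excess
  weights.
* **Mask dilation.** The intensity gate captures only the lobe core — at
  the default gates the lobe still stands at ~74 % of its peak on the mask
  boundary — while its wings bias the image ratios far outside it
  (measured: 0.57 mm reconstruction RMSE with raw masks vs 0.048 mm with
  dilated ones, against a 0.042 mm floor for a purely matte render). Each
  exclusion mask is therefore dilated by 3× the region's equivalent radius,
  which reaches roughly the 1 % level of the lobe. Where dilated zones
  overlap and fewer than two images would survive at a pixel, a coverage
  guard restores the dimmest (least contaminated) masked images so the
  march can pass through; the same guard applies inside the seed region.

The largest-area region across the four images becomes the specular seed
(ties to the lowest source index); the other three lights form the
Lambertian set.

## Integration: forward upwind fast marching

Discretised with one-sided differences selected by the signs of
$(F_\xi, F_\eta)$, the ratio PDE becomes, per pixel,
$Z(\lvert F_\xi\rvert + \lvert F_\eta\rvert) =
 \lvert F_\xi\rvert Z_{\text{up},x} + \lvert F_\eta\rvert Z_{\text{up},y}
 + \Delta\, s(Z)$, with $s = zF_\zeta$ and $\Delta = 1$ px (diagonal
stencils rotate the axes 45° and use $\Delta\sqrt2$). Because $F$ and $s$
depend on the unknown $Z$, each pixel solves a scalar fixed point, iterated
from the mean of its accepted neighbours with adaptive damping to
$10^{-6}$ mm (50 iterations max); the update is also the root of the scalar
residual, which a bisection oracle confirms in the tests.

Two numerical points deserve emphasis:

* **Orientation freedom.** Swapping the image pair negates $F$ and $s$,
  which turns every one-sided difference around; both orientations are
  equally consistent discretisations. A march that fixes one orientation
  can find its upwind neighbours pointing *away* from the seed over half the
  domain and silently drops terms, which is catastrophic (first measured as
  a ~9 mm RMSE). The implementation therefore couples image pairs,
  orientations and the two stencil families — the eight principal
  directions — and differences toward the already-accepted side, preferring
  options with no significant term missing (a strict pass) before accepting
  partial stencils.
* **Propagation order.** The front is processed deterministically: most
  accepted neighbours first, then Chebyshev distance from the seed, then
  pixel index; each pixel is finalised once. Pixels where every pair fails
  are retried after the front exhausts and, as a last resort, take the mean
  of their accepted neighbours (tracked in a status map; zero such pixels
  occur in the reference scene).

The Gauss–Seidel reference solves the same per-pixel equations by global
relaxation sweeps. When pinned to the equation choices the march recorded,
it reproduces the march to $<10^{-3}$ mm on test crops — evidence that the
march solves the system it assembles. Left free, Gauss–Seidel makes its own
(all-neighbours-available) orientation choices and converges to a slightly
different discrete solution; that gap is a property of one-sided schemes,
not a defect.

Errors injected at the seed are not damped by the PDE: a ±0.9355 mm seed
offset grows to ~1.9 mm RMSE over the frame (amplification ≈ 2), and
reconstruction error is monotone in the seed error — both asserted in the
tests. This is why the centroid pixel, whose estimate is the most accurate
in the region, is the recommended boundary condition.

## Radiometry

The camera-response module inverts a declared monotone response (linear,
gamma, or a tabulated curve; non-monotone tables are rejected) and
optionally pre-filters illuminance maps with a Gaussian blur ($\sigma = 1$
px) followed by a 3×3 median — white noise first, salt-and-pepper second;
order and sizes are package choices, configurable, and either stage can be
disabled. The synthetic pipeline uses the linear response, matching the
renderer's proportionality of pixel value to illuminance. PDE computations
use channel-mean luminance; colour is kept only where detection needs it.

## Known limitations

* One seed, one connected reconstruction: multi-highlight fusion and global
  refinement are out of scope.
* The method inherits the first-order scheme's $O(\Delta)$ bias on curved
  surfaces and the exponential sensitivity of PDE continuation to the
  boundary value.
* Specular contamination is excluded geometrically (dilated masks), not
  separated photometrically; heavily glossy scenes with overlapping lobes
  would starve the Lambertian pair selection.
* The renderer's idealisations (no interreflection, no shadows, exact
  calibration) bound what the synthetic validation can claim about tissue
  images.
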