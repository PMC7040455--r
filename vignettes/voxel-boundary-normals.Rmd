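---
title: "Methods: curved refractive boundaries in voxel Monte Carlo light transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curved refractive boundaries in voxel Monte Carlo light transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxlight)
```

## The problem

Monte Carlo photon transport in tissue optics is usually run on a regular
voxel grid: the photon hops a sampled free path, drops a fraction of its
weight into the voxel it scatters in, and spins into a new direction drawn
from the Henyey–Greenstein phase function. Where two media of different
refractive index meet, the photon reflects with the unpolarized Fresnel
probability or refracts by Snell's law. Both laws need the *boundary normal*
— and on a voxel grid the only normal the geometry itself offers is the
axis-aligned facet of the crossed voxel face. For a curved or oblique
interface the facet normal can be wrong by up to 45° in any one plane
(and worse in 3-D), which doubles into errors of up to 180° in the reflected
direction and badly distorts reflect/transmit proportions.

`voxlight` addresses this with a *precomputed surface-normal field*: an edge
detector applied to per-medium occupancy maps, smoothed to remove the
voxelization staircase, stored as one unit vector per boundary voxel, and
optionally refined at run time by a same-medium-masked trilinear
interpolation. The transport loop can run in four boundary modes — `matched`
(no Fresnel), `facet`, `surface`, and `interp` — so the effect of each
refinement can be isolated.

## The normal-field pipeline

For a labeled volume and its medium table the pipeline is, per unique
refractive index value:

1. build the binary occupancy map of that index (`binary_map()`);
2. apply the separable 3×3×3 Sobel–Feldman operator (`sobel3d()`), derivative
   kernel $(-1,0,1)$ along the gradient axis and smoothing kernel $(1,2,1)$
   along the two others, with replicate padding at the grid faces. The sign
   convention makes the gradient point *into* the region (away from the
   boundary), which is the orientation the Fresnel step expects;
3. smooth each gradient component with a penalized least-squares smoother in
   the discrete cosine basis (`smooth_field()`): \(\hat y = \mathrm{IDCT}\,
   \Gamma\, \mathrm{DCT}\, y\) with \(\Gamma = 1/(1 + s\Lambda^2)\), where
   \(\Lambda\) is the DCT eigenvalue field of the discrete Laplacian and $s$
   the scalar smoothing factor. The DCT-II basis implies reflective boundary
   conditions, so constants are reproduced exactly and the grid faces induce
   no spurious gradients;
4. mask each smoothed field by its own binary map — this is what prevents
   vectors on opposite sides of a boundary from cancelling — sum the masked
   fields, and normalize each voxel's vector to unit length
   (`aggregate_normals()`).

`compute_normal_map()` chains these steps. Smoothing each region's field
*before* masking lets the smoother see the full staircase context; masking
afterwards guarantees a voxel's stored normal derives only from its own
medium.

### Parameters

* **`s` (smoothing factor, dimensionless, default 2).** $s=0$ disables
  smoothing; larger values trade staircase ripple against deformation of
  genuine geometry. The default of 2 is a sensible middle ground for the
  phantoms shipped here; for new geometries visual inspection of the field
  against the intended surface is the honest way to choose it. The test
  suite verifies that $s=2$ strictly reduces the mean angular error of
  sphere normals relative to the raw Sobel field.
* **`mag_floor` (relative magnitude floor, default `1e-3`).** The DCT
  smoother leaves small nonzero values throughout each region's interior;
  normalizing those would manufacture unit-length noise vectors far from any
  boundary. Vectors whose pre-normalization magnitude falls below
  `mag_floor` times the field maximum are stored as zero, which confines
  nonzero normals to a shell of roughly a dozen voxels around the
  boundaries at $s=2$. Transport only consults the map at mismatched faces,
  where magnitudes are orders above the floor, so the choice does not affect
  the physics; the zero vector doubles as the "fall back to the facet
  normal" signal.

### Measured accuracy

On the validation sphere (radius 1 cm, voxel 0.01 cm) the acceptance tests
measure a mean angular error of the stored normals against the analytic
radial field of about 1.4° over the boundary-adjacent voxels, with a 99th
percentile near 6°: the typical normal is excellent and a small tail of
staircase-corner voxels is several times worse. Reflection doubles angular
errors, so *per-photon* reflected directions inherit a tail of roughly
twice that — which is why the headline validation below compares reflected
*beam edges* (aggregates), the quantity that actually shows in a fluence
image.

Two further properties are worth knowing. Halving the voxel size reduces
the median and mean normal error but not the extreme tail: $s$ acts in
voxel units, so the physical smoothing length shrinks with `dx`. And for
any axis-aligned planar interface the pipeline reproduces the facet normal
exactly (the Sobel response is axis-aligned and the smoother preserves the
planar symmetry), so `facet`, `surface` and `interp` runs of a slab are
bitwise identical.

## Interpolated normals

At a boundary crossing the photon sits on a voxel face. The interpolation
cube's eight vertices are the centroids of the voxels bracketing that
position (lower corner index `round(coord) - 1` per axis) and the
fractional coordinates are

$$x_d = x - \mathrm{round}(x) + 0.5,$$

with `round` half-away-from-zero — this makes a centroid query return its
own voxel's vector exactly ($x_d = 0$ at $x = 0.5$), which banker's
rounding would break. Each vertex carries a Boolean mask bit, set only if
that voxel's refractive index matches the photon's current voxel, so the
blend never mixes vectors across the boundary. The masked trilinear blend
is applied componentwise,

$$c_{00} = c_{000} v_{000}(1-x_d) + c_{100} v_{100}\, x_d, \quad \ldots
\quad c = c_0 (1-z_d) + c_1 z_d,$$

and the result is normalized. Masked terms simply drop out; the blend is
*not* re-weighted by the active mask sum, because the final normalization
absorbs the lost magnitude. If the blend is numerically zero (magnitude
below $10^{-9}$) the caller falls back to the stored voxel normal, then to
the facet normal — the fallback chain is this package's choice for a case
the interpolation equations leave open. Crossing points are *not* projected
onto a reconstructed virtual surface; they stay on the voxel face, a small
accuracy trade for a much simpler and faster inner loop.

## The transport loop

The loop is the standard dimensionless-step formulation: a step
$s = -\ln \xi$ is consumed across voxels as $\mu_t \ell$ per partial path
$\ell$, which is unbiased in heterogeneous media without re-sampling at
interfaces. Conventions that matter:

* **Ballistic media.** Voxels with $\mu_t = 0$ are traversed without
  consuming step, so "no scattering, negligible absorption" demonstrations
  run exact straight-line optics.
* **Boundary detection** compares the refractive index of the voxel being
  entered against the current voxel at each face crossing; Fresnel is
  evaluated on the face with the photon still on its incoming side. A
  single random draw decides reflect vs transmit (no weight splitting).
* **Post-Fresnel nudge.** After a reflection or transmission the photon
  advances $10^{-7}$ voxel units along its new direction before the voxel
  index is recomputed, which robustly prevents re-detecting the same face.
  A surface-normal reflection can point *into* the neighboring voxel; the
  nudge then lets the photon continue without a second Fresnel draw, the
  same behavior as the facet-based codes this loop descends from.
* **Absorption and roulette.** At a scattering event the voxel receives
  $\Delta W = W \mu_a/\mu_t$; photons below the roulette threshold
  (default $10^{-4}$) survive with probability $1/m$ and are re-weighted by
  $m$ (default 10). Every run's bookkeeping — launched = deposited +
  escaped + roulette net — is checked to $10^{-6}$ relative in the tests.
* **Grid exit.** Photons escape through the outer faces with no Fresnel
  step there (the outside world takes the face voxel's index); exit face,
  position, direction, weight and per-photon Fresnel event counts go into
  the escape record.
* **Fluence normalization.** $\varphi = $ deposited weight
  $/(\mu_a\, dx^3\, N)$ per voxel, in W/cm² per W delivered; voxels of
  non-absorbing media stay 0.
* **Reproducibility.** All randomness flows through R's RNG; a seed in the
  configuration makes runs bitwise reproducible, and the seed is carried in
  the fluence metadata.

## Validation experiments and what they show

**Sphere.** `setup_sphere_experiment()` voxelizes a sphere of radius 1 cm
(n = 1.33 inside, 1.00 outside, `dx` = 0.01 cm) and aims a collimated disk
beam (radius 0.15 cm, axis offset 0.6 cm from the sphere center) at its
side, covering incidence angles of roughly 27–49°. With scattering off,
every escaping photon that underwent exactly one Fresnel reflection is
compared against the analytic specular reflection of its own launch ray
(`reflected_angle_error()`). The *beam-edge* error (`beam_edge_error()`)
groups reflected photons launched in the outer 10% annulus of the source
disk into the near and far edges and compares each edge's mean Monte Carlo
direction with the mean analytic reflection of the same rays: this is the
aggregate quantity a fluence image shows. In surface and interpolated modes
the acceptance run measures beam-edge errors near 1°, against facet-mode
per-photon errors approaching 100°. The beam geometry is this package's
documented default — the validation statement gives no beam dimensions —
and is fixed, not fitted.

**Edge sweep.** The worst-case direction error of a facet normal against a
straight 2-D edge is 45° by construction; the 3×3 Sobel estimate is
evaluated by rasterizing ideal step edges (each pixel holds the exact area
fraction of the half-plane over its square) across orientations 0–45° and
sub-pixel offsets and reading the gradient direction at pixels centered on
the edge. The measured maximum is about 1.4°. Hard binary thresholding is
also available (`model = "binary"`) but measures the rasterization
staircase (maximum error ≈ 26.5°), not the operator, so the coverage model
is the default for the operator-accuracy sweep.

**Lens.** `setup_lens_experiment()` immerses a biconvex lens (n = 1.52;
R1 = R2 = 0.2 cm, center thickness 0.15 cm, aperture 0.3 cm — dimensions
are this package's defaults, chosen to put the water-immersed thin-lens
focus, 0.7 cm, inside the 1.28 cm grid) in water (n = 1.33) over a
scattering aqueous solution (μs = 100 cm⁻¹, g = 0.90) below z = 0.5 cm.
Absorption is set to 0.01 cm⁻¹ — negligible against scattering but nonzero
so absorbed weight records fluence everywhere. A 0.1 cm beam enters through
the lens; facet-normal and interpolated-normal runs share a seed, and the
voxel-wise percent-change map $100(\varphi_{FN} -
\varphi_{ISN})/\varphi_{ISN}$ is evaluated below and lateral to the lens
with a low-fluence floor of $10^{-8}$ (the floor, and the region
definition, are this package's choices; the comparison is meaningless in
voxels the reference run never visited). The facet run cannot focus, so the
map exceeds 90% by an order of magnitude in that region.

## Problem sizes

The validation sphere uses a 208³ grid and 2×10⁴ photons; the lens
comparison a 128³ grid and 10⁵ photons per mode in the tests (2×10⁵ in the
acceptance script); the edge sweeps 901 orientations × 10 offsets. These
sizes give stable aggregate statistics — edge bands of a few dozen
reflected photons, percent-change signals an order of magnitude above the
pass line — while keeping a full validation run around a minute on one
core.

## What the synthetic phantoms do and do not emulate

The slab, sphere and lens phantoms probe exactly the failure mode this
package targets — curved and oblique index-mismatched boundaries — with
analytic ground truth available. They do not emulate real segmented
anatomy: label noise, thin structures a voxel or two wide, multi-tissue
junctions where more than two media meet in one interpolation cube, or
strongly absorbing media where the drop step dominates. Passing the suite
shows the boundary handling is right; it does not certify accuracy on an
arbitrary segmentation, where the smoothing factor in particular should be
re-examined.

## Known limitations

* Per-photon reflected directions retain a staircase tail (roughly twice
  the normal-field tail); only aggregate beam quantities reach the ~1°
  regime.
* The smoothing factor is resolution-coupled: refining `dx` at fixed $s$
  shrinks the physical smoothing length, so the error *tail* does not
  improve with resolution (the median does). Scaling $s$ with resolution is
  the obvious extension.
* Unpolarized Fresnel only; no polarization tracking, thin films, or
  wavelength dependence.
* The dense normal map stores three doubles per voxel; a hash-table
  compressed store for the boundary shell would cut memory but is not
  implemented.
* The analytic oracle covers spheres and spherical lens caps only, and only
  scattering-free trajectories; scattering cases are validated by
  conservation and distribution properties, not by the oracle.
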