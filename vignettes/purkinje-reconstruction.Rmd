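---
title: "Reconstructing and simulating cardiac Purkinje networks from flat images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and simulating cardiac Purkinje networks from flat images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Purkinje network is the fast-conducting fiber system on the inner
(endocardial) surface of the ventricles.  It distributes the His-bundle
stimulus across the endocardium so that the ventricles activate quickly and
in the right order.  Its structure can be photographed after dissection and
Lugol staining, which darkens Purkinje fibers, but only as a *flat* image of
an opened ventricle.  purkinjemap carries such a flat, digitized network --
a binary texture with coupling sites marked at the fiber endings -- back
onto a three-dimensional endocardial surface, and then validates the
reconstruction by simulating the coupled ventricle-Purkinje excitation and
checking that the network alone can fully and plausibly activate the
ventricles.

## The curvilinear cylinder chart

The mapping problem is: given a texture $T : [0,W] \times [0,H] \to \{0,1\}$
and a curved surface, assign texture values to surface points with
controlled distortion.  The package approximates the endocardial surface by
a *cylinder* $C \times \mathbb{R}$ over a smooth closed plane curve $C$,
parameterized by arc length $s \in [0, L]$ and oriented counterclockwise.
$C$ is a closed piecewise-cubic Bezier spline through user control points
(`fit_closed_spline()`); arc length comes from a dense per-segment sampling
(200 points per segment by default) with a monotone lookup table, so
`curve_point()` is unit-speed to within $10^{-3}$.

The chart extends $(s)$ off the curve.  At any plane point $x$ the package
forms the inverse-distance weighted average of the curve's outward unit
normals $N(s)$:

$$V(x) = \frac{\int_0^L N(s)\, d(x, C(s))^{-1}\, ds}
              {\int_0^L d(x, C(s))^{-1}\, ds},$$

which converges to $N(s^\ast)$ as $x$ approaches $C(s^\ast)$ because both
integrals diverge there.  Trajectories of $\dot{x} = V(x)$ seeded at
equally spaced arc lengths, integrated inward and outward, carry $s$ into
the plane; interpolating $s$ over all trajectory points yields coordinates
$(s, t)$ for every charted point, with $t$ the signed path length (negative
inside $C$).  On a circle the construction reduces exactly to polar
coordinates, which is the package's primary correctness oracle.

A texture placed on the rectangle $[a,b] \times [c,d]$ of the cylinder
(arc length times cylinder axis) extends to all of space by holding its
value constant along trajectories:

$$F(x, y, z) = T\!\left(\frac{s - a}{b - a} W,\; \frac{z - c}{d - c} H\right),$$

and evaluating $F$ inside a thin endocardial voxel shell yields the
three-dimensional network.

### Numerical choices in the chart

* **Quadrature.** $V$ is evaluated by the periodic trapezoid rule over
  equally spaced arc-length samples (spectrally accurate for smooth closed
  curves).  Within a few sample spacings of the curve the $1/d$ integrand
  peaks too narrowly for the base rule; those grid nodes are re-evaluated
  with the sample count scaled to their distance (the rule converges like
  $e^{-2\pi n d / L}$), and nodes lying on the curve receive the limit value
  $N(s)$ directly.
* **Gridding.** $V$ is precomputed on a regular grid (default spacing: the
  ventricular voxel spacing) and queried by bilinear interpolation;
  `field_at(..., exact = TRUE)` re-runs the quadrature for verification.
* **Integration.** Classical fixed-step RK4 on the *normalized* field.  The
  time parameter of the trajectory system is artificial -- only the traced
  path matters -- so normalizing $V$ to unit magnitude is a pure
  reparameterization that makes the step a path-length step and $t$ a
  signed path length.  Inward trajectories stagnate where $V \to 0$ (for
  example at the center of a convex curve) and are truncated with a flag.
* **Branch cut.** $s$ is interpolated through the embedding
  $(\cos 2\pi s/L, \sin 2\pi s/L)$ and recovered with atan2, so the
  $s = 0/L$ seam leaves no artifact.
* **Scattered interpolation.** Chart maps assign each grid node the
  inverse-distance weighted value of its 4 nearest trajectory points;
  deterministic and mesh-free.  Default 256 seeds; the seed spacing $L/256$
  bounds the chart's $s$ resolution.

## Geometry: phase fields and the endocardial shell

Ventricular anatomy enters as a phase field $\phi \in [0,1]$ on a uniform
voxel grid (1 = tissue), which both defines the tissue mask
($\phi \ge 0.5$) and imposes no-flux boundaries in the solver.  The chamber
cavity is the 6-connected flood fill of $\{\phi < 0.5\}$ from a seed voxel.
The endocardial layer is extracted as in the source procedure: convolve the
chamber indicator with a voxelized spherical kernel (default radius 3
voxels), keep entries strictly greater than 1, and intersect with tissue;
the result overlaps the wall by roughly the kernel radius.  The
strictly-greater-than-1 threshold is taken literally; note that with a
radius-1 kernel it keeps only voxels touching at least two cavity voxels,
i.e. a strict subset of the one-voxel dilation.

The cylinder axis must be one of the principal grid axes; reorienting
misaligned volumes is out of scope.

## Projection and its failure mode on coarse grids

`project_network()` marks every shell voxel whose center maps to a fiber
texel.  When the texel size is comparable to the voxel size -- exactly the
regime of interest, since one texture pixel is matched to about one grid
cell -- center sampling alone *aliases* one-pixel-wide fibers: whole texels
fall between voxel centers and the voxelized network breaks into fragments.
Two complementary repairs keep the network electrically connected:

1. **Per-pixel seeding.**  Every fiber pixel is also mapped to its nearest
   shell voxel in the $(s, z)$ metric, so the texture-to-volume map is onto.
2. **Bridging dilation.**  Where two 8-adjacent fiber pixels land on voxel
   groups that are not 26-adjacent, shell voxels adjacent to both groups
   are added (a one-voxel bridge; the network never grows beyond that).

Coupling sites are mapped to the nearest projected-network voxel along the
trajectory through the site's $(s, z)$; sites with no voxel within 3 voxel
widths are reported unmapped.  Site-to-voxel assignment ties break on the
lowest linear index, for determinism.

Aspect-ratio distortion of the placement rectangle is allowed (and
routinely useful: a single network image must stretch over endocardia of
different sizes); `preserve_aspect = TRUE` enforces
$(b-a)/(d-c) = W/H$ when wanted.

## Electrophysiology

Excitation follows the monodomain equation
$\partial_t v = -I_\mathrm{ion} + \nabla \cdot (D \nabla v)$ with the
two-variable Mitchell-Schaeffer membrane model:

$$I_\mathrm{ion} = -\frac{h v^2 (1 - v)}{\tau_\mathrm{in}}
  + \frac{v}{\tau_\mathrm{out}}, \qquad
  \dot h = \begin{cases}(1 - h)/\tau_\mathrm{open} & v < v_\mathrm{gate}\\
  -h/\tau_\mathrm{close} & v \ge v_\mathrm{gate}\end{cases}$$

Defaults (ms): $\tau_\mathrm{in} = 0.3$, $\tau_\mathrm{out} = 6$,
$\tau_\mathrm{open} = 120$, $\tau_\mathrm{close} = 150$,
$v_\mathrm{gate} = 0.13$.  These are package defaults (the source work does
not print its values); every one is configurable.  The gate uses the exact
exponential solution of its piecewise-linear ODE per step, which keeps
$h \in [0,1]$ unconditionally.  $v$ advances by forward Euler.

Diffusion is discretized in divergence form with phase-field face weights,

$$\dot v_i \mathrel{+}= \frac{1}{\phi_i} \sum_{j \in \mathcal{N}(i)}
  \frac{\phi_i + \phi_j}{2}\, \frac{D_i + D_j}{2}\,
  \frac{v_j - v_i}{\lVert x_j - x_i \rVert^2},$$

which enforces no-flux boundaries on the irregular tissue boundary and
conserves $\sum_i \phi_i v_i$ exactly (the acceptance suite checks
conservation to $10^{-10}$ per step).  Bulk ventricular tissue uses the
face (6-neighbor) stencil.  The Purkinje domains use the full 8/26-
neighborhood with distance-scaled conductances: a voxelized fiber chain
runs diagonally as often as not, and face-only coupling would sever it.
The stability check is the Gershgorin bound
$\Delta t \le 1 / \max_i \sum_j g_{ij}/\phi_i$, which reduces to the
textbook $h^2 / (2 \cdot \mathrm{dim} \cdot D)$ for uniform face stencils;
the default step is 80% of the tightest bound across domains.

Purkinje diffusivity is 20 times the ventricular $D_0 = 0.001$
cm$^2$/ms, so the Purkinje conduction velocity is about $\sqrt{20} \approx
4.5$ times the myocardial one (CV $\propto \sqrt{D}$ in the monodomain
model; the suite verifies the ratio within 5%).

## The coupled 3D-3D and 3D-2D models

Both models share the ventricular domain.  The 3D-3D model voxelizes the
Purkinje network into the same grid; the 3D-2D model solves the network on
its own 2D pixel raster, one node per texture pixel, with physical spacing
$\Delta_P x = (b-a)/W$, $\Delta_P y = (d-c)/H$ -- the placement rectangle
extent per pixel, carrying proper length units.  Coupling is a symmetric
resistive exchange at the site pairs, applied in a second phase after both
domains have advanced:

$$v_v \mathrel{+}= \Delta t\, g_c (v_p - v_v), \qquad
  v_p \mathrel{+}= \Delta t\, g_c (v_v - v_p),$$

computed from the phase-1 values, so each pair's sum is conserved and the
large-$g_c$ limit approaches voltage clamping.

Two coupling-related choices deserve their rationale:

* **Coupling strength.**  $g_c$ is not stated in the source work.  A single
  junction voxel must ignite three-dimensional bulk myocardium, which has a
  liminal size: sustained injection of roughly 10/ms (on the dimensionless
  $v$ scale, at $D_0 = 0.001$, $h = 0.025$ cm) is the measured ignition
  threshold for a point source, while 2/ms fails.  The default is
  $g_c = 10$/ms; at 1/ms the ventricles never activate and the model cannot
  meet its stated purpose.
* **Stimulus region.**  The His-bundle entry is marked by a
  `bundle_branch` flag in the site list.  That marker is a stimulus
  location, *not* a Purkinje-myocardial junction (the His bundle is
  insulated), so it is excluded from the coupling set -- otherwise the
  ventricle would activate at the stimulus onset with no conduction delay.
  Because the fast network has a space constant of
  $\sqrt{20 D_0 \tau_\mathrm{out}} \approx 0.35$ cm, a one-node stimulus
  cannot ignite it either; the protocol therefore excites all network
  nodes within `stim_radius` (default 0.4 cm) of the flagged node, with
  amplitude 2/ms for 1 ms.

Activation maps record each node's first upward crossing of $v = 0.5$ with
linear sub-step interpolation.  `compare_maps()` implements the three
comparison schemes -- differences from the stimulus clock ($c = 0$), from
each model's first activation ($c = -(f_3 - f_2)$), and with the
least-squares offset, whose closed form is $c = -\overline{A_3 - A_2}$
(the brute-force grid search is retained as a test oracle only).  The
offset shifts but never reshapes the difference distribution, so the
standard deviation and range width are scheme-invariant.

## What the synthetic fixtures emulate -- and what they do not

No anatomical volumes or photograph digitizations are redistributable, so
the package generates its own study conditions (`reference_fixture()`,
seed 7, frozen by checksum):

* an **ellipsoid-pair** phase field on an $80^3$ grid at 0.025 cm spacing
  (the spacing of the real anatomical grids): two ellipsoidal cavities with
  walls sharing a septum, emulating a two-chamber ventricle pair at desk
  scale (the real grids are $138 \times 130 \times 152$ and
  $400 \times 320 \times 320$; those sizes remain supported but the suite
  runs in minutes at $80^3$);
* an **exact-cylinder** phase field whose cavity boundary is a true right
  cylinder, so the approximating-cylinder error is zero and the 3D-3D vs
  3D-2D comparison isolates the model-construction difference;
* a depth-4 **binary-tree network image** ($96 \times 96$, 16 leaf coupling
  sites plus the flagged root), emulating a digitized branch: a bundle
  origin, recursive branching, terminal junctions.

The synthetic cavities are closed at both poles, unlike real ventricles,
which open at the base; the chart degenerates at pole caps (the
cross-section shrinks to a point), so the reference placement trims 15% off
each axial end of the shell and keeps the texture on the well-charted band.

Passing the suite on these fixtures demonstrates the mapping and the
coupled dynamics are implemented correctly; it does *not* demonstrate
anatomical accuracy on real hearts, which depends on how well a cylinder
approximates a given endocardium, on the digitization quality, and on
placement choices that the original study made by eye against dissection
landmarks.  Real networks also have two orders of magnitude more coupling
sites (130 and 100 per branch in the source digitizations) than the toy
tree.

On the frozen fixture, both models activate 100% of ventricular nodes from
a bundle-branch stimulus, the earliest ventricular activations occur at
coupling-site voxels, and the two models' activation maps agree to an RMS
of well under 5 ms after the least-squares offset -- the desk-scale
analogue of the sub-2 ms agreement reported for real geometries.

## Known limitations

* Only isotropic (scalar or per-node) diffusivity: the face-stencil
  discretization does not implement cross-derivative terms, so full fiber
  orientation tensors are rejected rather than silently mishandled.
* The cylindrical approximation fails where the surface is far from a
  cylinder over a principal axis (e.g. near the apex); non-cylindrical
  approximating surfaces are out of scope.
* Trajectories far outside strongly non-convex curves can cross; the chart
  flags coverage gaps and multivalued cells rather than resolving them.
* No junctional delay model and no anterograde/retrograde asymmetry at the
  Purkinje-myocardial junctions; no bidomain model; no ECG.

## A minimal session

```{r example}
library(purkinjemap)

fx <- reference_fixture(seed = 7)
ph <- fx$ellipsoid$phase
mp <- map_network(ph, fx$ellipsoid$chamber_seeds[[1]],
                  fx$curve_ellipsoid, fx$network, fx$config)
r33 <- simulate_model(ph, mp, fx$network, "3d3d",
                      ep_config = fx$config$ep, t_end = 200)
r32 <- simulate_model(ph, mp, fx$network, "3d2d",
                      ep_config = fx$config$ep, t_end = 200)
compare_maps(r33$activation$ventricle, r32$activation$ventricle)
plot_isochrones(r33$activation$ventricle, slice = 40)
```
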