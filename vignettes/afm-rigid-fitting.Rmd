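---
title: "Rigid-body fitting to AFM images: model, search and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body fitting to AFM images: model, search and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmrigid)
```

## The problem

A high-speed AFM frame is a two-dimensional array of surface heights: the
topography of a biomolecule weakly bound to a mica stage, as felt by a
probe tip raster-scanned across it. Two unknowns stand between the image
and a three-dimensional interpretation: where (and in which orientation)
the molecule sits, and what the probe tip looks like — its radius varies
from sharpening run to sharpening run and cannot be imaged at the
relevant resolution. `afmrigid` infers both at once: it renders candidate
pseudo-AFM images from an atomic model over a discrete grid of placements
and tip geometries, scores each against the reference image, and returns
the best-scoring combination.

## Probe model and collision detection

The tip is a hemisphere of radius $r$ joined smoothly to a cone frustum
whose flank makes the half-apex angle $\theta$ with the vertical; the
frustum is treated as extending upward indefinitely, since specimen
heights (tens of nm at most) never reach a realistic frustum top. For a
pixel centred at lateral distance $d$ from an atom of radius $r_a$ whose
centre sits at height $z_a$, the apex height at first contact is

$$z_{tip} = \begin{cases}
 z_a + \sqrt{(r+r_a)^2 - d^2} - r, & d \le (r+r_a)\cos\theta \\
 z_a + \dfrac{r_a + r - d\cos\theta}{\sin\theta} - r, & \text{otherwise},
\end{cases}$$

the two branches meeting continuously at the regime boundary. A pixel's
height is the maximum of $z_{tip}$ over all atoms, floored at the stage
plane $z = 0$. These closed forms are verified in the test suite against
a brute-force oracle that samples the tip surface densely and descends it
onto the atom sphere; agreement is required to $10^{-3}$ nm across a
$10 \times 10 \times 10$ sweep of $(r, \theta, d)$. Because the cone
flank always touches the atom at *some* apex height, the closed form is
returned for every input; far from the atom the value is far below the
stage and the floor removes it.

Atoms are hard spheres. By default per-element van der Waals radii are
used (C 0.170, N 0.155, O 0.152, S 0.180, H 0.120, P 0.180 nm); a uniform
radius can be requested instead, and radius 0 reduces atoms to points.
All internal lengths are nm; PDB angstroms are converted on input.

## Trimming and the four scores

Reference images carry noise everywhere, and a search that scored the
full frame would happily park the molecule on a high-noise patch. Both
images are therefore trimmed to the minimum bounding rectangle of
strictly positive pixels of the *pseudo* image before scoring — the
noisy reference never influences the window.

Four cost functions are provided: cosine similarity (scale-invariant,
shift-sensitive), Pearson correlation (scale- and shift-invariant),
pixel-RMSD (sensitive to both) and the penalty score. The penalty
conditions overlap at exact equality in their piecewise definition; here
the protrusion branch is taken strictly ($H^{sim} > H^{ref}$) and the
reward band is $H^{ref} - t < H^{sim} \le H^{ref}$, matching the reading
that rewarded pixels lie *at or just beneath* the reference surface.
Windows on which a score is undefined — zero norm for cosine, zero
variance for correlation — evaluate to `Inf`, the worst possible cost,
so the search skips them without NaN propagation.

## The search grids

**Orientation.** A step $s$ (degrees, dividing 360 into a multiple of 4;
10° in production) places latitude rings at polar angles $ns$ from the +Z
pole. Ring $n$ carries $4n$ evenly spaced azimuths and the poles one
point each, so the equatorial ring ($n = 90/s$) is divided at exactly the
step spacing: 614 directions at 10°. Each direction is combined with all
$360/s$ spins about the new Z axis (22,104 rotations at 10°; the
octahedral 24 at 90°). A literal reading of "divide the $n$-th circle
into $n$ components" is also implemented (`ring_scheme = "n"`), but it
populates the sphere far more sparsely near the equator than the step
spacing implies, so the $4n$ rule is the default.  Spins are applied
uniformly, including at the poles, where they are redundant but keep the
enumeration simple and deterministic.

**Grounding.** After each candidate rotation the model is re-grounded so
that $\min(z_i - r_{a,i}) = 0$; without this, most orientations would
float above or clip through the stage. Z offsets are then searched only
when the reference contains a pixel taller than every pseudo-image pixel,
in steps of 0.064 nm (finer than the typical 0.05–0.15 nm vertical
resolution), and are applied by raising the non-zero pixels of the
rendered image rather than re-rendering.

**Translation.** Integer pixel offsets, over the full range where the
trimmed window stays inside the reference.

Ties are broken by enumeration order — orientation, then row-major
offset, then Z index, then probe — so a fit is fully deterministic. The
search reports the best placement per (orientation, probe) pair and ranks
those candidates for `top_k`; candidates differing only in translation or
Z within one orientation are collapsed to their best placement. On a
small instance the whole machinery is required by the tests to agree
exactly with a naive quadruple-loop enumeration written in plain R.

**Probe grid.** Radii $\{0.5, 1, 2, 3, 4, 5\}$ nm and half-apex angles
$\{5, \dots, 30\}$°, the range of tips encountered in practice; per-axis
refinement (e.g. 1° angle steps at a fixed radius) is just a different
`probe_grid()`.

## Stage correction and noise statistics

Experimental frames sit on a stage that is close to, but not exactly,
the scanner XY plane. `fit_stage_plane` fits $z = ax + by + c$ by
ordinary least squares over background pixels (manual rectangles or an
automatic low-quantile rule, default 25%), `subtract_plane` removes it
(without clipping at zero, preserving the symmetric background noise),
and `noise_sd` reports the residual standard deviation. Note that the
automatic quantile mask is height-selected and therefore biased low when
applied to pure noise; for quantitative noise estimates use masks chosen
independently of height (e.g. rectangles away from the specimen).
`affine_rescale` solves the post-hoc least-squares uniform scale/shift
between a best-fit pseudo-image and the reference, optionally restricting
the shift to non-positive values — useful when flexible loops compress
under the tip and the rigid model overshoots the observed height.

## Twin experiments

A twin experiment plants the answer: ground a model by its
oriented-bounding-box (largest PCA face down), render it with a known
probe, add Gaussian pixel noise, then hand the image to the search and
ask whether the planted probe and placement come back. Per replicate the
template is randomly re-oriented about X, Y and Z so the exact truth
orientation is off the search grid; recovery is judged by exact grid-cell
equality of the probe, and placement by structure-RMSD without
re-superposition (so the orientation step bounds the attainable RMSD).
Sub-filament templates are scored with the windowed RMSD: the minimum
over all consecutive monomer registrations in the longer ground truth.

The synthetic generators define the study conditions:

- `make_blob` samples beads uniformly in an ellipsoid, normalises the
  sampled ranges to the requested extents and applies a mild shear so the
  shape is chiral. The acceptance-level twin uses 1200 beads of radius
  0.3 nm in a 15 × 10 × 6 nm envelope — the bead density (~3 nm⁻³) and
  scale of a coarse-grained model of a large motor protein;
- pixel size 1 nm, noise sd 0.3 nm (the level measured in real high-speed
  AFM backgrounds), 10 noise replicates, probe grid radii 0.5–5 nm at
  10°/20°, ground truth 3 nm/20°;
- the orientation step is widened to 30° to keep a full 2 × 10-replicate
  study at roughly two minutes of compute; the 10° production grid uses
  the same code path and differs only in cost.

Under those conditions the cosine score recovers the planted radius in
7/10 replicates and the penalty score selects a radius at or below the
truth in 10/10 — the penalty's systematic preference for smaller probes
(fewer non-zero pixels means fewer chances to protrude) makes it
unsuitable for probe inference, which is precisely what the twin harness
is designed to expose. What passing twins do *not* show: robustness to
specimen flexibility, tapping-mode artifacts, scanner drift or
line-noise, none of which the generator emulates.

## Blind tip reconstruction

For comparison, the classic morphology-based estimator is included: an
outer bound on the tip is tightened iteratively from a flat start, using
the constraint that every image pixel must admit at least one feasible
tip-sample contact; the worst case over feasible contacts bounds each tip
pixel from above, and the iteration stops at a fixed point. A threshold
parameter relaxes every bound by the allowed noise violation depth.
Positions within one window of the border give no certain constraint, so
images must span at least twice the tip window. The estimate is
guaranteed blunter than (or equal to) the true tip; on a noiseless image
of an isolated spike it recovers the tip exactly, while on noisy
biomolecular images it degrades quickly and depends sensitively on the
threshold — the behaviour that motivates the parametric-tip search as the
primary method.

## Numerical choices

- Pixel $(i, j)$ (row 1 = lowest Y) has its centre at
  `origin + (j - 0.5, i - 0.5) * pixel_size`; frames are sized from the
  tip-dilated footprint of the model so no non-zero pixel is clipped.
- PCA axis signs in the grounding are fixed (largest-magnitude component
  positive), making `ground_on_stage` idempotent to 1e-9 nm and the
  choice between two equal OBB faces deterministic.
- Noise is reproducible under an explicit seed and never clips at the
  stage; twin replicates derive their seeds as `base + i` (noise) and
  `base + 10000 + i` (template re-orientation).
- Height maps are written as plain text at 1e-4 nm resolution, finer than
  the 0.064 nm Z step, so files round-trip bit-identically.
- Degenerate inputs fail loudly: collinear atom sets cannot be grounded,
  empty pseudo-images raise a distinct empty-window condition, and
  sub-pixel models simply render into a single-pixel frame.

## Known limitations

The fit is rigid: flexible loops, induced fit and tip-induced deformation
are not modelled, and for specimens with compressible surface regions the
shift-invariant correlation score (plus `affine_rescale` for post-hoc
comparison) is the pragmatic fallback. The orientation grid bounds the
attainable structure-RMSD; near-symmetric molecules can fit equally well
in flipped orientations, which shows up as bimodal RMSD across twin
replicates long before it shows up in the cost. Scan-line artifacts and
tapping-mode dynamics are out of scope.
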