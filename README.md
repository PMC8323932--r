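# afmrigid

Rigid-body fitting of atomic structures to atomic force microscopy (AFM)
height maps, with simultaneous inference of the probe-tip shape.

High-speed AFM records the surface height of single biomolecules at work,
but every image is a convolution of the specimen with the probe tip, whose
geometry is rarely known. `afmrigid` treats the tip as a hemisphere of
radius *r* capped by a cone of half-apex angle *θ*, generates pseudo-AFM
images from an atomic model by collision detection (per pixel, the lowest
apex height at which the descending tip touches any atom), and exhaustively
searches the discrete space of molecular orientation, XY translation, Z
offset, *r* and *θ* for the placement whose pseudo-image best matches a
reference image. Both the molecular placement and the effective probe
shape fall out of the same search. It is aimed at structural biologists
analysing high-speed AFM movies of proteins on a mica stage.

## Cost functions

With `H^(sim)` the pseudo-image and `H^(ref)` the reference, both trimmed
to the minimum bounding rectangle of non-zero pixels of the pseudo-image
(N pixels), the four scores are

- cosine similarity
  `c.s. = Σ_p H_p^(sim) H_p^(ref) / sqrt(Σ_p (H_p^(sim))² Σ_p (H_p^(ref))²)`,
  cost `V = 1 − c.s.`;
- Pearson correlation coefficient (same form with means subtracted),
  cost `V = 1 − c.c.`;
- pixel-RMSD `V = sqrt((1/N) Σ_p (H_p^(sim) − H_p^(ref))²)`;
- a penalty function: per pixel `+k_penalty` if the pseudo-image protrudes
  above the reference, `−k_reward` if it lies within a `thickness` band
  just beneath it, 0 otherwise (defaults 10, 1 and 1.2 nm).

The cosine and pixel-RMSD scores are linked by the identity
`V_RMSD(normalized)² = (2/N) V_c.s.(unnormalized)`, which the test suite
asserts to 1e-12.

## Worked example

```r
library(afmrigid)

# synthetic ground truth: an anisotropic blob grounded on the stage
blob  <- ground_on_stage(make_blob(50, c(8, 4, 2), seed = 3, radius = 0.3))
probe <- probe_shape(2, 15)                   # 2 nm radius, 15 degree
ref   <- render_afm(blob, probe, pixel_size = 1, margin = 2)

fit <- exhaustive_fit(blob, ref,
                      probes = probe_grid(radii = c(1, 2), angles = c(15, 25)),
                      score = "cosine", angle_step = 90)
fit
#> afm_fit (cosine): best cost 0 with probe 2.00 nm / 15 deg
#>   offset (3, 3) px, z offset 0.000 nm, 24 orientations x 4 probes
structure_rmsd(apply_fit(fit), blob)
#> [1] 3.764949e-17
```

The fit recovers the planted probe (2 nm/15°) with zero cost and places
the structure back on its ground truth to machine precision. A full twin
experiment (noise sd 0.3 nm, 10 replicates) is one call:

```r
rep <- run_twin(make_blob(1200, c(15, 10, 6), seed = 7, radius = 0.3),
                probe_shape(3, 20), noise_sd = 0.3, n_replicates = 10,
                probes = probe_grid(radii = c(0.5, 1, 2, 3, 4, 5),
                                    angles = c(10, 20)),
                angle_step = 30, seed = 2024)
radius_recovery_count(rep)
#> [1] 7
```

Seven of ten noise replicates recover the planted 3 nm tip radius; the
remainder pick a neighbouring grid cell.

A thin command-line front end with `generate`, `fit`, `twin`, `stage`,
`noise` and `blindtip` subcommands is installed under
`system.file("cli", "afmrigid.R", package = "afmrigid")`.

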