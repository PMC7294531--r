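---
title: "From CT angiography to a printable hollow vascular model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT angiography to a printable hollow vascular model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmold)
```

## The problem

Endovascular embolization of visceral artery aneurysms is planned on CT
angiography, but a scan cannot tell an interventionalist how catheters,
guidewires and embolic agents will actually behave in a particular vessel.
A 3D-printed *hollow* model of the aneurysm and its parent artery — a solid
block whose internal cavity reproduces the contrast-filled lumen — can be
connected to a sheath, filled with saline and navigated with real devices
before the procedure.

`vesselmold` implements the computational portion of that fabrication
chain: from a CT volume in Hounsfield units (HU) to a watertight STL surface
a printer toolchain will accept. The physical printing itself (FDM, nylon)
and everything clinical downstream of it are out of scope.

## The segmentation model

Contrast-filled lumen appears as a high-intensity plateau over soft-tissue
background. The package models a voxel's intensity as a mixture of two
tissue classes, lumen at the histogram peak $p$ and surrounding tissue at an
assumed $b = 80$ HU. A boundary voxel that is half lumen by volume reads
approximately the mean of the two, which motivates the partial-volume
threshold

$$T = \frac{p + b}{2}, \qquad b = 80 \text{ HU},$$

the midpoint rule used throughout the pipeline. `threshold_from_peak()`
implements it exactly; a voxel is classified lumen when its value is
$\ge T$ (the inclusive convention is fixed so runs are bit-reproducible).
The peak $p$ is the mode of a 1 HU-wide histogram computed over a region of
interest around the aneurysm (`compute_histogram()`, `histogram_peak()`);
ties between equally tall bins resolve toward the lower HU value, the
conservative direction (more lumen kept). The ROI is user-supplied (a
sphere or box near the aneurysm) rather than auto-detected: aneurysm
detection is a different problem, and the histogram only needs a
lumen-dominated sample, not a precise outline.

The formula is strictly increasing in $p$, satisfies
$b \le T \le p$ whenever $p \ge b$, and degenerates to $T = b$ when the
lumen is no brighter than tissue — at which point the method has nothing to
segment and the code warns.

Thresholding alone keeps every bright structure (bone, other vessels), so
the mask then goes through connected *object selection*
(`select_component()`: the 26-connected component containing a seed voxel
placed in the target vessel) and optional *region cutting*
(`crop_box()`). 26-connectivity is chosen because thin oblique vessels can
touch diagonally across voxel corners; 6-connectivity would fragment them.
Masks are binarized to the two-level $\{0, 255\}$ scale consumed by the
surface step.

## Hollowing

The printed object is not the lumen, it is the material *around* the
lumen. The default construction (`make_block_complement()`) is literal
inversion bounded to a block: foreground is the lumen bounding box expanded
by `block_margin_mm` (default 5 mm of wall material) minus the lumen. If
the margin exceeds the scan extent the grid is padded, never truncated —
geometric fidelity of the cavity is the entire product. The exact identity
$|\text{solid}| + |\text{lumen}| = |\text{box}|$ holds by construction and
is tested.

An alternative thin-shell mode (`make_shell()`) dilates the lumen to a
constant *physical* wall thickness using a Euclidean distance transform
computed with the per-axis voxel spacing. CT voxels here are anisotropic
(0.5–0.8 mm slices versus ~0.6 mm pixels), so a voxel-count dilation would
give walls up to 60% thicker in-plane than through-plane; the
physical-distance criterion does not.

A sealed cavity would be unprintable and unusable, so at least one *port*
is mandatory: `open_ports()` extrudes the lumen cross-section at a seed
slice along a grid axis until it exits the solid, then verifies by
exterior flood fill (6-connectivity, the right notion for a fluid channel)
that the cavity actually connects to the outside. Ports are axis-aligned
straight channels — the simplest geometry that mates with a cylindrical
sheath.

## Surface extraction

`extract_surface()` extracts the iso-surface of the $\{0,255\}$ model mask
at level 128, the midpoint of the binarized scale, after padding the mask
with one background voxel so surfaces touching the grid edge still close.
The implementation marches the *tetrahedral* (Freudenthal) decomposition of
the voxel grid: each cube of eight neighbouring voxel centres splits into
six tetrahedra in a face-consistent way, and linear interpolation places
crossings halfway between foreground and background centres. Unlike the
classic cube-table variant, the tetrahedral walk has no ambiguous
configurations, so the output is watertight and edge-manifold *by
construction* — a hard requirement for slicers, and an invariant the test
suite checks on every extracted surface rather than trusts.

Two numerical consequences are worth knowing:

* For a clean two-level mask, any iso level strictly inside $(0, 255)$
  yields the *same* mesh combinatorics; only the crossing positions shift,
  by $(\text{iso} - 127.5)/255$ of a voxel. 128 is the canonical midpoint.
  At 128 the crossing sits $0.196\%$ of a voxel off exact centre — a
  sub-micron bias at CT resolution.
* Enclosed volume (signed, by the divergence theorem) tracks the voxel
  count times voxel volume to within a few percent for convex solids of
  radius ≥ 5 voxels; staircase chamfering accounts for the difference.

Vertices are emitted in millimetres, scaled per axis by the voxel spacing —
STL is unitless and every slicer assumes mm. Optional Taubin smoothing
(`smoothing_iterations`, default 0) is available but off: the reference
workflow printed unsmoothed surfaces and accepted layer stepping.

The array convention everywhere is axis 1 = slice (scanner z), axes 2–3 =
in-plane row/column, with `spacing`/`origin` in that order; mesh vertices
are the exception, using $(x, y, z)$ = (column, row, slice) as mesh
consumers expect. `validate_mesh()` reports watertightness, manifoldness,
orientation consistency, component count, volume, area and bounding box;
`mesh_summary()` adds a farthest-point diameter estimate used to sanity-check
model scale against the known aneurysm diameter.

## The synthetic phantom

No patient scans ship with the package; the `phantom` module generates
them. A phantom is an analytic vessel tree — polyline centerline with a
tube radius, a saccular aneurysm sphere, optional small side branches —
rasterized by voxel-centre membership, filled with a lumen plateau over an
80 HU background, blurred by a Gaussian point-spread of configurable FWHM
(the partial-volume stand-in), and overlaid with Gaussian noise. Noise is
added after blur, approximating reconstruction noise on top of the system
PSF. The pre-blur mask is returned as exact ground truth, so `dice()` and
`volume_error()` can score any segmentation without a human reference.

Four presets mirror the treated cases: aneurysm diameters 25, 10, 15 and
15 mm, and lumen plateaus 336, 406, 218 and 306 HU — the peaks that the
midpoint formula maps to the reported thresholds 208, 243, 149 and 193 HU.
The second preset carries a 0.8 mm side branch originating from the
aneurysm dome, echoing the pancreaticoduodenal case where selecting such a
branch was the point of the exercise. Preset grids are 64×80×80 voxels at
0.8 × 0.683 × 0.683 mm — the coarse end of the acquisition geometry the
models were built from, and small enough that the full pipeline runs in
seconds on one core; the vessel calibre (2.5 mm radius) is a typical
splenic artery. Presets default to a noiseless, unblurred acquisition so
worked examples are exact; measurement effects are opt-in
(`blur_fwhm_mm`, `noise_sigma_hu`), and the source histograms' ROI extent
and noise levels were never published, so those defaults are the package's
own and labelled as such.

What the phantom does *not* emulate: beam hardening, streak artefacts,
flowing-contrast inhomogeneity, surrounding anatomy with its own bright
structures, and patient motion. Passing recovery tests on phantoms
therefore demonstrates correctness of the *constructions* (threshold
formula, component selection, hollowing, meshing) under the stated imaging
model — not clinical segmentation performance on real scans.

## Determinism and degenerate inputs

All randomness flows from a single integer seed through the phantom
generator (Mersenne-Twister, inversion normals), restored after use so the
caller's RNG stream is untouched; the same config and seed give
byte-identical STL output, and staged execution through intermediate files
equals the single-shot pipeline bit for bit. Degenerate inputs fail loudly
rather than guess: empty ROIs (no histogram mode), seeds on background,
empty masks at meshing, sealed ports, inverted crop boxes, non-uniform
DICOM slice gaps beyond 1% and oblique acquisitions are all errors.

## File formats

DICOM series (uncompressed little-endian, axis-aligned; slices ordered by
Image Position (Patient) along the slice normal, never by filename), NIfTI
via RNifti, and MetaImage (`.mha`, double precision, bit-exact round trip)
for volumes and masks; STL in both binary (default — compact and
universally consumed) and ASCII dialects for surfaces. The mask
interchange format between pipeline stages is MetaImage: the workstation
formats used in the original workflow are proprietary and undocumented, so
the package defines its own lossless intermediate instead of emulating
them.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(phantom_preset = "patient1", output_dir = "run1")
report <- run_pipeline(cfg)
report$threshold_hu   # 208: (336 + 80) / 2
report$mesh_report    # watertight, manifold, single component
```

The same run from a shell, via the installed script:

```sh
vesselmold run --config demo_patient1.yaml --output run1 --seed 1
```

## Known limitations

* Segmentation is a global threshold plus connectivity; no vesselness
  filtering or learning. Vessels whose lumen intensity differs strongly
  from the histogram ROI's will be under- or over-segmented.
* The histogram ROI must be supplied for real scans; only phantoms get one
  automatically.
* Oblique DICOM orientations and compressed transfer syntaxes are
  rejected, not resampled.
* The farthest-point diameter is exact for convex symmetric cavities only.
* Ports are straight and axis-aligned; threaded or angled connectors are a
  printing-side concern.
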