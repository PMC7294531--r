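# vesselmold

Turn contrast-enhanced CT angiography into 3D-printable **hollow vascular
models** — solid blocks whose internal cavity reproduces a patient's vessel
and aneurysm lumen, so endovascular embolizations can be rehearsed with
real catheters, guidewires and embolic agents before the procedure.

The package implements the computational portion of that fabrication
workflow for visceral artery aneurysms, plus a synthetic phantom generator
so every stage is testable without patient data. Physical printing (FDM)
and everything clinical are out of scope.

## The method

Contrast-filled lumen is a high-intensity plateau over soft tissue. With
the lumen histogram peak *p* (the "peak distributed CT intensity" over a
region of interest around the aneurysm) and an assumed surrounding-tissue
level *b* = 80 HU, the segmentation threshold accounts for the partial
volume effect by sitting midway between the two classes:

> *T* = (*p* + 80) / 2

A voxel ≥ *T* is lumen. The mask is refined by connected 3D object
selection (26-connectivity from a seed voxel) and optional region cutting,
binarized to {0, 255}, then **inverted** into a bounded solid block (default
5 mm margin) whose cavity is the lumen; axis-aligned ports open the cavity
to the exterior for sheath connection. The printable surface is the
iso-surface of the model mask at level 128 — extracted on the tetrahedral
decomposition of the voxel grid, so it is watertight and edge-manifold by
construction — scaled to millimetres by the per-axis voxel spacing and
written as STL (binary or ASCII).

For the four bundled presets the lumen peaks 336, 406, 218 and 306 HU map
to thresholds **208, 243, 149 and 193 HU**.

Supported formats: DICOM series (uncompressed little-endian), NIfTI,
MetaImage for volumes/masks; STL for surfaces. Segmentation quality can be
scored against phantom ground truth with `dice()` and `volume_error()`;
`validate_mesh()` reports watertightness, manifoldness, orientation,
enclosed volume and surface area before anything goes near a printer.

## Worked example

```r
library(vesselmold)
cfg <- pipeline_config(phantom_preset = "patient1", output_dir = "run1", seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
[vesselmold] generated phantom preset 'patient1' (64x80x80 voxels)
[vesselmold] histogram peak 336 HU -> threshold 208 HU, 23812 lumen voxels
[vesselmold] block_complement model: 198284 solid voxels
[vesselmold] surface: 226204 faces, watertight=TRUE, volume 73971.4 mm^3
<run_report>
  peak 336 HU, threshold 208 HU (background 80 HU)
  lumen 23812 voxels (8886.4 mm^3), mode block_complement
<mesh_report>
  watertight TRUE, manifold TRUE, consistently oriented TRUE, 1 component(s)
  enclosed volume 73971.4 mm^3, surface area 14884.9 mm^2
  bounding box 60.1 x 37.56 x 36.8 mm
```

Reading the output: the patient-1 preset emulates a 25 mm splenic-artery
aneurysm whose lumen intensity peaks at 336 HU; the partial-volume formula
gives (336 + 80)/2 = 208 HU; 23 812 voxels (8 886 mm³) of lumen survive
thresholding and object selection; the inverted block model encloses
~74 cm³ of printable material around that cavity, and its surface is a
single watertight component — `run1/` now holds `phantom.mha`,
`lumen.mha`, `hollow.mha`, `model.stl` and a `report.json` with the same
numbers.

The same pipeline runs from a shell through the installed script (see
`?cli_entry` for the `phantom` / `segment` / `hollow` / `mesh` stage
subcommands, which compose bit-identically with the single-shot run):

```sh
vesselmold run --config demo_patient1.yaml --output run1 --seed 1
```

A demo config ships at `inst/extdata/demo_patient1.yaml`.

## Package layout

* `R/`, `src/` — volume I/O (DICOM/NIfTI/MetaImage, STL), phantom
  generator, segmentation, hollowing, meshing, pipeline + CLI; compiled
  kernels (iso-surface, components, distance transform, blur) in Rcpp.
* `tests/testthat/` — unit, property and end-to-end suites; fixtures are
  generated in code.
* `vignettes/hollow-vascular-models.Rmd` — the methods write-up: model
  assumptions, parameter choices, numerical conventions, limitations.
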