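# Demo pipeline configuration: patient-1 preset phantom (25 mm splenic-artery
# aneurysm scale, lumen peak 336 HU over 80 HU tissue).  Sub-sections mirror
# segmentation_config(), hollow_config() and mesh_config(); omitted keys take
# the package defaults (ports derived from the preset vessel ends).
phantom_preset: patient1
seed: 1
log_level: info
segmentation:
  background_hu: 80
  bin_width_hu: 1
mesh:
  iso_level: 128
  pad_voxels: 1
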