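# Default study configuration for the dbtrecon CLI.  Every key is optional;
# omitted keys fall back to the package defaults (which this file spells out
# for the main ones).
n_views: 15
arc_span: 15.0
fluence_per_view: 10000.0
fbp_kernels: [ramp, shepp_logan]
seeds: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9]
profile_half_length: 2.0
geometry:
  source_to_detector: 700.0
  source_to_support: 660.0
  detector_rows: 160
  detector_cols: 288
  pixel_pitch: 0.14
phantom:
  slab_thickness: 40.0
  volume_extent: [17.92, 17.92, 32.0]
  voxel_size: [0.14, 0.14, 1.0]
  attenuation_adipose: 0.046
  attenuation_glandular: 0.080
  bg_reference: [0.0, 0.0]
sart:
  n_iterations: 5
  relaxation: 1.0
mlem:
  n_iterations: 2
asdpocs:
  n_iterations: 5
  alpha: 0.002
  ng: 25
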