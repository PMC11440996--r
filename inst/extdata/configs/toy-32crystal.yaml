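# Desk-scale 4-ring scanner (32 transaxial crystals) used by the examples
# and the validation suite.  Small enough that the full sinogram (15 radial
# x 16 views x 16 planes) can be simulated and reconstructed in seconds.
name: toy-32crystal
scanner:
  n_rings: 4
  modules_per_ring: 4
  crystals_per_module: 8
  ring_radius_mm: 60.0
  axial_pitch_mm: 10.0
sinogram:
  n_radial: 15
  n_views: 16
  max_ring_difference: 3
  axis_order: PVR
# TOF bin grid sized to cover the in-FOV ray segments plus the 3-sigma
# kernel margin, as on clinical systems.
tof:
  num_tofbins: 11
  tofbin_width_mm: 20.0
  sigma_mm: 12.0
  num_sigmas: 3
image:
  shape: [25, 25, 7]
  voxel_size_mm: [4.0, 4.0, 6.0]
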