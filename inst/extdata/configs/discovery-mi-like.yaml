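# Clinical-scale preset modeled on a 20 cm axial FOV TOF PET/CT system.
# Crystal pitches are approximate (chosen for 20 cm axial coverage over 36
# rings); the sinogram plane count follows from max_ring_difference (all
# ring pairs -> 36^2 = 1296 planes).
name: discovery-mi-like
scanner:
  n_rings: 36
  modules_per_ring: 34
  crystals_per_module: 16
  ring_radius_mm: 380.0
  axial_pitch_mm: 5.5556
  axial_center_offset_mm: 0.0
sinogram:
  n_radial: 415
  n_views: 272
  max_ring_difference: 35
  axis_order: PVR
tof:
  num_tofbins: 29
  tofbin_width_ps: 169.0
  fwhm_ps: 385.0
  num_sigmas: 3
image:
  shape: [215, 215, 71]
  voxel_size_mm: [2.78, 2.78, 2.78]
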