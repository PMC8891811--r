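# Default simulation configuration. Every numeric default of sim_config()
# is spelled out here; values are SI unless the key says otherwise.
transducer:
  center_frequency_hz: 1000000.0
  aperture_diameter_m: 0.046
  curvature_radius_m: 0.110
  vertex_offset_m: 0.002
  drive_amplitude: 1.0
grid:
  spacing_m: 0.000125
  radial_extent_m: 0.026
  axial_extent_m: 0.128
pml:
  wavelengths: 1.0
  target_reflection: 0.0001
  profile_order: 2
water:
  speed_of_sound_mps: 1482.0
  density_kg_per_m3: 998.0
  attenuation_db_per_m: 0.0
standoff_m: 0.020
radial_boundary: pml
source: bowl
layers: []
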