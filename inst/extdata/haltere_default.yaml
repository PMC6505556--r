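# Default haltere run configuration.
# Lengths in micrometres unless the key says otherwise.
geometry:
  section:
    kind: annulus        # annulus | plus
    r_out_um: 150
    r_in_um: 50
    # for kind: plus use height_um / thickness_um instead
  bulb:
    shape: sphere        # sphere | ellipsoid
    radius_um: 500
    # for ellipsoids: semi_axes_um: [353.55, 353.55, 1000]  (x', y', z')
    offset_um: [0, 0]    # centre-of-mass offset along (y', z')
    density: 1200        # kg m^-3
  stalk_length_um: 5000  # base to bulb centre of mass
  n_elements: 31
material:
  youngs_modulus_pa: 1.5e9
  density_kg_m3: 1200
  poisson: 0.33
kinematics:
  amplitude_rad: 1.5707963268   # pi/2
  frequency_hz: 40
  rotation_rate_rad_s: 10       # 0 = flapping only
  ramp_periods: 2
  total_periods: 10
  analysis_periods: 5
  dt_s: 1.0e-5
filter:
  window_ms: 20
  freq_hz: 45
  center_ms: 8
  sd_ms: 3.5
  dt_ms: 0.1
  xi0: 0.5
  slope: 0.08
  pmax: 1.0
  threshold: 0.9
  strain_floor: 5.0e-6   # RMS strain detection floor
  floor_exponent: 4
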