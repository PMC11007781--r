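# Standard desk-scale dual-aperture study: two 64-element curved arrays at
# an 80-degree inter-probe angle imaging a pulsating vessel (10 mm inner
# radius, 1.7 mm wall) at 40 mm depth; 5 steered diverging waves per
# probe; 11 frames over one cycle with a 2% peak inner-radius excursion.
seed: 42
mode: bistatic
scene:
  center: [0.0, 40.0]
  inner_radius: 10.0
  wall_thickness: 1.7
  wall_density: 10.0
  background_density: 3.0
acq:
  n_elements: 64
  pitch: 0.508
  radius: 49.57
  f0: 3700000.0
  fs: 14800000.0
  c: 1540.0
  prf: 4000
  angles: [-12.0, -6.0, 0.0, 6.0, 12.0]
model:
  n_frames: 11
  excursion: 0.02
register:
  init_error: [5.0, 5.0, 3.0]
  max_iter: 50
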