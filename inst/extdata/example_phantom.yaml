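# Small example phantom specification for the `simulate` CLI subcommand:
# a 48^3 head with one deep-grey nucleus pair and a venous arc.
grid_shape: [48, 48, 48]
b0_tesla: 3
noise_sd: 0.07
seed: 20220629
echo_times_s: [0.003, 0.0084, 0.0138, 0.0192, 0.0246]
regions:
  - region: GM
    type: ellipsoid
    center: [0.5, 0.5, 0.5]
    semi_axes: [0.40, 0.45, 0.38]
  - region: WM
    type: ellipsoid
    center: [0.5, 0.5, 0.5]
    semi_axes: [0.30, 0.34, 0.27]
  - region: GP
    type: ellipsoid
    center: [0.39, 0.51, 0.50]
    semi_axes: [0.05, 0.07, 0.06]
  - region: GP
    type: ellipsoid
    center: [0.61, 0.51, 0.50]
    semi_axes: [0.05, 0.07, 0.06]
  - region: vein
    type: cylinder_arc
    center: [0.5, 0.5, 0.5]
    axis: 1
    radius: 0.24
    tube_radius: 0.022
    angle_deg: [30, 180]
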