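# Example simulator scene: three motility regions on a frozen-speckle
# background, 512 frames at 100 Hz.
width: 48
height: 48
frame_rate: 100
n_frames: 512
background_level: 10000
reference_level: 1000
shot_noise: false
seed: 42
regions:
  - rect: [4, 4, 19, 19]
    model: {kind: relaxation_phase, amplitude: 800, rate: 1, seed: 11}
  - rect: [28, 4, 43, 19]
    model: {kind: relaxation_phase, amplitude: 800, rate: 20, seed: 12}
  - circle: [24, 34, 8]
    model: {kind: white_intensity, amplitude: 300, seed: 13}
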