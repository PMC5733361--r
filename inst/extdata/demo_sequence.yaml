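# Demo sequence: a drifting soft-edged disc over gray, then a binary random
# checkerboard, then a sine grating edge-enhanced by a difference-of-
# Gaussians filter and renormed back into the displayable range.
label: demo
seed: 7
geometry:
  width_px: 48
  height_px: 48
  frame_rate_hz: 60
stimuli:
  - label: moving_disc
    duration_frames: 20
    components:
      - type: primer
        name: disc
        params:
          center_x: 8
          center_y: 24
          radius: 6
          edge_width: 2
          fill_color: 1.0
          background_color: 0.25
      - type: motion
        name: linear
        params:
          velocity_x: 90
          velocity_y: 0
      - type: modulation
        name: sine
        params:
          mean: 0.6
          amplitude_start: 0.4
          amplitude_end: 0.4
          frequency_start: 3
          frequency_end: 3
  - label: checkerboard
    duration_frames: 15
    components:
      - type: prng
        name: xorshift128
        params:
          rows: 12
          cols: 12
      - type: primer
        name: checkerboard
        params:
          mode: binary
  - label: filtered_grating
    duration_frames: 10
    components:
      - type: primer
        name: sine_grating
        params:
          spatial_frequency: 0.08
          orientation: 0.5
      - type: spatial_filter
        name: dog
        params:
          sigma_center: 1
          sigma_surround: 2
      - type: tonemap
        name: renorm
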