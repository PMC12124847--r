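# Default acquisition protocol: RF-spoiled 3D GRE on a small-bore system.
# Net spoiling moments: 3 cycles/voxel (readout), 3.76 cycles/voxel (slice).
# The lobe layout built from these values is a documented approximation
# (prephaser + readout plateau centered on TE + end-of-TR spoilers); replace
# individual lobes in code for an exact timing diagram.
protocol:
  tr: 20          # ms
  te: 4           # ms
  voxel_readout: 0.30   # mm
  voxel_slice: 0.78     # mm
  readout_cycles: 3
  slice_cycles: 3.76
  matrix_size: 100
  bandwidth_khz: 50
  prephaser_dur: 1      # ms
  spoiler_dur: 2        # ms
tissue:
  t1: 540      # ms (CuSO4-doped water)
  t2: 340      # ms
  d: 1.93e-3   # mm^2/s
sweep:
  flips: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90]
  psi: [50, 115.4, 117, 150, 169]
  d: [0]
  tr: [20]
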