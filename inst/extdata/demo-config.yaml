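# End-to-end demo: toy bias-exchange metadynamics on the canonical 2D
# three-well potential, free-energy recovery, landscape + path extraction,
# and a two-state HDX population-recovery study.  All randomness derives
# from `seed`.
seed: 42
output_dir: metafes-demo
temperature: 298
simulate:
  potential:
    centers: [[-0.8, -0.5], [0.8, -0.5], [0.0, 0.7]]
    depths: [4.5, 4.0, 3.5]
    widths: 0.3
    confinement: 2.0
  nSteps: 60000
  timestep: 0.005
  friction: 1.0
  exchangeInterval: 500
  recordStride: 10
  start: [-0.8, -0.5]
  replicas:
    - {biased: [1, 2], height: 0.12, sigma: 0.15, pace: 250}
    - {biased: [1, 2], height: 0.12, sigma: 0.15, pace: 250}
    - {biased: [1, 2], height: 0.12, sigma: 0.15, pace: 250}
    - unbiased
fes:
  edges: {lower: [-1.8, -1.8], upper: [1.8, 1.8], nBins: 36}
  minCount: 20
  discardFraction: 0.3
landscape:
  x: 1
  y: 2
  nBlocks: 10
path:
  start: [-0.8, -0.5]
  end: [0.8, -0.5]
  startLabel: OF
  endLabel: IF
hdx:
  nResidues: 30
  nFrames: 80
  truePopulations: {A: 0.8, B: 0.2}
  rho: 0.7
  times: [0.2, 0.5, 1.5, 4.0, 8.0, 15.0]
  gamma: 1000
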