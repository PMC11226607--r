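# Desk-scale preset: tiny backbone on 64x64 synthetic leaf images.
data:
  root: null
  testFraction: 0.3
  seed: 1
model:
  backbone: tiny
  upsampleSize: 16
  regionGrid: 4
  pyramidLevels: [2, 3]
  poolMode: average
  gcnLayers: 2
  gcnEnabled: true
  dropoutRate: 0.3
  headNorm: layer
  seed: 1
train:
  learningRate: 0.02
  epochs: 30
  batchSize: 12
  lrDropFactor: 5
  lrDropEpoch: 20
  momentum: 0.9
  augment: null
  seed: 1
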