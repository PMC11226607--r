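# Full-scale training protocol preset: 256 -> 224 random crop, SGD with
# categorical cross-entropy, 150 epochs with the learning rate divided by 5
# after 100, dropout 0.3, 4x4 region grid, pyramid levels (2, 3), two
# 2048-wide graph-convolution layers on a complete node graph.
data:
  root: null          # set to the class-per-folder dataset root
  testFraction: 0.3
  seed: 1
model:
  backbone: xception
  upsampleSize: 16
  regionGrid: 4
  pyramidLevels: [2, 3]
  poolMode: average
  gcnLayers: 2
  gcnFeatures: 2048
  gcnEnabled: true
  dropoutRate: 0.3
  headNorm: layer
  seed: 1
train:
  learningRate: 0.001
  epochs: 150
  batchSize: 12
  lrDropFactor: 5
  lrDropEpoch: 100
  momentum: 0.9
  freezeBackbone: true
  augment:
    rotationDeg: 20
    scaleFrac: 0.20
    translateFrac: 0.20
    flip: true
    noiseSd: 5
    cropSize: 224
  seed: 1
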