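# Example run configuration for runPipeline(). All stage parameters
# shown here equal the package defaults; omit any block to use them.
seed: 42
simulation:
  nTranscripts: 2000
  nPerGroup: 10
  genderBalance: 0.5
  baselineSd: 0.5
  deSpec:
    - size: 100
      group: MSA-P
      logFC: 1.5
contrasts:
  - "MSA-P:CTRL"
  - "MSA-C:CTRL"
stability:
  k: 4
  nIter: 100
  nPerm: 100
  detectP: 0.05
  qCutoff: 0.0001
  scope: contrast
gsea:
  # gmt: path/to/collection.gmt   # omit to skip the GSEA stage
  nPerm: 1000
  minSize: 15
  maxSize: 500
  weight: 1
  pCutoff: 0.05
  nTop: 100
atlas:
  # path: path/to/atlas.tsv       # omit to skip the atlas stage
  minSamples: 3
  fdrCutoff: 0.01
  fcCutoff: 2
  maxGenes: 800
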