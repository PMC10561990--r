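# Example run configuration: five base-learner families, elastic-net
# meta-learner, pooled meta-training on 5-fold out-of-fold predictions.
base_learners:
  - method: random_forest
    grid:
      mtry: [10, 33]
      num.trees: [300]
      min.node.size: [5]
  - method: gradient_boosting
    grid:
      nrounds: [200]
      eta: [0.05, 0.1]
      max_depth: [3]
      subsample: [0.8]
  - method: svm_radial
    grid:
      C: [1, 10]
      sigma: [0.01]
  - method: elastic_net
    grid:
      alpha: [0.5, 1]
      lambda: [0.01, 0.1]
  - method: pls
    rows:
      - ncomp: 5
      - ncomp: 20
meta_learner:
  method: elastic_net
  rows:
    - alpha: 0.5
nfold: 5
train_each_fold: false
seed: 1
cores: 1
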