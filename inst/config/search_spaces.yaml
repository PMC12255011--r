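# Hyperparameter search spaces per learner family, versioned with the code.
# Types: int (uniform integer), float (uniform), logfloat (log-uniform).
gbdt_a:
  nrounds: {type: int, low: 50, high: 400}
  eta: {type: logfloat, low: 0.01, high: 0.3}
  max_depth: {type: int, low: 3, high: 10}
  min_child_weight: {type: int, low: 1, high: 10}
  subsample: {type: float, low: 0.6, high: 1.0}
  colsample_bytree: {type: float, low: 0.5, high: 1.0}
  reg_lambda: {type: logfloat, low: 0.01, high: 10.0}
gbdt_b:
  nrounds: {type: int, low: 50, high: 400}
  eta: {type: logfloat, low: 0.01, high: 0.3}
  max_leaves: {type: int, low: 7, high: 127}
  min_child_weight: {type: int, low: 1, high: 10}
  subsample: {type: float, low: 0.6, high: 1.0}
  colsample_bytree: {type: float, low: 0.5, high: 1.0}
  reg_lambda: {type: logfloat, low: 0.01, high: 10.0}
random_forest:
  num_trees: {type: int, low: 100, high: 600}
  mtry_frac: {type: float, low: 0.05, high: 0.8}
  min_node_size: {type: int, low: 1, high: 10}
knn:
  k: {type: int, low: 1, high: 25}
logistic:
  decay: {type: logfloat, low: 0.00001, high: 1.0}
  maxit: {type: int, low: 100, high: 300}
mlp:
  size: {type: int, low: 4, high: 64}
  decay: {type: logfloat, low: 0.00001, high: 0.1}
  maxit: {type: int, low: 100, high: 300}
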