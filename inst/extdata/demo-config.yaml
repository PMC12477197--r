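# Small synthetic end-to-end demo: generates a down-scaled dataset,
# preprocesses it, summarizes peaks, trains a subset of the registry,
# stacks the best models and writes per-sample decisions.
seed: 1
dataset:
  synthetic:
    separability: 2
    group_sizes: {A: 8, B: 6, C: 8}
    spectra_per_sample: [4, 6]
    grid: [300, 3400, 4]
preprocess:
  range: [300, 3400]
  step: 4
  snr_min: 3
peaks:
  unit: sample
models:
  fraction: 0.8
  smote_k: 3
  names: [MLP, ANN, LDA, NB, KNN]
ensemble:
  top_k: 3
  k_folds: 4
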