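variable: sample_size
values: 20, 60, 100
pipelines: logreg
schemes: split, kfold, nested, fs_out, tune_out
runs: 10
n_features: 50
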