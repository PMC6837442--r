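variable: discriminable_sample_size
values: 20, 40, 60, 80, 100, 120, 140, 160, 180, 200, 220, 240, 260, 280, 300,
 320, 340, 360, 380, 400, 420, 440, 460, 480, 500, 520, 540, 560, 580, 600,
 620, 640, 660, 680, 700, 720, 740, 760, 780, 800, 820, 840, 860, 880, 900,
 920, 940, 960, 980, 1000
pipelines: svm
schemes: kfold, nested, split
runs: 50
n_features: 50
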