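# synthetic SWC tree with controlled within-segment diameter variability
task: fixtures_tree
branch_depth: 3
noise_cv: 0.2
seed: 7
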