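# legacy vs corrected pool peak errors over the depth/decay grid
task: pool_error_grid
diameters: [0.2, 0.5, 1.0, 2.0, 6.0]
depths: [0.05, 0.1, 0.15, 0.2, 0.25]
betas: [0.02, 6.86, 10]
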