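# per-diameter shell counts and outer depths for both discretization schemes
task: geometry_audit
shell_d: 0.1
diameters: [0.2, 0.4, 0.6, 1.0, 2.0, 4.0, 6.0]
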