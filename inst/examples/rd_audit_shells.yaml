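# variable- vs fixed-depth scheme peak errors of the buffered model
task: rd_audit_shells
diameters: [0.5, 1.0, 2.0, 4.0, 6.0]
scalings: [0.5, 1, 2]
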