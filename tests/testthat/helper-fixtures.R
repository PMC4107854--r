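# shared fixtures for the suite

REST <- 45e-6  # resting calcium, mM

# a short transient influx waveform (two inward alpha pulses)
burst_wf <- function(t_end = 60) {
  make_spike_burst_waveform(2, 15, 0.02, 2, t_end = t_end)
}

# default ramp-driven P-type influx
ramp_drive <- function(scale = 1) {
  ghk_drive(ghk_channel(), ramp_protocol(), scale = scale)
}

# write SWC text lines to a temp file
swc_file <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# clean tapered test tree (deterministic)
taper_tree <- function(noise_cv = 0, taper = 0.7, depth = 2, seed = 7) {
  generate_tree(tree_recipe(branch_depth = depth, points_per_segment = 8,
                            segment_length = 16, base_diam = 2, taper = taper,
                            noise_cv = noise_cv, seed = seed))
}
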