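# dendroca

Diameter-dependent intracellular calcium dynamics in dendritic compartmental
models.

Peak dendritic Ca²⁺ levels are largely set by the surface-to-volume ratio
(SVR) of each branch: influx scales with membrane surface, dilution with
volume, and for a cylinder SVR ∝ 1/diam. Many published compartmental models
silently lose this diameter dependence through two implementation details:

1. **Single-pool models** with a submembrane shell volume of `SA·d`
   (`SP_old`) have constant SVR = 1/d — every branch produces the same
   transient. The corrected convention (`SP_new`) uses the true annular
   volume `π·d·(diam−d)·L`, i.e. an equivalent depth
   `d_eq = d − d²/diam` in the pool equation

   d[Ca]ᵢ/dt = −I_Ca(t)/(2·F·d_eq) − β([Ca]ᵢ − [Ca]₀)

2. **Radial 1D diffusion models** discretize the cross-section into
   concentric shells. The classic variable-depth scheme
   (`Shells = ⌊diam/(4d) + 1.5⌋`, outer depth `d1 = diam/(4(Shells−1))`)
   lets the submembrane depth drift between 0.75·d and 1.25·d with diameter,
   perturbing the current-to-concentration conversion; the fixed-depth
   scheme (`⌈diam/(2d)⌉` shells of depth `d`, adjusted core) keeps it
   constant.

The package implements both model families (with the full buffered dynamics:
calbindin, parvalbumin with Mg competition, surface pump with compensating
leak, GHK influx), a deterministic axisymmetric (r,z) finite-volume reference
solver, SWC morphology reading with per-segment diameter-CV statistics,
compartmentalization at two resolutions, and the summary analyses (integrated
calcium, adjacent-branch ratios, diameter-pair ratio maps). A synthetic
SWC-tree generator with controlled diameter variability provides all test
inputs.

For whom: modelers building compartmental neuron models who need correct
calcium mechanisms (or need to quantify the error of legacy ones), and anyone
studying how morphological detail propagates into calcium predictions.

## Worked example

```r
library(dendroca)

geom  <- compartment_geometry(diam = 0.5, L = 1)   # thin dendrite, um
drive <- ghk_drive(ghk_channel(), ramp_protocol()) # P-type GHK + voltage ramp

# single-pool model under both volume conventions
old <- simulate_pool(geom, pool_params(variant = "SP_old"), drive)
new <- simulate_pool(geom, pool_params(variant = "SP_new"), drive)
cat(sprintf("peak [Ca] SP_old: %.3f uM\n", 1e3 * max(old$ca)))
cat(sprintf("peak [Ca] SP_new: %.3f uM\n", 1e3 * max(new$ca)))
cat(sprintf("legacy peak error: %.1f%%\n",
            100 * (max(old$ca) - max(new$ca)) / max(new$ca)))

# detailed buffered radial-diffusion model on a fixed-depth shell stack
st  <- shells_fixed_depth(geom, 0.1)
res <- simulate_system(build_system(st), drive, t_end = 180)
tr  <- submembrane_trace(res)
cat(sprintf("detailed-model submembrane peak: %.3f uM at %.1f ms\n",
            1e3 * max(tr$ca), tr$time[which.max(tr$ca)]))
integrated_ca(tr, c(110, 130))   # 20 ms around the transient peak
```

Output:

```
peak [Ca] SP_old: 0.836 uM
peak [Ca] SP_new: 1.240 uM
legacy peak error: -32.6%
detailed-model submembrane peak: 22.847 uM at 120.0 ms
integrated calcium: 0.305339 mM ms over [110, 130] ms
```

Reading the numbers: in a 0.5 µm dendrite the legacy constant-SVR pool
underestimates the peak by a third — exactly `d_eq/d − 1` with `d = 0.169` µm
in the large-influx limit — while the detailed buffered model reaches much
higher submembrane concentrations than either pool, and its response depends
on diameter through both the SVR and the shell discretization.

Higher-level audits: `peak_error_grid()` maps the legacy-pool error over
(diam, d, β); `dm_dmfd_peak_errors()` and `fixed_shellcount_error_audit()`
quantify shell-discretization errors of the buffered model;
`diameter_pair_ratio_map()` predicts integrated-Ca contrasts between
compartment pairs; `diameter_cv()` and `compartmentalize()` analyze SWC
reconstructions. A thin command-line dispatcher lives at
`inst/cli/dendroca.R` with example YAML configs under `inst/examples/`.

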