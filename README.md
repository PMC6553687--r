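# phyllofield

Simulation and analysis of phyllotaxis — the regular arrangement of leaves
around a plant stem — with inhibitory-field models of the shoot apical
meristem (SAM). In this model family every existing leaf primordium emits
an inhibitory power against new primordium initiation, the inhibition
decays with distance, and the next primordium forms where the summed field
on the SAM periphery is weakest. The package is for theorists and
quantitative botanists who want to simulate these models, classify the
emergent patterns (distichous, Fibonacci/Lucas spiral, decussate,
tricussate, orixate, x-cycle), map them over parameter space, and analyse
the stability of the orixate arrangement.

## Models

Lengths are in units of the formation-circle radius `R0`, times
standardized by `V0/R0`; a primordium born at `t_m` sits at
`r_m = R0 exp(t - t_m)`.

* **DC1** — discrete, planar apex, one primordium per plastochron:
  `I(θ) = k Σ_m d_m(θ)^(-η)` with `r_m = R0 e^{G(n-m)}`,
  `G = ln(r_m/r_{m+1})` (log plastochron ratio). The new primordium takes
  the global field minimum. Parameters `η`, `G`.
* **DC2** — continuous time, conical apex of flatness `N = sin(ψ/2)`:
  `I(θ) = Σ_m E(d_m/d0)` with the threshold kernel
  `E(x) = Es (coth(αx) − 1)/(coth(α) − 1)`; a primordium forms immediately
  wherever `I < Es`, so plastochrons are emergent and whorls possible.
  Parameters `α`, `Γ = d0/(R0 N)`, `N` (`Es = 1`).
* **EDC1 / EDC2** — the same with each contribution multiplied by a
  logistic function of primordium age, `F(Δ) = 1/(1 + e^{−a(Δ−b)})`
  (rates/timings `a, b` in plastochrons; `A, B` in standardized time).
  The age-dependent inhibitory power is what makes orixate phyllotaxis —
  the tetrastichous alternate pattern with divergence cycle
  `(180°, 90°, −180°, −90°)` — attainable as a stable pattern.

The continuous engine is compiled (Rcpp); everything is deterministic.
See the vignette (`vignettes/inhibitory-field-models.Rmd`) for the model
assumptions, the conical-distance convention, numerical choices and
limitations.

## Worked example: an orixate pattern

```r
library(phyllofield)
params <- edc2_params(alpha = 1, Gamma = 2.8, N = 1/3, A = 4.8, B = 0.72)
trace  <- run_dc2(params)          # 0.1° grid, dt = 0.001, 100 primordia
trace
#> <phyllo_trace> EDC2, 100 primordia
#>   last divergence angles (deg): -89.4, -176.2, 89.3, 176.2, -89.3, -176.2, 89.3, 176.2
#>   last plastochrons: 0.327, 0.101, 0.324, 0.102, 0.326, 0.101, 0.325, 0.101

pattern <- classify_pattern(trace)
pattern
#> <pattern_class> four_cycle_alternate (cycle 4)
#>   angles (deg): -89.3, -176.2, 89.3, 176.2
#>   mean |divergence| = 132.8 deg
#>   angle ratio = 0.507, plastochron ratio = 0.309
```

The divergence angle cycles through four values close to `±90°` and
`±180°` — a tetrastichous, nearly orthogonal alternate pattern — and the
standardized plastochron oscillates between about 0.10 and 0.33, with the
longer interval on the `±90°` (adjacent) pairs: the signature of orixate
phyllotaxis. `ratio_stats(pattern)` returns the angle ratio (0.507; ideal
orixate is 0.5) and plastochron ratio (0.309) used in pattern scatter
plots, and `color_encode(pattern)` gives the HSL colour used by sweep
maps (`sweep_grid()` + `run_sweep()` + `render_map()`).

Other entry points: `run_dc1()` for the discrete models,
`inhibition_landscape()` / `make_normal_orixate()` for fixed-arrangement
stability probes, `solve_edc1_condition()` / `find_intersections()` for
the orixate stationarity curves, `dc1_orixate_scan()` for the
impossibility scan, `inhibition_map()` for contour maps, and the
`inst/cli/phyllofield` Rscript for shell use (`simulate`, `sweep`,
`classify`, `solve-orixate`, `landscape`).

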