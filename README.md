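# remapgeom

Simulation and population-geometric analysis of hippocampal place-field
remapping under the assumption of a linear decoder.

## The problem

When an animal moves between environments, hippocampal place cells
re-organize their firing fields ("remapping") — sometimes completely and
seemingly at random, sometimes partially, sometimes only in rate. `remapgeom`
is for computational neuroscientists who want to generate, compare, and
statistically fingerprint the three population-level mechanisms that can
produce remapping when the latent variables are linearly decodable from
population activity. Writing rates `r`, latents `z = (z_p, z_c)`, decoder
`D`, and its right pseudo-inverse `E = D⁺`, the pseudo-linear encoder

    r^A(p) = E^A z^A(p) + ν^A(z^A(p)),      D ν(·) = 0

offers exactly three environment-dependent degrees of freedom:

| mechanism | what changes | package scenario kinds |
|---|---|---|
| encoder-decoder (ED) | the map `E^A` | `multi_chart`, `grid_realign` |
| mixed-selective (MS) | the cognitive latents `z_c^A` | `space_feature`, `implicit_space`, `reward` |
| null-space (NS) | the null-space term `ν^A` | `null_space` |

Environmental variables are encoded as angles on a torus (per variable,
`α = π(p+1)` and `z = (cos α, sin α)`; multi-module grid codes scale the
angle by `(3/2)^f`), and steady-state firing rates solve the spike-coding
network's nonnegative quadratic program

    r*(p) = argmin_{r ≥ 0} ‖y(p) − D_y r‖² + 2 Tᵀ r,

solved by a compiled active-set method with a KKT certificate. Remapping is
quantified by population-vector **overlap** (cosine similarity of
environment-mean rates) and per-neuron **spatial correlation**, each against
a 20-realization permutation shuffle null with Bonferroni-corrected one-sample
t-tests, plus a decomposition of the remapping vector into spatial, cognitive,
and null-space norms.

## Worked example

```r
library(remapgeom)

cf  <- scenario_config("multi_chart", seed = 1)  # N = 256, Y = 16, K = 10
rec <- run_scenario(cf)
print(rec)
#> <run_record: multi_chart scenario, 10 environments, N = 256>
#>   median autoencoding rel. error: 0.0786
#> Remapping statistics over 45 pairs (45 used):
#>   overlap        0.3808  vs shuffle 0.3418  p = 1.87e-05 * (above shuffle)
#>   spatial corr   0.0387  vs shuffle 0.0369  p = 0.513 n.s.
```

Reading: the ten environments share a 16-dimensional embedding space, so
which neurons are co-active is structured (overlap significantly above its
shuffle null), while *where* each neuron fires is statistically
indistinguishable from random reassignment — the signature of encoder-decoder
remapping. A mixed-selective run (`scenario_config("space_feature")`) instead
leaves both statistics significantly above shuffle, and a null-space run
(`scenario_config("null_space")`) does the same while the activity change
stays out of the decoded subspace (`rec$ns$decoded_ratio` ≈ 0.07–0.12).

Lower-level entry points: `encode_angles()` / `decode_angles()` /
`encode_grid()`, `sample_cognitive_trajectory()`, `sample_multichart_map()`,
`sample_gridshift_map()`, `sample_decoder()`, `solve_rates()` /
`batch_solve()`, `analyze_ratemaps()`, `remap_norms()`,
`place_field_stats()`, `argmax_mosaic()`, `gnomonic_embed()`,
`reward_code_comparison()`.

A command-line front end wraps the runner:

```sh
Rscript inst/cli/remapgeom.R simulate --config cfg.yaml --out outdir
Rscript inst/cli/remapgeom.R analyze  --in outdir
Rscript inst/cli/remapgeom.R report   --in outdir
```

Persisted runs (full-precision CSV rate maps, stats table, JSON summary,
checksummed manifest) reload with `load_and_analyze()`, reproducing the
in-process statistics exactly; identical configs and seeds give byte-identical
outputs.

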