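---
title: "Simulating place-field remapping with linear decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating place-field remapping with linear decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remapgeom)
```

## The model

Hippocampal place cells fire at restricted locations, and the same population
re-organizes its firing fields ("remaps") when the animal moves to a new
environment. `remapgeom` simulates and analyzes remapping under a single
structural assumption: the environmental variables encoded by the population
can be read out with a *linear* decoder. Writing the population rates
$r \in \mathbb{R}^N$ and the latent representation
$z = (z_p, z_c) \in \mathbb{R}^Z$ of position $p$ and cognitive variables $c$,
the assumption $ \hat z = D r$ forces the most general encoder to be
*pseudo-linear*,

$$ r^A(p) = E^A z^A(p) + \nu^A\!\big(z^A(p)\big), $$

with $E = D^+$ the right pseudo-inverse and $\nu$ an arbitrary function in the
null space of $D$. The superscript $A$ indexes environments, and the three
ways this equation can change across environments define the three remapping
types the package generates:

* **encoder-decoder (ED)** — the map $E^A$ changes: either a random
  orthonormal rotation of the latent trajectory inside a shared embedding
  space (the multi-chart model), or coherent per-module phase shifts of a
  multi-module grid code (grid realignment);
* **mixed-selective (MS)** — the cognitive part of the latents $z_c^A$
  changes while the map is fixed: each environment carries its own smooth
  cognitive trajectory (space-feature coding), possibly with no explicit
  position code at all (implicit-space coding);
* **null-space (NS)** — only $\nu^A$ changes: neuron excitability
  (thresholds) is modulated so that different neurons carry the same decoded
  content.

### Angular coding

Environmental variables in $[-1, 1]$ are encoded as angles,
$\alpha = \pi(p + 1)$, and placed on the unit circle,
$z = (\cos\alpha, \sin\alpha)$, so the latent trajectory lives on a torus.
This yields localized, place-field-like tuning and a fixed-energy code.
Decoding inverts with `atan2(sin, cos)` mapped into $[0, 2\pi)$; with this
branch the round trip `decode(encode(p))` is the identity on $[-1, 1)$ (an
additive half-period constant, which some formulations carry, would cancel in
every relative statistic but break absolute decoding, so the package uses the
identity-preserving branch). The boundary $p = +1$ encodes identically to
$-1$; grids are therefore half-open and the decoder canonicalizes the seam to
$-1$.

Grid codes use $m$ modules with angular scale factors $(3/2)^{f_j}$ and
$f_1 = 0$ pinned, so the first module is a bijection with position and is the
only one used for decoding; the default exponents are $f = (0)$, $(0, 1)$,
$(0, 1, -1)$ for $m = 1, 2, 3$.

### The network

Steady-state rates come from the spike-coding network, whose fixed point
solves a nonnegative quadratic program,

$$ r^*(p) = \mathrm{argmin}_{r \ge 0} \; \lVert y(p) - D_y r \rVert^2
   + 2\, T^\top r, $$

with $y = R^A z$ the embedding-space input, $D_y \sim U_{norm}(Y \times N)$
random unit-column decoding weights (the code schemes `M`, `C`, `CM`, `pM`
impose mixed, conjunctive, conjunctive-mixed, or pure-and-mixed column
normalizations), and optimal thresholds
$T = \tfrac12\,\mathrm{diag}(D_y^\top D_y)$. The package solves this program
with an active-set method (Lawson–Hanson extended with the linear threshold
term, implemented in compiled code) and certifies every solution by its KKT
conditions: $g = D^\top(Dr - y) + T \ge 0$ and $r_i g_i = 0$, checked to
$10^{-6}$ in the tests. A tiny Tikhonov term ($10^{-9}$ of the mean Gram
diagonal) keeps degenerate active sets well posed and is removed by an exact
polish on the final support, so reported solutions solve the unregularized
program.

### Input normalization

Latent blocks are normalized before entering the network: with both
positional and cognitive blocks present each is scaled to norm $1/\sqrt 2$
(total norm 1), a single block to norm 1. For embedding dimensionalities
$Y > 4$ the input is then rescaled as $y \leftarrow Y\,y$. This linear-in-$Y$
rescale is what keeps the autoencoding accurate as dimensionality grows: the
thresholds stay at $1/2$ while the signal grows, so the threshold-induced
shrinkage of the decoded estimate becomes negligible (median relative
reconstruction error 0.08 on the reference multi-chart configuration; a
$\sqrt Y$ rescale, which a casual reading of the normalization might suggest,
leaves a 0.29 median error and visibly biased decoding).

## Remapping statistics

Analysis follows the population-vector methodology: rate maps are thresholded
at $10^{-3}$; the **overlap** $\omega(A,B)$ is the cosine similarity of the
environment-mean population vectors; the **spatial correlation** $\rho(A,B)$
is the mean cosine similarity of per-neuron rate maps over neurons active in
both environments. Each is compared against a permutation null — neuron
identities shuffled for $\omega$, random co-active neuron pairs $i \ne j$ for
$\rho$ — averaged over 20 realizations per environment pair, and the per-pair
statistics are tested against the overall shuffle mean with a two-sided
one-sample t-test at a Bonferroni-corrected threshold $0.05/n_{tests}$
($n_{tests} = 1$ for a single run; for the full-dimensional multi-chart
control we follow the published analysis of that comparison and use
$n_{tests} = 3$).

The remapping vector $\Delta r(p) = r^A(p) - r^B(p)$ is decomposed into a
spatial part $D_p \Delta r$, a cognitive part $D_c \Delta r$, and a null-space
part $\Delta r - E D \Delta r$, aggregated over the grid as a root mean
square. With an orthonormal encoder the squared total equals the sum of the
squared parts exactly; with random unit columns the identity is approximate
but the decomposition remains the diagnostic fingerprint of each remapping
type: ED remapping is all-spatial, MS remapping is cognitive-dominated, NS
remapping is null-space-dominated.

Expected signatures on the reference configurations:

| scenario | overlap vs shuffle | spatial corr vs shuffle |
|---|---|---|
| multi-chart ED (low-D) | above (significant) | indistinguishable |
| multi-chart ED (full-D) | indistinguishable | indistinguishable |
| grid realignment ED | above | indistinguishable |
| space-feature MS (low $\sigma$) | above | above |
| NS participation modulation | above | above |

## Reference configurations and problem sizes

The published parameter sweeps run to thousands of neurons; the package's
reference configurations are desk-scale versions chosen so each scenario runs
in seconds to tens of seconds while preserving every qualitative signature:

* `multi_chart`: $N = 256$, $Y = 16$, $P = 2$ (32×32 grid), $K = 10$
  environments; full-D variant $N = Y = 64$.
* `grid_realign`: $N = 96$, $m = 3$ modules, $P = 2$, $Y = Z = 12$,
  conjunctive code.
* `space_feature`: $N = 256$, $P = 2$, $C = 6$, $Y = Z = 16$,
  conjunctive-mixed code, $\sigma = 0.3$, GP length scale $v = 0.3$.
* `implicit_space`: as space-feature with $P = 0$ on a 1-d grid.
* `null_space`: a single multi-chart environment at the reference redundancy
  ($N = 256$, $Y = 16$, 1-d track), modulated at
  `spar` $\in \{0, 0.25, 0.5, 0.75, 1\}$ with 5 random suppression draws per
  value, compared against the default map (`spar = 0.5`).
* `reward`: $P = 1$, $C = 1$, $Y = 4$, $N = 32$, two environments with reward
  locations $\mu = \pm 0.5$ and spread $\sigma_r = 0.2$.

Two of these sizes deserve comment. The null-space scenario could be run on
the small network of the illustrative figures ($N = 48$), but threshold
modulation halves the active population, and at that size the surviving
subnetwork drops out of the accurate-coding regime — the activity change then
acquires a decoder-visible component of 15–22% rather than the sub-10% that
characterizes genuinely null-space-confined remapping. The reference
redundancy $N/Y = 16$ keeps even the modulated maps accurate, which is the
regime the NS mechanism describes. Likewise the reward example uses $N = 32$
rather than a minimal 16: the winner-take-all mosaic along a 100-point track
needs enough neurons for the winner-density contrast between reward zone and
corridor to be a stable property rather than a coin flip of the random
decoder draw.

### Parameters that matter

| parameter | meaning | default |
|---|---|---|
| $\sigma \in [0,1]$ | cognitive offset scale and GP amplitude (one knob) | 0.3 (MS) |
| $v > 0$ | GP length scale, normalized position units | 0.3 |
| `spar` $\in [0,1]$ | fraction of neurons at normal excitability | 0.5 default map |
| $T_{suppr}$ | suppression threshold | 10 (~10× baseline) |
| `rescale_cutoff` | $Y$ above which $y \leftarrow Yy$ applies | 4 |
| `n_shuffle` | shuffle realizations per pair | 20 |
| `field_fraction` | fraction of peak defining a place field | 0.1 |

The `spar` convention follows the sweep-figure reading: it is the *active*
fraction, so `spar = 1` releases all suppression ("cell birth" relative to
the default map at 0.5) and `spar = 0` silences everyone. The published
description of the procedure can be read with either sign; the package
documents and tests this one. With $T_{suppr} = 10$ a fully suppressed
small-$Y$ map is silent; overlap against a silent map is undefined and such
pairs are reported as `NA` with a note and excluded from the means and tests,
consistent with the observation that fully replaced maps do not admit
overlap measurements.

### Numerical choices

* Solver tolerances: optimality $10^{-10}$ scaled by the input magnitude;
  KKT certificate $10^{-6}$; rates below $10^{-15}$ clamped to zero (analysis
  re-thresholds at $10^{-3}$).
* GP sampling adds $10^{-8}$ jitter to the kernel diagonal; cognitive values
  are wrapped into $[-1, 1)$ (the same circle the angular code uses), which
  can create seam discontinuities — deliberately allowed.
* $\sigma = 0$ is taken as exactly zero cognitive input (the normal
  distribution with zero scale degenerates to the constant 0).
* Argmax ties in mosaics break to the lowest neuron index; mesh points where
  no neuron is positively excited are background.
* Haar sampling of orthonormal maps QR-orthogonalizes a Gaussian matrix and
  corrects column signs with the R-factor diagonal, giving exact rotation
  invariance in distribution.
* All sub-seeds derive from the master seed through a counter, so adding
  environments never perturbs earlier ones and every run is bit-reproducible.

## What the generator emulates — and what it does not

The synthetic environments reproduce the structural features the theory is
about: equally spaced position grids, smooth per-environment cognitive
trajectories with controlled variance, random orthonormal chart changes,
coherent grid-module phase shifts, and excitability modulation. They do not
emulate spiking variability, temporal dynamics within a traversal, learning
or plasticity across exposures, irregular sampling of positions, or
measurement noise of real recordings. A passing suite therefore demonstrates
that the three mechanisms produce their predicted population signatures in a
controlled steady-state setting — not that real hippocampal data will show
them at the same magnitudes.

## Worked example

```{r, eval = FALSE}
library(remapgeom)

cf <- scenario_config("multi_chart", seed = 1)
rec <- run_scenario(cf)
print(rec)
#> <run_record: multi_chart scenario, 10 environments, N = 256>
#>   median autoencoding rel. error: 0.0786
#> Remapping statistics over 45 pairs (45 used):
#>   overlap        0.3808  vs shuffle 0.3418  p = 1.87e-05 * (above shuffle)
#>   spatial corr   0.0387  vs shuffle 0.0369  p = 0.513 n.s.
```

The overlap sits significantly above its shuffle null — environments share a
low-dimensional embedding space, so the same neighborhoods of neurons recur —
while per-neuron field locations are statistically indistinguishable from
random reassignment, the fingerprint of encoder-decoder remapping.

## Known limitations

* The steady-state formulation only: no spiking, no within-trial dynamics,
  no path integration.
* Square grid-module geometry (frequency ratios of $3/2$); hexagonal
  twisted-torus geometry is out of scope.
* Significance tests treat environment pairs as independent samples, as the
  source methodology does; pairs sharing an environment are in fact
  correlated, so p-values are approximate.
* The implicit-space scenario cannot decode position (nothing encodes it);
  position-referenced statistics there describe the generator's hidden
  coordinate.
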