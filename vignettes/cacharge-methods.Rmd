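---
title: "Conformation-adaptive multi-spin charges: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation-adaptive multi-spin charges: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

Spin-crossover dynamics of the heme–O2 binding site couple three electronic
states (singlet, triplet, quintuplet). A force field for such dynamics needs
atomic partial charges that depend on both the spin state and the
conformation. `cacharge` fits that dependence statistically: per-atom,
per-spin random-forest regressors map a geometric descriptor vector to an
ESP-style charge, giving 14 atoms × 3 spins = 42 independent models for the
simplified Fe(C3N2)2(NH3)·O2 complex.

The prediction for atom *i* is the mean of its ensemble's B tree outputs,
and the reported uncertainty is the *population* spread of those outputs
(denominator B, not B−1). Both are recomputable from
`tree_predictions()`, which exposes the raw per-tree outputs; a test holds
the aggregation to within 1e−12 of external recomputation.

## Descriptors

Two featurizations are provided behind one training interface.

**Atom-centered symmetry functions** (`scheme = "sf"`): per atom, one
radial Gaussian term per element and one angular term per unordered element
pair, under the smooth cosine cutoff `fc`. The defaults — η = 1 Å⁻²,
R_s = 1 Å, λ = +1, ζ = 1, and R_c = 99 Å — use a single function per
component and a cutoff far beyond the molecular diameter, so every atom
pair contributes and the descriptor is a smooth, symmetry-respecting
encoding of the whole neighborhood. Invariance under rigid motions and
same-element permutation is by construction and is property-tested against
100 random motions; a naive triple-loop implementation serves as an
independent oracle at 1e−10.

Numerical choices: `cos θ` is clamped to [−1, 1] before exponentiation;
coincident atoms raise a degenerate-geometry error naming the pair rather
than propagating infinities; the angular sum runs over *unordered* neighbor
pairs, each counted once, which keeps the term symmetric in its two element
labels and avoids double counting (an ordered sum would merely scale
same-element components by 2, which a tree model absorbs, but the unordered
convention is fixed so that serialized models and layouts are unambiguous).

The layout is a pure function of elemental composition: components that are
identically zero for *every* atom by composition are dropped. The rule is
"can any center atom have two distinct neighbors covering the pair": for
this complex only Fe–Fe fails it (one Fe atom cannot be its own neighbor
pair), giving 5 radial + 15 − 1 angular = **19 components**. The same rule
applied to a single water molecule (2 H, 1 O) also drops O–O, giving 4 —
the rule is about realizability, not about any particular element.
Hydrogens are part of the composition and are featurized even though
charges are modelled only for the 14 heavy atoms; without them the count 19
is not reproducible from any composition reading.

**Internal coordinates** (`scheme = "internal"`): 11 chemically chosen
parameters (8 distances, the Fe–O12–O13 angle, 2 ring dihedrals) describing
the whole conformation; every atom's model then shares the same feature
vector. Angles are reported in degrees; dihedrals are signed in (−180, 180]
with a right-hand convention about the central bond, and exactly planar
trans arrangements report +180. Collinear atoms make a dihedral undefined
and error loudly.

## Forest training protocol

- **Split**: frames (not rows) are partitioned at random, so an atom's
  train and test conformations never mix; `round(fraction · N)` frames go
  to training (default fraction 0.5).
- **Trees**: B = 200 full-size bootstrap resamples, m features tried per
  split (`resolve_m()` supports counts, fractions of p, and the keywords
  `third`/`log2`/`sqrt`/`all`; the default `third` is the classic
  regression heuristic ⌈p/3⌉, and m = 5 is the setting selected for the 19
  symmetry functions by the `sweep_m()` diagnostic), variance-reduction
  splitting, grown until nodes are pure or below `min_samples_split = 2`.
- **Constant features** are excluded from the candidate pool before m is
  resolved: a split on them is never valid, and a backend that lets a node
  go terminal because its random candidate draw was all-constant would
  silently break the grow-to-purity contract on degenerate (noise-free)
  data. With no constant columns — the normal case — this is a no-op.
- **Seeding**: a single master seed fans out to per-(atom, spin) sub-seeds
  through a fixed integer mix, so training is deterministic and
  order-independent; all randomness in the package flows from explicit
  seeds, never hidden global state.
- **Backend**: the tree ensemble is delegated to `ranger` configured to
  this exact contract, with per-tree predictions kept accessible so the
  mean/spread aggregation stays in package code.

Model archives are single compressed RDS files embedding a format tag,
format version, the forests and all featurization metadata; loading
verifies the tag and version, and a reloaded model predicts bit-identically.

## The synthetic generator

The generator stands in for the non-deposited trajectory dataset. Each
frame draws the Fe–O12 distance uniformly from 1.8–4.0 Å and the
Fe–O12–O13 angle from 100–180°, places O2 on an idealized template (square
N4 plane at 2.0 Å, axial NH3 at 2.1 Å, O–O bond 1.25 Å), and jitters every
coordinate with N(0, 0.05² Å²) — a thermal-scale distortion of the whole
scaffold. True charges follow

q_a = μ(a, s) + α(a, s)·(g(d) − ½) + β(a, s)·(cos θ − E[cos θ]) + ε,

with g a sigmoid of the Fe–O12 distance (center 2.9 Å = the midpoint of the
sampled range, scale 0.35 Å, normalized to [0, 1] over that range — a
smooth bound/unbound charge-transfer switch), ε ~ N(0, 0.01² e²), and a
final uniform shift enforcing the exact total charge (default 0 e, the
natural choice for ESP charges of a neutral complex). Because the geometry
terms are centered and every parameter column sums to zero, μ is the center
of each atom's charge distribution and the sum constraint never shifts the
spin offsets.

The default tables encode the system's reported charge statistics: Fe
centered at 1.2/1.3/1.5 e across the three spins (singlet range roughly
0.2–2.1 e), triplet−singlet offset exactly 0.1 e and quintuplet−triplet
0.2 e for Fe, non-iron spreads of 0.5–0.7 e with O12 varying more than O13,
and a small zero-sum spin perturbation of the ring couplings so spin states
differ in shape, not just offset. The orientation coupling β is
concentrated on the axial site (Fe, N11, O12, O13): a remote ring atom's
own symmetry-function vector carries essentially no information about how
O2 is tilted (distant-atom terms are exponentially suppressed at η = 1), so
locality of β is both the physically sensible choice and what makes the
data learnable by the per-atom architecture.

**What the generator does not emulate**: real ESP charge surfaces (its
charge law is a smooth two-coordinate family, not quantum chemistry),
trajectory autocorrelation (frames are i.i.d.), ring-deformation charge
response beyond jitter, and conformations outside the sampled coordinate
box. Passing tests therefore demonstrate that the pipeline recovers a
smooth conformation- and spin-dependent charge law at realistic noise — not
that it reproduces any particular quantum-chemical dataset.

## Study sizes and numerical checks

The package's standard simulation study uses 4000 frames (2000 training
after the half split), at which the held-out per-spin average MAE is below
0.02 e and every per-(atom, spin) Pearson r exceeds 0.96; the worked
example in the README uses 600 frames for a quick desk run. Parameter
recovery is checked on noise-free data — both the charge noise and the
geometric jitter of the generator switched off, leaving the deterministic
two-coordinate family — where 2000 frames train to a held-out MAE of at
most 0.01 e for every atom and spin. With jitter on, a per-atom bound that
tight is not meaningful: the binding coordinate reaches each atom's
descriptor only through jittered interatomic distances (σ ≈ 0.07 Å for an
atom pair), which puts an estimator-independent floor of several
hundredths of an e under the large-coupling atoms, Fe above all.

Evaluation metrics are MAE, RMSE, the standard deviation of signed errors
(sample convention n−1 by default; the population form is available via
`error_std_denom`), and Pearson r. A zero-variance input makes the
correlation undefined: `charge_metrics()` errors loudly rather than
returning a sentinel, and `evaluate_model()` marks such cells `degenerate`
with `pearson = NA`. Spin-difference histograms use bins centered on
multiples of the bin width (default 0.02 e) so a difference concentrated at
0.1 e falls inside one bin rather than on an edge.

## Interface conventions

Charge tables and all user-visible outputs index atoms 0-based, matching
the fixed label table `heme_atom_table()` (Fe = 0 … O13 = 13); function
arguments that address atoms *positionally* inside a structure are 1-based,
as is natural in R. Angles and dihedrals are degrees at every interface.
The CLI is a thin dispatcher over the exported functions: YAML config files
supply defaults, flags override, the merged effective config is echoed next
to the outputs, and exit codes separate config, data and I/O failures.

## Known limitations

- The model is specific to one composition per training run; predicting a
  structure with a different element multiset is a layout error, not a
  warning.
- Only one symmetry function per component is supported (no η/R_s grids) —
  matching the 19-component setting; richer multi-parameter sets would
  need a layout extension.
- No out-of-bag error machinery and no significance testing of metric
  differences; reports are descriptive.
- The tree-spread uncertainty σ is an ensemble-disagreement measure, not a
  calibrated predictive interval.
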