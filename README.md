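# fatenet

Attractor dynamics of transcription-factor–enhancer networks for cell
identity.

Cell types are remarkably stable, yet cells also differentiate through
progenitor hierarchies and can be reprogrammed directly by overexpressing
a handful of transcription factors (TFs). `fatenet` implements a
mechanistic model in which all three behaviours emerge from one
ingredient: enhancers compete for limiting transcriptional machinery,
with TF binding setting each enhancer's chromatin state and hence its
competitiveness. The package is for computational and systems biologists
who want to simulate identity dynamics, predict progenitor hierarchies
and reprogramming recipes directly from terminal cell-type expression
profiles, or study the analytic theory of such attractor networks.

## The model

A network is the tuple (Ξ, Q, w, β, τ): an E×T binding matrix Ξ (enhancer
types × identity TFs), a coupling matrix Q (production rates; Q = νΞ in
the autoregulatory case), baseline log-activities w (signalling), an
effective inverse temperature β (sharpness of the chromatin-mediated
competition) and a turnover timescale τ. With enhancer activities
p(x) = softmax(βΞx + w), expression follows

    τ dx/dt = Qᵀ p(x) − x,

a gradient flow (for Q = νΞ) of the log-sum-exp potential
V(x) = ‖x‖²/2 − (ν/β) log Σᵢ exp(β ξᵢ·x + wᵢ) — the energy of a modern
Hopfield associative memory. At high β every row of Q is an attractor
(one per observed cell type); at low β only their global average survives
(a multipotent progenitor with low-level multilineage priming); at
intermediate β, averages of similar pattern subsets are metastable
progenitors. Annealing β from low to high reproduces Waddington-style
hierarchical commitment, and transient TF overexpression (an additive
production term δ/τ) reshapes basins to drive direct reprogramming.

The theory module provides closed forms — subset-average energies,
critical β for bipotent commitment and for leaving the global average,
and the specification gain χ = 2·ln2·η(1−η)·N / ln K quantifying how much
sharper competition must get to individuate newly evolved sister cell
types — each cross-validated in the tests against numerical oracles.

## Worked example

Annealing the bundled toy network (six enhancer types over nine TFs;
enhancer pairs share one TF, and EN5 carries a small signalling bias
w₅ = 0.05) from the EN1 identity:

```r
library(fatenet)

fx <- fixture_progenitor_toy()
fx$net
#> TF-enhancer attractor network (6 enhancer types, 9 TFs)
#>   beta = 20, tau = 1, symmetric: Q = nu * Xi (nu = 1)
#>   weights: 0.00 0.00 0.00 0.00 0.05 0.00

traj <- anneal(fx$net, fx$x0, fx$schedule)
detect_plateaus(traj, fx$net)
#>   t_start t_end                           label     distance
#> 1     7.0  51.0 average:EN1,EN2,EN3,EN4,EN5,EN6 0.0001076646
#> 2    98.5 211.5                 average:EN5,EN6 0.0195285553

assign_identity(fx$net, traj$states[nrow(traj$states), ])$label
#> [1] "EN5"
```

The cell first rests at the multipotent average of all six identities,
then at the restricted {EN5, EN6} progenitor selected by the signalling
bias, and finally commits to the induced fate EN5 — two progenitor
plateaus, then terminal commitment.

Scoring reprogramming factors for a target type ranks TFs that bind the
target's enhancer strongly and uniquely:

```r
rank_candidate_factors(fx$net, "EN3", max_factors = 2)
#>   factors    margin
#> 1     TF4 0.7071068
```

And the analytic specification gain at the sparse neuronal-code
parameterization (118 classes, 68 variable TFs, active fraction 0.1):

```r
specification_gain_chi(K = 118, N = 68, eta = 0.1)
#> [1] 1.778387
```

an ~80% increase in competition sharpness to stabilize newly evolved
sister classes.

A command-line entry point (`exec/fatenet`, a thin wrapper over
`fatenet_cli()`) exposes the same operations as subcommands
(`fixture`, `simulate`, `anneal`, `attractors`, `tree`, `reprogram`,
`theory`) writing CSV/JSON/Newick outputs with a run manifest.

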