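---
title: "Modelling cell identity through enhancer competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell identity through enhancer competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatenet)
```

## The model

`fatenet` implements a mechanistic model of cell-identity regulation in
which enhancers compete for limiting transcriptional machinery. A network
is parameterized by an $E \times T$ binding matrix $\Xi$ (affinity of each
enhancer type for each identity transcription factor), a coupling matrix
$Q$ of the same shape (the rate at which transcription initiated at an
enhancer produces each TF), a baseline log-activity vector $w$
(signalling input), and an effective inverse temperature $\beta$ that
summarizes how sharply chromatin-mediated competition discriminates
between enhancers. Writing $p(x) = \mathrm{softmax}(\beta \Xi x + w)$ for
the Boltzmann distribution of transcription-initiation probabilities at
expression state $x$, TF expression relaxes as

$$\tau \,\frac{dx}{dt} = Q^\top p(x) - x .$$

Autoregulation — identity TFs bind the enhancers that drive their own and
each other's expression — corresponds to $Q = \nu \Xi$. In that case the
Jacobian is symmetric (reciprocity of TF interactions), and the dynamics
are a gradient flow of

$$V(x) = \tfrac12 \lVert x \rVert^2 -
  \frac{\nu}{\beta} \log \sum_i e^{\beta \xi_i \cdot x + w_i},$$

a log-sum-exp potential of the kind used in modern Hopfield associative
memories. Its minima are the stable cell identities: at large $\beta$
these are the rows of $Q$ (the observed terminal cell types, when the
model is parameterized from data), while at small $\beta$ only their
global average survives — a multipotent state that co-expresses all
lineage programs at low level, as progenitors do. At intermediate
$\beta$, averages of similar subsets of patterns are metastable: these
are the restricted progenitors, and annealing $\beta$ from low to high
walks a cell down this hierarchy.

Two conventions deserve note. First, the weights $w$ enter the scores
*unscaled* by $\beta$, so a signalling bias persists at small $\beta$ and
can steer which branch an annealed cell commits to; the balanced-
differentiation feedback applies fixed additive decrements to $w$, which
only makes sense on a $\beta$-free scale. Second, at $\beta = 0$ the
log-sum-exp term degenerates; `potential()` returns the analytic limit
$\tfrac12\lVert x\rVert^2 - \nu\, p_0^\top \Xi x$ with
$p_0 = \mathrm{softmax}(w)$, whose gradient is exactly the $\beta = 0$
drift (an additive constant that diverges with $1/\beta$ and does not
depend on $x$ is dropped).

## Numerical choices

Deterministic trajectories use the adaptive `lsoda` integrator at
relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$;
stochastic paths use fixed-step Euler–Maruyama with $dt = 0.01\,\tau$,
per-component additive noise of amplitude $\sigma$, and clipping at zero
after each step (deterministic flow preserves nonnegativity on its own
because $dx/dt \ge -x/\tau$). Every stochastic entry point requires an
explicit seed. Fixed points are polished by damped Newton iteration on
the analytic Jacobian with projection onto the nonnegative orthant;
stability is classified from the Jacobian spectrum with a strict margin
(leading real part below $-10^{-8}$; anything within $10^{-8}$ of zero is
reported *marginal*, never silently stable). Attractor sets deduplicate
at Euclidean distance $10^{-3}$ but label states by cosine distance,
because identity is a TF *pattern*, not a magnitude. Candidate progenitor
subsets are singletons, pairs, the global average, and the nested
clusters of the patterns' cosine dendrogram — not all $2^E$ subsets,
since progenitors are only predicted for subsets of high internal
similarity.

Plateau detection during annealing uses the instantaneous speed
$\lVert dx/dt \rVert$: a progenitor visit is a maximal interval below
`speed_threshold` (default $10^{-3}\times$ the typical pattern norm per
$\tau$) lasting at least `min_dwell` (default $2\tau$), excluding the
terminal interval. The bundled demonstration network of six enhancers
over nine TFs (pairs of enhancers sharing one TF, with a small signalling
bias $w_5 = 0.05$) uses a *staged* schedule: a hold at $\beta = 0$ long
enough to erase the starting identity, a ramp, a pause inside the
stability window of the biased pair-average progenitor, and a final ramp.
Pausing near the transition is standard practice in simulated annealing;
under a continuous ramp the narrow progenitor window is crossed at a
tracking speed proportional to the ramp rate, which no fixed threshold
detects robustly. With the staged schedule the two progenitor plateaus
(global average, then the `{EN5, EN6}` average) are detected across a
hundredfold range of threshold and dwell settings.

## Parameterizing from data

`network_from_profiles()` turns a cell-type-by-TF expression table into a
model: each cell type's profile becomes one enhancer-type row, normalized
to unit Euclidean norm (the cosine-similarity algebra of the theory
assumes comparable overall binding affinities), with $Q = \Xi$, $w = 0$
and $\tau = 1$. Preprocessing follows common practice for averaged
atlases: $\log(1+x)$ transform, then keep TFs whose row mean *and* row
standard deviation exceed $\log 4$ (strict inequalities; population
standard deviation, configurable). The only remaining free parameter,
$\beta$, is calibrated by `calibrate_beta()` as the smallest grid value
at which every observed cell type is a stable attractor — the model
therefore has no fitted parameters in the usual sense.

## The analytic theory and its oracles

For ensembles of $K$ related patterns with mean within-family inner
product $A$ (and two-bit variants at inner product
$C = 1 - 1/(\eta N + N')$), the package provides closed forms that are
each cross-validated in the test suite against an independent numerical
oracle built only from `potential()`, `jacobian()` and the fixed-point
machinery:

* `averaged_pattern_energy()` — the two-level energy of a subset average;
  exact on constant-similarity families built from shared and private
  blocks, where every assumption of the formula holds identically.
* `critical_beta_global()` — the energy crossing
  $\beta_1 = 2\ln K / ((1-A)(1-1/K))$ at which individual patterns drop
  below the global average; numerical potential crossings on explicit
  families agree within a few percent.
* `critical_beta_bipotent()` — two thresholds for a bipotent pair. The
  *commitment* form $4\ln 2/(1-A)$ is the asymptotic energy crossing used
  by the specification-gain ratio; the exact crossing solves
  $u = 4\ln(2/(1+e^{-u}))$ with $u = \beta(1-A)$, about 12% below the
  asymptote (the tests pin both facts). The *destabilization* form
  $2/(1-A)$ is the local pitchfork at which the pair average loses
  stability; it matches the endpoint of the numerical stability interval
  from `bifurcation_scan_beta()` to within 5%.
* `specification_gain_chi()` — the ratio
  $\chi = 2\ln 2\,\eta(1-\eta)N/\ln K$ of the variant-pair commitment
  temperature to the global-average crossing. It depends only on the
  variable TFs and scales with the variance $\eta(1-\eta)$ of the active
  code; it is invariant to the number of always-active TFs. At the sparse
  neuronal-code parameterization ($K = 118$, $N = 68$, $\eta = 0.1$) it
  evaluates to $\chi \approx 1.78$ — an $\approx 80\%$ further sharpening
  of enhancer competition to individuate newly evolved sister classes.

### Why the operational two-threshold ratio is smaller

`two_threshold_scan()` measures, on a sampled family, the smallest
$\beta$ at which the multipotent average stops being a stable fixed point
and the smallest $\beta$ at which every class is a distinct stable
attractor. One might expect their ratio to reproduce $\chi$; it does not,
and the package reports what it measures. The reason is multistability:
individual patterns become attractors while the near-average state is
still locally stable (fluctuation-driven loss of the average occurs near
$\beta \approx 19$ on this ensemble, whereas all 118 classes are already
distinct attractors near $\beta \approx 10$), so the operational ratio
lands near $0.5$ rather than near $2$. The analytic $\chi$ compares
*energy crossings* — the temperatures at which the landscape's global
preference shifts — which govern the quasi-static annealing hierarchy but
not the boundaries of local stability. The energy-crossing ratio measured
directly from `potential()` on explicit families does agree with $\chi$
(tested), so the discrepancy is a real property of the dynamics, not an
implementation artifact: progenitors and terminal identities genuinely
coexist over a wide band of $\beta$, which is also what makes transient
annealing (rather than a static $\beta$) necessary for differentiation.

## Shadow enhancers and new cell types

The evolution fixture (`fixture_sister_evolution()`) uses *physical* enhancer copies
with $Q \neq \Xi$: each copy drives only its genomically adjacent TF,
while binding is shared across copies — so the full copy-level dynamics,
and their exact reduction to enhancer types (`reduce_to_types()`), are
both exercised. An ancestral type expressing TF1–TF4 owns copies adjacent
to each TF plus shadow copies near TF1 and TF2. Variant enhancers that
lost one TF's site bind their distinguishing TF at full site affinity and
the shared TFs at half; rows are unit-normalized. This concentration is
load-bearing: with equal per-site affinities the ancestral state's
TF3$\leftrightarrow$TF4 symmetric mode undergoes a *supercritical*
pitchfork, so sister states would be born exactly where the ancestral
state destabilizes and the coexistence stage could not exist. With
concentrated variant binding and shadows diversified one-to-each-variant,
the sister attractors appear by saddle-node well inside the ancestral
state's stability range, giving the three-attractor stage; a further
mutation of the remaining ancestral-binding copies leaves the ancestral
state as a symmetry-protected saddle and only the sisters survive. In the
coexistence regime the ancestral attractor's TF3/TF4 activity is strongly
reduced (near zero at the fixture's default sharpness). Background cell
types on disjoint TFs remain attractors throughout all stages. Because a
uniform magnitude factor $s$ on $\Xi$ and $Q$ acts exactly like
$\beta \mapsto s^2\beta$, and the stage properties hold from roughly a
quarter of the default $\beta$ upward, all counts are robust to at least
a $\pm 50\%$ magnitude rescaling at fixed $\beta$.

## Synthetic data: what it emulates, and what it does not

The generators produce (i) cell-type-by-TF count matrices with sparse
private identity blocks, low off-target expression, flat housekeeping
rows and lognormal multiplicative noise; (ii) nested-block terminal
profiles whose cosine structure encodes a known eight-lineage hierarchy;
and (iii) sparse binary pattern families with a prescribed number of
active TFs per class. They emulate the *similarity structure* of averaged
expression atlases — which is all the model consumes — but not read-count
statistics, dropout, batch effects, or correlated gene programs. Tests
passing on these fixtures therefore validate the dynamical and
statistical machinery, not robustness to the technical noise of real
single-cell data.

Study-condition defaults follow the methods they emulate: annealing from
$\beta = 0$ to $\beta = 50$ over 50 time units with additive noise
$\sigma = 0.01$ for differentiation runs; balanced differentiation resets
$w$ to zero and, after a run commits to lineage $i$, applies
$w_i \leftarrow w_i - 0.5\,(1 - k/k_{\max})$ and re-centres $w$;
reprogramming forces $\delta = 1$ per factor for $20\tau$ with $20\tau$
of relaxation, entering as additive production $\delta/\tau$ rather than
clamping, so the attractor coordinates themselves are never edited. The
test suite uses modest problem sizes (networks of up to ten patterns,
300 balanced-differentiation runs, 68-dimensional ensembles at $K = 118$)
chosen so the full suite completes in a few minutes while keeping every
statistical check at its stated power.

## The chromatin barrier extension

`barrier_params()` adds a slow repressive modification $u_i$ per enhancer
with autocatalytic Hill production gated by a decreasing function of
enhancer activity, basal production, linear degradation, and an energy
penalty $-\lambda u_i$ on the enhancer's weight. While an enhancer stays
active the low branch is stable; once activity falls below `p_crit` the
low branch vanishes and $u_i$ jumps to a high branch, locking the
enhancer out — a barrier against reprogramming into disused identities.
The published account fixes only this qualitative contract, not a
functional form; the implemented closure (production multiplied by the
activity-dependent drive, defaults chosen by a root scan of the
production–degradation balance) is documented in `?barrier_params` and
tested for the low branch, the jump, and sweep hysteresis in the bistable
regime.

## Known limitations

* The operational two-threshold ratio deliberately follows its stated
  definitions and therefore does not reproduce the analytic $\chi$ (see
  above); both quantities are exposed.
* Attractor enumeration is restart-based; it carries no global
  completeness guarantee in high dimension beyond the dense-restart
  cross-checks in the tests.
* The commitment-type bipotent threshold is an asymptotic form with a
  known, constant 12% offset from the exact two-pattern energy crossing.
* Adapters for real expression atlases are limited to plain CSV/TSV
  tables of averaged profiles; no single-cell container formats.
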