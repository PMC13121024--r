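---
title: "Integrated information, control energy and mean-field modelling with phidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information, control energy and mean-field modelling with phidyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phidyn)
```

## What this package computes

`phidyn` quantifies how much information a two-part dynamical system carries
*as a whole, beyond its parts*, and connects that quantity to two mechanistic
frameworks: linear network control on a structural connectome, and a
biophysical mean-field simulator with regionally heterogeneous inhibition.
Everything runs on plain numeric matrices (time-by-regions timeseries,
square weighted adjacencies, per-region scalar maps), so the full pipeline is
testable on synthetic data generated by the package itself.

## The information decomposition

For two (possibly multivariate) parts $X$ and $Y$ of a stationary process,
the time-delayed mutual information
$I(X_{t-\tau}, Y_{t-\tau};\, X_t, Y_t)$ measures all information flowing
from the system's past to its future. Partial information decomposition
splits the information two sources carry about a target into redundant,
unique and synergistic components; applying it jointly to past sources and
future targets splits the TDMI into $4 \times 4 = 16$ atoms, one per pair of
lattice nodes $\{\mathrm{Red}, \mathrm{Un}X, \mathrm{Un}Y, \mathrm{Syn}\}$
in the past and future.

We work in the Gaussian regime, where all the required mutual informations
are log-determinant ratios of covariance sub-blocks and the
minimum-mutual-information (MMI) redundancy rule applies. The value of the
double-redundancy function at a product-lattice node pair is the minimum MI
between every constituent source collection of the past node and every
constituent collection of the future node; at the bottom node this is the
familiar
$\min\{I(X_p;X_f), I(X_p;Y_f), I(Y_p;X_f), I(Y_p;Y_f)\}$,
and at the top node it is the TDMI itself. The 16 atoms are recovered by
Möbius inversion over the product partial order (a fixed triangular
16-by-16 system). Atoms may legitimately be negative — the MMI double
redundancy is monotonic but not totally monotonic on the product lattice —
and are never clipped.

Derived measures (all in nats):

* $\Phi_R$: the nine atoms that involve synergy plus the two pure-transfer
  atoms. Equivalently, whole-minus-sum information with the persistent
  redundancy added back.
* $\Phi_{2008} = \Phi_R - \mathrm{Red}\!\to\!\mathrm{Red}$: the original
  whole-minus-sum measure, which double-counts persistent redundancy and can
  go negative in redundancy-dominated systems.
* Transfer entropy
  $TE_{X\to Y} = \mathrm{Syn}\!\to\!\mathrm{Red} + \mathrm{Syn}\!\to\!\mathrm{Un}Y
  + \mathrm{Un}X\!\to\!\mathrm{Red} + \mathrm{Un}X\!\to\!\mathrm{Un}Y$, and
  causal density $= TE_{X\to Y} + TE_{Y\to X}$.
* Net information flow
  $= |\mathrm{Un}X\!\to\!\mathrm{Un}Y - \mathrm{Un}Y\!\to\!\mathrm{Un}X|$:
  the absolute pure-transfer imbalance, zero when the two directions are in
  balance. The sentence defining this measure admits two readings (sum of
  absolute differences per pair, or absolute difference of sums); we take
  the per-pair absolute imbalance, which realizes "zero when the two terms
  are equal" exactly and is averaged over pairs like every other measure.

Identities that the test suite verifies against independent computations:
the atoms sum to the TDMI; $I(X_p;X_f)$ equals the sum of its four
constituent atoms; transfer entropy from atoms equals the conditional MI
$I(X_p; Y_f \mid Y_p)$ computed directly from the covariance; and under MMI
one of the two parts always has zero unique information about any given
target.

### The two-node testbed

```{r twonode}
m <- lagged_model_from_cov(var_lagged_cov(two_node_ar(0.2, 0.8, self = 0.4)),
                           dims = c(1, 1))
unlist(info_measures(phiid_atoms(m)))[c("phi_R", "phi_2008", "double_redundancy")]
```

The canonical testbed is a two-node vector autoregression with symmetric
cross-coupling $a$, innovation correlation $c$ and (optionally)
self-coupling $s$. Its lagged covariance is available in closed form through
the discrete Lyapunov equation, so every information measure can be checked
against analytic values. Two properties of this family matter for
interpretation and are easy to miss:

* With $s = 0$ and $a = 0$ the process has *no temporal structure at all*:
  every measure is exactly zero no matter how large $c$ is. Moreover, for
  $s > 0$ but $a = 0$ the joint lagged correlation factorizes as a Kronecker
  product and $\Phi_{2008}$ is *exactly* zero. Redundancy domination with
  $\Phi_{2008} < 0$ requires both intrinsic memory ($s > 0$) and common
  noise ($c > 0$) together with coupling. Our canonical grid therefore uses
  $s = 0.3$ alongside $a \in [0, 0.45]$ and $c \in [0, 0.9]$; in its high-$c$
  cells $\Phi_{2008}$ is negative while $\Phi_R$ stays nonnegative
  everywhere, and $\Phi_R$ increases monotonically with $a$ at $c = 0$.

### Estimation choices

Each region is z-scored before covariance estimation (all MI quantities are
scale invariant; this also makes the stationarity check on past/future
blocks meaningful). Joint covariances receive a relative diagonal loading of
$10^{-9}$ only when the smallest eigenvalue falls below $10^{-10}$. The lag
defaults to one sample — the minimal nontrivial choice for slow,
TR-sampled signals — and is configurable everywhere. Measures are averaged
over *unordered* region pairs; this is immaterial for the symmetric
$\Phi_R$ and makes directed quantities (the two transfer entropies) appear
as separate columns rather than an ordered-pair average. Beyond pairs, a
bipartition estimator samples sets of $K$ regions (default 6) split into
even halves, which raises sensitivity to distributed integration at
manageable cost. Estimation bias is removed, when requested, by subtracting
the mean measure over surrogates that jointly permute timepoints across all
regions — the unique construction that preserves each region's marginal
distribution and the zero-lag covariance exactly while destroying all lagged
structure. Alternatives such as circular shifts preserve autocorrelation and
would not serve as a zero-information reference.

## Network control energy

Brain-state transitions are modelled by the linear system
$\dot{x} = A x + B u$ with $A = C/(\lambda_{\max}(C)+1) - I$ built from the
connectome $C$ (all eigenvalues in $[-2, 0)$; the stabilization convention
is not dictated by the scientific question, so it follows the standard
network-control literature and is configurable). The minimum-energy input
driving $x_0$ to $x_f$ over horizon $T = 1$ costs
$E = v^\top W_T^{-1} v$ with $v = x_f - e^{AT}x_0$ and the controllability
Gramian $W_T = \int_0^T e^{At} B B^\top e^{A^\top t}\,dt$, computed exactly
via an augmented-matrix exponential. Per-node energies integrate
$\|u_i^*(t)\|^2$ by Simpson quadrature and sum to the total within $10^{-6}$
relative. Timeseries are z-scored per region and consecutive frames are
treated as transition pairs.

Regionally heterogeneous inhibition enters as $B = I - \mathrm{diag}(m)$
for a map $m \in [0,1]^N$, with diagonal entries clipped below at
$10^{-3}$ to keep the Gramian invertible. Reducing any control weight can
never reduce the energy (a Loewner-order fact the tests verify numerically),
so map-weighted control always costs at least as much as uniform control.

When a map is compared against spatial-autocorrelation-preserving null maps,
the raw map and every surrogate pass through one identical sigmoid
normalization before becoming control weights. We found that the obvious
alternative — clipping surrogate values into $[0,1]$ — silently sends some
null control weights to the clipping floor and inflates null energies by
orders of magnitude, an artifact of the surrogate family's value extremes
rather than of spatial placement. Even with matched normalization, a
caveat applies that our own analysis makes precise: in this linear pipeline
the mean transition energy of a map is governed far more by the *depth* of
its deepest control deficit than by *where* the deficits sit (regressing
null energies on null statistics, the minimum control weight dominates
while alignment with node strength contributes almost nothing), and
per-node energy sensitivity is strongly *anti*-correlated with node
strength — weakly connected regions are the expensive ones to lose, since
the network cannot reach them indirectly. Synthetic planted-map experiments
at desk scale (tens of regions) therefore rarely clear a 95th-percentile
null threshold, whatever the planted direction; detecting placement-specific
energy effects appears to require the richer structure of empirical
connectomes and genuinely smooth expression maps.

## The mean-field simulator

Each region is a reduced excitatory–inhibitory neural-mass pair: synaptic
gating variables $S_E, S_I$ with sigmoidal rate functions, NMDA coupling
$G \cdot C$ between regions, an external excitatory current scaled per
region by `exc_input_scale` (baseline 1; "stimulation" of a node set raises
it, by default to 3, with 1.5 and 2 as alternatives), and a per-region
inhibitory weight $J_i$ with baseline 0.7. Heterogeneous inhibition raises
$J_i = 0.7\,(1 + m_i)$ for a normalized map $m$, spanning 0.7 to 1.4
(doubled inhibition). The constants are the canonical reduced Wong–Wang
values with an override slot; $J$ is a free parameter manipulated directly
(no automatic inhibition tuning), since the scientific use case is exactly
that manipulation. Integration is Euler–Maruyama at 0.1 ms by default; the
heavier batteries in the test suite run at 0.2 ms, where the integration is
equally stable and trajectories are statistically indistinguishable at the
summary level. The haemodynamic observation model is a standard
Balloon–Windkessel transform; we drive it with the excitatory gating
$S_E \in [0,1]$, which keeps the haemodynamic state equations in their
well-behaved regime, and sample the resulting BOLD-like signal at the TR
(default 2 s) after discarding a 10 s transient. Noise comes from an
internal 64-bit Mersenne twister seeded from the parameter set, so
simulations are bit-reproducible per seed and independent of R's RNG
stream.

Global coupling is fitted by matching functional connectivity dynamics
(FCD): sliding-window FC patterns (default window 30 samples, step 3;
typical sliding-window practice) compared between windows by correlating
their vectorized upper triangles; the fit minimizes the Kolmogorov–Smirnov
statistic between the pooled simulated FCD value distribution and the
target's, with ties broken toward smaller $G$. An important honest caveat,
established by the package's own self-consistency experiments: with $J$
held at its 0.7 baseline (no feedback-inhibition tuning — the configuration
in which $J$ is a directly manipulated parameter), this reduced model has
no dynamical transition over $G$; firing rates and static FC rise smoothly
while the FCD distribution shifts by less than the Kolmogorov–Smirnov
noise floor attainable with a few 6–10-minute runs. At desk scale the KS
profile over a $G$ grid is therefore dominated by seed noise and the
generating $G$ is not reliably recovered. Reliable FCD-based fitting
appears to require the near-critical multistable regime of feedback-tuned
working points and substantially longer simulations. Downstream
experiments (inhibition and stimulation batteries) therefore take their
working point as an explicit argument rather than inheriting a fitted
value.

The condition battery runs matched-seed simulation sets per condition —
homogeneous vs map-weighted vs null-map-weighted inhibition, or no-stim vs
stimulation of chosen node sets — and summarizes each run by its mean
pairwise $\Phi_R$. Matched seeds across conditions turn the comparisons
into paired contrasts and remove most of the between-run noise.
Map-weighted inhibition reliably lowers integration relative to both the
homogeneous model and spatial-surrogate maps. Nodal stimulation effects
are subtler: on synthetic modular connectomes the difference between
stimulating the strongest versus the weakest node is only a few per cent
of $\Phi_R$, and its sign depends on whether the strongest node happens to
be a cross-module integrator or merely a within-module hub — stimulation
of a within-module hub can inject shared drive (redundancy) into its own
community without raising global integration. Robust hub-stimulation
recovery appears to require genuinely thalamus-like broad connectivity
profiles, which generic modular graphs only sometimes produce; treat the
stimulation battery's direction on any single synthetic connectome with
corresponding caution.

## Statistics

General dominance analysis decomposes a regression $R^2$ into per-predictor
importances by averaging each predictor's incremental $R^2$ over all
subsets of the others, first within subset sizes and then across sizes;
importances sum exactly to the full-model $R^2$ and are checked against an
independent all-subsets oracle. The overall fit is reported both raw and
adjusted; importances are computed on raw $R^2$, where the increments are
defined. The model-level test permutes the target (arousal scores) with
predictors fixed: $p = (1 + \#\{R^2_{perm} \ge R^2_{emp}\})/(n_{perm}+1)$.

Spatial correlations between regional maps use Spearman's rho against
Moran-spectral-randomization nulls: the map is projected onto the
eigenvectors of the doubly centred spatial weight matrix (default inverse
Euclidean distance, zero diagonal, row-normalized; symmetrized internally
for the eigenbasis), coefficient signs are randomized and coefficients are
permuted within blocks of eigenvalues equal to within a relative tolerance
of 0.05, and the mean is restored exactly. Two-sided p-values compare
absolute correlations, since associations of either sign are of interest.
Cross-species gene ranking ranks genes by signed correlation within each
species, averages ranks across species, z-scores the averaged ranks and
scores genes by the magnitude, so consistent extremes of either sign rank
highest; the alternative order of operations (z-scoring within species
before averaging) is available behind a flag because the verbal definition
is ambiguous.

## The synthetic-data generator

The generator exists so the full pipeline has inputs with known ground
truth; it emulates the *statistical* skeleton of a multi-subject,
multi-condition anaesthesia study, not the biology. A study consists of a
modular weighted connectome (log-normal-like weights, heavier within
modules; no isolated nodes), uniform random 3-D coordinates, a smooth truth
map (Gaussian random field, sigmoid-normalized), and per subject-condition
VAR(1) timeseries on the connectome. Conditions differ by a global coupling
scale (1.0 awake-like, 0.4 anaesthesia-like — a strong but subtotal
reduction), an innovation equicorrelation (0.1 by default), and an
inhibition weight that attenuates each region's incoming coupling in
proportion to the truth map.

Two sources of run-level variability make the emulation statistically
honest rather than a two-point contrast. First, each subject-condition's
effective coupling scale receives Gaussian jitter (sd 0.08, clamped to
$(0.05, 1]$): biological variability that turns the arousal link into a
graded one. Arousal scores follow
$\mathrm{round}(11\,g_{\mathrm{eff}}) + \{-1,0,1\}$ clipped to $[0,11]$ —
a deliberately simple monotone link sufficient to exercise dominance
analysis; without within-condition gradation all candidate measures
separate the two conditions equally and relative-importance analysis is
ill-posed. Second, every run receives a shared slow drift — a global AR(1)
component (coefficient 0.8) added to all regions with amplitude
$|N(0, 0.8)|$ drawn per run — emulating global physiological artifact
whose strength varies across runs independently of arousal. The drift
selectively inflates persistent redundancy (it is the same signal in every
region at every lag), which decouples the whole-minus-sum measure from the
revised one exactly as observed empirically in this literature, while
leaving synergy- and transfer-based quantities nearly untouched. The
equicorrelation level also jitters across runs (sd 0.15, clamped to
$[0, 0.8]$). VAR burn-in is 100 steps, at least ten autocorrelation times
for every default system. All generators are pure functions of their
parameters and seed, and leave the caller's RNG state untouched.

Null networks: lattice and fully random topologies are generated directly;
degree-preserving nulls use Maslov–Sneppen double-edge swaps with weights
riding along (weight multiset preserved exactly); strength-preserving nulls
additionally refit weights on the rewired topology by iterative
proportional fitting until node strengths match within $10^{-6}$ relative.
These two goals — preserving the exact weight multiset and the exact
strength sequence — cannot hold simultaneously on a rewired topology, so
the strength-preserving variant trades multiset exactness for strength
exactness; the degree-preserving variant makes the opposite trade.

What passing tests on these synthetics do *not* show: haemodynamic
realism of the VAR channel (the mean-field module owns biophysics),
empirical-atlas geometry, scanner noise structure, or subject-level
heterogeneity beyond seed variation. Directional conclusions (anaesthesia-like
coupling reduction lowers $\Phi_R$ and raises transition energy, with the
two anti-correlated across runs) are statements about the generator's
planted structure being recoverable, not about any particular dataset.

## Problem sizes and numerical conventions

The shipped test suite and acceptance analyses use 2–6-dimensional parts
for lattice identities (residual tolerances $10^{-9}$), 20–30-node
connectomes for control and study analyses, 25-node mean-field batteries
with 2–6-minute simulated runs at 0.2 ms steps, and 10-replicate null
experiments with 99 surrogates. These sizes were chosen as the smallest at
which every qualitative effect is stable across seeds; all of them are
arguments, not constants. Degenerate inputs follow explicit conventions:
constant maps cannot be sigmoid- or rank-normalized (rejected), constant
FCD windows are skipped with a log message, failed region pairs are
excluded from pairwise means with a reported count, and ill-conditioned
Gramians (condition number beyond $10^{12}$) are rejected rather than
silently pseudo-inverted.

## Known limitations

Pairwise (and sampled-bipartition) estimation bounds integrated information
from below; no higher-order lattice is implemented. The MMI rule is the
only redundancy function offered. The mean-field model is homogeneous in
its neural constants across regions apart from $J$ and the input scaling,
and no feedback-inhibition auto-tuning is performed. Spatial surrogates
assume a meaningful embedding; with arbitrary coordinates their
autocorrelation constraint is weak. And as discussed above, placement-specific
control-energy effects are intrinsically hard to detect against
value-distribution jitter at desk scale.
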