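---
title: "Markov state model analysis of ligand-binding trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state model analysis of ligand-binding trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandMSM)
```

# The problem

Ligand binding to a G-protein-coupled receptor is a rare event on molecular
dynamics timescales. The standard strategy is to run many short, adaptively
restarted simulations, project them onto a handful of biologically meaningful
features (ligand-binding distances, side-chain dihedrals, helix-helix
distances), discretize the feature space, and estimate a Markov state model
(MSM) whose stationary distribution recovers unbiased thermodynamics from the
biased sampling. Kinetics between macrostates then come from transition path
theory (TPT), long synthetic trajectories from kinetic Monte Carlo (kMC), and
uncertainties from a trajectory bootstrap. Two ligand-bound ensembles (for
example a full agonist versus a partial agonist in the agonist pose) are
compared by PCA, per-feature symmetrized Kullback-Leibler divergence, and a
mutual-information network over residue dihedrals whose shortest paths trace
allosteric communication.

ligandMSM implements this entire analysis chain, together with a synthetic
trajectory generator with a known hidden-state ground truth, so that every
stage is testable end-to-end without any MD data.

# The model chain

## Markov state model

Transitions are counted at a lag of $\tau$ frames, either at every origin
(sliding) or at strides of $\tau$. The transition matrix is the plain
row-normalized maximum-likelihood estimator
$T_{ij} = C_{ij} / \sum_j C_{ij}$, restricted to the largest strongly
connected component of the count graph (the active set). We deliberately use
the non-reversible estimator as the default because it is the estimator
defined by the row-normalization equation itself; a reversible variant
(count symmetrization, which enforces detailed balance) is available behind
`estimateMSM(..., reversible = TRUE)`. The stationary distribution $\pi$ is
the leading left eigenvector, and state free energies are
$G_i = -k_B T \ln \pi_i$ with $k_B = 0.0019872$ kcal/mol/K and a 300 K
default temperature, shifted so the minimum is zero (figures report
differences, so the shift is convention only).

Lag selection uses implied timescales $t_i = -\tau / \ln \lambda_i$: the lag
is adequate once the timescale curves are flat in $\tau$. Eigenvalues that
are complex or non-positive have no real relaxation time and are reported as
`NA`; eigenvalues at 1 beyond the stationary process report `Inf` rather
than a large number.

## Landscapes and conditional probabilities

MSM-weighted landscapes weight each frame by
$w = \pi_{s(\text{frame})} / n_{s(\text{frame})}$, the state's equilibrium
probability spread evenly over that state's observed frames; frames in
states outside the active set get zero weight. Weights are histogrammed over
one or two observables and converted by
$G_{\mathrm{bin}} = -k_B T \ln (w_{\mathrm{bin}} / \max w_{\mathrm{bin}})$,
with empty bins masked rather than carried as infinities. Conditional
probabilities are ratios of the same weights,
$P(\text{outcome} \mid \text{condition}) = W(\text{condition} \wedge
\text{outcome}) / W(\text{condition})$, with a zero-weight condition treated
as an error, not as 0/0.

## TICA, k-means, VAMP2

TICA solves the generalized eigenproblem of the symmetrized lagged
covariance against the instantaneous covariance after mean removal. Two
numerical choices matter. First, the lagged covariance is symmetrized
(averaged with its transpose) so the spectrum is real on finite data.
Second, the instantaneous covariance receives a diagonal ridge of
$10^{-8} \cdot \mathrm{tr}(C_0)/F$, so constant or collinear features are
regularized out with a warning instead of producing NaNs. Components are
orthonormal under the instantaneous covariance; the retained count is the
smallest achieving the requested fraction of total kinetic variance (sum of
squared eigenvalues).

Discretization is Lloyd k-means from k-means++ seeding, with 10 seeded
restarts by default, keeping the best inertia. For multi-million-frame
inputs the centers are fitted on a seeded random subsample (`fitCap`,
default 200k frames) and every frame is then assigned to its nearest center;
the nearest-center invariant is enforced explicitly after fitting.

The VAMP2 score of a discretization is the sum of the top squared singular
values of the half-weighted propagator estimated from the discrete jump
process; the stationary process contributes exactly 1. For hyperparameter
selection we cross-validate by trajectory: singular functions are estimated
on training folds and scored on held-out folds (with a small ridge against
singular-function directions unsupported in the test fold, and singular
values clipped at their theoretical bound of 1). On well-separated synthetic
states the held-out score *saturates* above the true state count rather than
decaying, so the recommended selection rule is parsimony: the smallest
cluster count whose mean cross-validated score is within 5% of the grid
best. This rejects under-resolved discretizations decisively and avoids
reading noise as a preference among saturated models.

## Transition path theory

Macrostates are defined the way practitioners read landscapes: among the
model states whose centers fall in a region of interest, take the `nTop = 5`
with the highest raw frame count (ties to the lower index; fewer than
requested is allowed with a warning). The forward committor solves
$q^+_i = \sum_j T_{ij} q^+_j$ with $q^+ = 0$ on the source and 1 on the
sink; unreachable sinks are reported as errors naming the offending states.
The backward committor is the forward committor of the time-reversed chain
$\tilde T_{ij} = \pi_j T_{ji} / \pi_i$ (the time-reversal definition is our
choice; only the forward object is forced by the formulas). The reactive
flux is $F_{AB} = \sum_{i \in A} \sum_{j \notin A} \pi_i T_{ij} q^+_j$ and
the mean first-passage time is reported as
$\mathrm{MFPT} = \tau \, \pi_A / F_{AB}$.

A caution we document rather than hide: other TPT conventions normalize the
rate by $\sum_i \pi_i q^-_i$ instead of $\pi_A$. The two agree exactly when
source and sink partition the state space (hence for all two-state systems)
and agree to within a few percent whenever intermediate states carry little
stationary population — the metastable regime MSMs are built for. Our
simulation checks therefore use metastable two-basin chains with
fast-draining transit states (`randomErgodicChain`); with heavily populated
intermediates the $\pi_A$ convention answers a different question (time
spent in the source per reactive event) and would not match naive
first-passage simulations.

## Kinetic Monte Carlo

kMC uses the cumulative-row rule: draw $R \sim U[0, 1)$ and jump to the
state whose cumulative transition probability interval contains $R$; each
step advances one lag time. Trajectories can be rendered as frame sequences
by drawing, uniformly at random, one frame from the visited state's pool at
each step — uniform, not density-weighted, matching the practice of picking
a random representative frame.

## Ensemble comparison

Symmetrized K-L divergence is the *sum* of the two directed divergences over
shared histogram bins (30 by default) spanning the common sample range, with
a $10^{-10}$ pseudocount per bin; identical samples give exactly zero and a
degenerate range is defined as zero. The sum convention (rather than the
mean) is stated here because "symmetrized" alone does not pin it down.
Per-residue scores are means over the features involving each residue.

Normalized mutual information between residue dihedrals uses 24 angular bins
per axis on $[-180°, 180°)$, MI in nats, normalized by the smaller marginal
entropy and clipped to $[0, 1]$; a constant series is defined to have zero
normalized MI. Because finite samples never give exactly zero MI, the
"nonzero MI" edge gate is made operational as a per-pair permutation null:
the default threshold is the 97.5th percentile of 20 shuffles. Edges also
require spatial contact (distance below 6 Å). Edge path-cost is
$-\ln(\mathrm{nMI})$, clipped at 20, so the Dijkstra shortest path is the
route of highest information flow; the cost choice is ours, as a weighted
graph alone does not define one.

## Bootstrap

Uncertainty comes from resampling trajectories: each of 200 rounds draws 80%
of the trajectories (with replacement by default; a without-replacement
subsample mode exists because the protocol wording "randomly picked N
trajectories" admits both), keeps the original state labels fixed,
re-estimates the MSM, and re-evaluates the statistic. Rounds that break a
statistic's preconditions (a lost macrostate state, a zero-weight condition)
are counted as failures and skipped, never imputed. Per-trajectory count
matrices are precomputed once so each round is a cheap matrix sum. Spread is
reported as the standard deviation over successful rounds, and is labelled
as such.

# The synthetic generator

`buildGroundTruthChain()` defines hidden metastable chains with
diagonal-covariance Gaussian emissions per state — the simplest emission
model that makes TICA/k-means/MSM recovery a real inference problem while
keeping every downstream quantity analytically known. All randomness flows
from one integer seed through a documented Lehmer-style splitting scheme
(`deriveSeed`); there is no hidden global RNG state.

The `binding_landscape` preset encodes the qualitative physics of partial
agonist binding in six states — unbound, entry, two antagonist-like poses
distinguished by the alkyl-chain orientation, and two agonist-like poses
distinguished by the chain-dihedral sign — over four features: binding
distance (Å), chain dihedral (deg), a toggle-switch $\chi_2$-like angle
(deg) and a TM3–TM6-like distance (Å). Binding distances run from 25 Å
(unbound) through 19/15 Å (antagonist-like poses) to 10 Å (agonist-like);
the toggle angle rotates from 90° to 0° and the TM3–TM6 distance opens from
8 to 10.5 Å only in the agonist-like poses. The topology forces the
pathway unbound → entry → antagonist poses → agonist poses, with no direct
unbound-to-agonist edge. Basin means are separated by at least ~8 emission
standard deviations on some feature so that discretization error is
negligible against the recovery tolerances; the exact numbers are generator
configuration, chosen once, not claims about any real receptor.

`double_well_1d` encodes a configured basin free-energy gap (default
1.0 kcal/mol at 300 K) *exactly* in its stationary distribution via detailed
balance, so landscape recovery has a closed-form truth.
`bottleneck_chain` is a six-state linear chain with forward probability 0.02
and backward 0.15 per frame — a landscape biased against forward progress,
the regime where least-counts restarts should beat a single long trajectory.
`randomErgodicChain` produces metastable two-basin chains with
fast-relaxing transit states for the TPT-versus-simulation checks.

Dihedral ensembles plant a coupling chain: each residue along the path is a
wrapped-normal perturbation of its predecessor with noise standard deviation
$90(1 - c)$ degrees for coupling strength $c$ (so $c = 1$ is an exact copy);
off-path residues are independent. Consecutive path residues are placed
4.5 Å apart, decoy short contacts (4.0 Å) connect uncoupled pairs, and
non-consecutive path residues are kept out of contact so that transitive
correlations cannot create distance-gated shortcuts. The two conditions
differ by a 70° mean shift on a configured subset of off-path residues — the
ground truth for divergence-ranking tests.

## What the generator does not emulate

Gaussian emissions are unimodal and frame-wise independent given the state:
real feature time series have intra-state autocorrelation, anharmonic and
multimodal basins, and state-dependent noise couplings. The generator's
hidden chain is Markovian at unit lag by construction, so implied-timescale
curves are flat from lag 1, whereas real discretized dynamics converge only
beyond some lag. Passing the recovery suite therefore demonstrates that the
estimators are correct and internally consistent — not that any particular
MD dataset is well described by an MSM, which remains a judgement call made
with the implied-timescale and cross-validation tools the package provides.

# Study sizes and numerical choices

The validation suite and the acceptance script use problem sizes chosen so
that statistical noise sits well below each tolerance: generator recovery
uses 100 trajectories of 10,000 frames (10^6 transitions; sampling error on
any transition probability below 0.002); the double-well landscape uses
5 × 10^5 frames (gap noise ~0.02 kcal/mol against a 0.15 tolerance);
TPT simulation oracles use 10,000 first-passage runs or hit-fraction runs
per check (Monte-Carlo error ~1% and ~0.005); kMC consistency uses 10^6
steps on a fast-mixing two-state model, where the ergodic noise floor is
~0.003 in L1 — on a slowly mixing chain the same run length would measure
trajectory length rather than kMC correctness. The cross-validated VAMP2
selection study deliberately uses scarce data (12 × 100 frames) because
saturation makes the selection question trivial, and meaningless, with
abundant data. The adaptive-sampling comparison is 20 rounds × 5
trajectories × 20 steps against a single 2000-step trajectory, paired over
20 seeds with a one-sided sign test.

Other numerical choices: covariance ridge $10^{-8}$ tr$/F$; k-means++ with
10 restarts and a 200k-frame fitting cap; landscape bins masked (NA) when
empty; committor solutions clamped to $[0, 1]$ against roundoff; macrostate
count ties broken toward lower indices; kMC cumulative rows closed at 1 plus
an epsilon so a draw of $R = 1 - \epsilon$ cannot fall off the row.

# Known limitations

The estimator family is deliberately small: no Bayesian MSM posteriors, no
hidden-Markov coarse-graining, no PCCA+, no reactive-pathway decomposition
beyond net flux and MFPT, and no reading of raw MD trajectory formats —
featurization from structures happens upstream. The $\pi_A$ MFPT convention
is faithful to the formula it implements but, as noted, diverges from other
TPT rate conventions when intermediates are heavily populated. Mutual
information uses fixed-width binning; estimators with adaptive partitioning
would have lower bias at small sample sizes but also weaker invariance
guarantees for the permutation-null gate.
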