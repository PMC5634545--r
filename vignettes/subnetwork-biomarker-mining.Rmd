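---
title: "Mining discriminative subnetwork biomarkers from coherence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining discriminative subnetwork biomarkers from coherence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Functional neuroimaging studies often summarize each experimental session as
a *global-state network*: a fully connected graph whose nodes are brain
regions, whose edge weights are pairwise coherence values of the regional
activity time series, and which carries a single binary label for the whole
session — here, whether the session showed a high or a low learning rate in
a sensorimotor task. The scientific question is not which single edge
differs between states but which small, *connected* subgraphs of edges carry
a coherence pattern that discriminates the states. Connectivity matters
because a set of edges sharing regions is interpretable as a coordinated
circuit, while a scatter of unrelated edges usually is not.

`subnetminer` implements this analysis end to end: network construction from
time series, behavioral labeling, a spectral subnetwork learner, consensus
mining over repeated cross-validation, and significance testing against a
null of random connected subgraphs, with q-value (FDR) control.

# From sessions to labeled networks

**Coherence networks.** Each session's regional time series (T time points
by N regions) becomes an N-by-N matrix of band-limited magnitude-squared
coherence. The estimator is an analytic-Morlet continuous wavelet transform
with time-smoothed auto- and cross-spectra, averaged over fixed frequency
bins spanning the band of interest (default 0.06–0.12 Hz, a standard
low-frequency band for hemodynamic signals sampled at a TR of about 2 s).
Two numerical choices deserve note:

* the smoothing window spans twenty wavelet scales (capped at half the
  series length). Adjacent wavelet coefficients decorrelate over roughly one
  scale, so a window of only a few scales averages almost no independent
  information and biases the coherence of unrelated signals toward one.
  With the default window the mean coherence of independent white-noise
  pairs is near 0.1 at T = 4096;
* zero-variance inputs raise an error naming the offending region rather
  than returning an imputed value — a silently imputed coherence would
  contaminate the null model downstream.

The estimator is deliberately a standard, reproducible choice; it is
pluggable, so an alternative spectral estimator (for example a
minimum-variance distortionless response estimator) can stand behind the
same `band_coherence()` interface.

**Labels from behavior.** Movement time across trial bins is fit by
nonlinear least squares to `MT(b) = A exp(-kappa b) + B`, with `kappa >= 0`
and an asymptote `B` because movement time cannot physically decay to zero.
The decay rate `kappa` (the learning-rate drop-off) is the labeling
statistic. The fit uses a deterministic initializer plus five jittered
restarts under a fixed seed, keeping the best sum of squares, so it is
reproducible. Session labels come from clustering the drop-off values into
two groups many times (one-dimensional 2-means with random initial centers);
the modal partition's center midpoint is the pivot, values above it are
labeled `"high"`, and the fraction of repetitions agreeing with the modal
partition is reported as a stability measure. Ties between equally frequent
partitions go to the partition with the larger between-center gap.

# The edge-dual graph

Subgraph mining operates on the *edge-dual* (line) graph: every functional
edge becomes a dual vertex, and two vertices are linked iff their region
pairs share exactly one region. For a clique on N regions the dual has
`|E| = N(N-1)/2` vertices and `|L| = |E|(N-2)` links (for N = 112 regions:
6216 vertices and 683,760 links; for the 4-region worked example: 6 vertices
and 12 links). The transform's value is the exact correspondence between
link-connected vertex sets in the dual and connected edge sets in the
original network, which reduces "connected subgraph of edges" to "connected
set of dual vertices".

Vertex order is canonical: lexicographic on the sorted region pair, with
0-based region ids. Every on-disk artifact references regions through the
atlas (names plus explicit ids); internal matrix indices never leak to disk.

# Sub-network learning (SNL)

Let `V` be the |E|-by-m matrix whose columns are the sessions' edge
coherence vectors, and `y` their labels. Cosine similarity between session
vectors weighs two meta-networks: `A+` over same-label pairs and `A-` over
different-label pairs; `D` is the diagonal of row sums of `A+`. The learner
seeks the one-dimensional projection `u` over dual vertices that minimizes
the projected scatter of same-label pairs while maximizing that of
different-label pairs, subject to a topology penalty `u'Cu` (with `C` the
dual-graph combinatorial Laplacian) and the normalization
`u'(V D V')u = 1`.

The package solves the Lagrangian form: `u` is the top generalized
eigenvector of

$$(V L^- V^\top - V L^+ V^\top - \lambda C)\,u = \mu\,(V D V^\top + \epsilon I)\,u,$$

with `L+`/`L-` the Laplacians of `A+`/`A-`. This is exact for the quadratic
objective, and the ridge-type weight `lambda` plays the role of the
topology-budget parameter, tuned by inner cross-validation together with the
number of selected edges. Numerical choices:

* `V D V'` has rank at most m, which is always far below |E|; a ridge
  `epsilon I` with `epsilon = 1e-8 * trace(V D V')/|E|` makes the metric
  positive definite. The scaling keeps the ridge meaningful regardless of
  the coherence scale;
* the eigenproblem is whitened through a Cholesky factor of the metric and
  solved as a symmetric dense problem, so the optimum is global and
  deterministic; the sign is fixed by making the largest-magnitude entry of
  `u` positive;
* "cosine distance used as weights" is implemented as cosine *similarity*
  weights: the objective pulls same-label pairs together proportionally to
  their affinity weight, so similar pairs must carry the larger weight —
  distance weighting would invert that semantics;
* edge selection takes the k largest `|u|` entries, with exact ties broken
  toward the canonically smaller vertex (logged), and partitions them into
  dual-connected components;
* the inner-CV classifier on selected features is a linear support-vector
  machine (a linear margin classifier); it is a pluggable choice. Grid ties
  go to the smaller k, then the smaller lambda, preferring the most
  parsimonious model.

Useful invariants, all covered by tests: the solution is invariant to
rescaling all sessions by a positive constant; increasing `lambda` never
increases the Laplacian quadratic form of the returned `u`; and the returned
vector dominates random feasible vectors in objective value.

# Consensus over repeated cross-validation

A single selection run on few, high-dimensional sessions overfits. The
pipeline therefore repeats stratified k-fold cross-validation (default
9 folds, 5 repeats, hence 45 training runs), records each run's tuned
selection, and mines subgraphs *conserved* across runs: every
link-connected dual vertex set of size 1 to `max_subgraph_edges` contained
in the selected set of at least `ceiling(threshold * n_runs)` runs (default
threshold one third). Folds are stratified by label because unstratified
9-fold splits of a study with a few dozen sessions can easily produce
single-class folds.

Because dual vertices carry unique identities (region pairs), frequent
connected-subgraph mining degenerates to set inclusion, and the enumeration
grows connected sets from frequent single vertices with antimonotone
pruning — exactly the frequent-connected-subgraph semantics of gSpan on
uniquely labeled graphs, without DFS-code canonization, which is
unnecessary here. All frequent connected subgraphs are reported, not only
maximal ones, so the candidate list is intentionally redundant. Support
counts a subgraph once per run when it is contained in the run's full
selected set, even if that selection is larger or disconnected. The default
size cap of 8 edges bounds combinatorial growth generously relative to the
1–5 edge range observed in practice.

# Significance against a uniform connected null

A conserved subgraph might discriminate merely because *any* subgraph of its
size does. Each candidate's cross-validated accuracy (polynomial-kernel SVM,
degree 3 by default, on its edge features only) is therefore compared with a
background of `background_samples_per_size` (default 1000) random connected
subgraphs of the same size, classified under the same fold scheme and seed
policy so that the comparison is like with like. Resubstitution accuracy is
available as a configuration mode, but cross-validation is the default for
both candidates and background. Exactly duplicated feature columns are
dropped before classification, making accuracy invariant to feature
redundancy.

**Uniform sampling.** Null subgraphs are drawn uniformly over all connected
k-sets by a Metropolis chain: a step removes a vertex whose deletion keeps
the remainder connected, adds a uniform neighbor of the remainder, and
accepts with ratio `R(S)/R(S')` where `R` counts removable vertices. The
neighbor-count proposal factors cancel because both directions share the
same remainder, so the stationary distribution is exactly uniform. Burn-in
and thinning default to 100 and 5 steps per edge. A design note on
validation: total-variation distance to the exact uniform distribution is
asserted below 0.05 at 10^4 draws on every enumerable instance whose
multinomial noise floor permits it; for the N = 6 clique at size 3 (260
connected sets) even a perfect sampler has an expected TV near 0.06 at that
draw count, so uniformity there is verified by a chi-square goodness-of-fit
test at the same draws instead.

**p- and q-values.** Empirical p-values are one-sided and add-one smoothed,
`p = (1 + #{background >= observed}) / (n + 1)`, so p is always positive.
q-values follow Storey's estimator with the null proportion estimated at
lambda = 0.5; with fewer than 20 p-values that estimate is unstable, so
pi0 = 1 is used and the result coincides exactly with Benjamini–Hochberg
step-up adjustment (cross-checked in tests). Candidates with q at or below
`q_threshold` (default 0.015, boundary inclusive) are retained, the union of
their edges is split into connected biomarker regions, and each union edge
is summarized by its class-conditional mean coherence and its Pearson
correlation with the continuous drop-off.

# The synthetic study generator

The generator exists so that every stage is testable without imaging data,
and its defaults define the benchmark conditions used throughout the tests:
20 regions, 27 sessions per class, a planted connected 3-edge subgraph
whose mean coherence differs by 0.25 between classes, a baseline coherence
of 0.5, and exponential behavioral curves with `kappa = 0.5` (high) versus
`0.05` (low), amplitude 2, asymptote 1, and noise 0.05 s. The
session-to-session coherence noise is 0.15: this puts the per-edge effect
size near d = 1.7 and single-edge classifier accuracy close to the 74–85%
range reported for candidate subgraphs in real sensorimotor data, which is
what makes it a realistic difficulty level rather than a toy separation.

Two modes decouple concerns. *Coherence mode* (fast) draws session
coherence matrices directly — truncated normal around the class-conditional
means, truncation to (0, 1) by redraw so symmetry of the noise is preserved
— and exercises everything downstream of network construction.
*Time-series mode* synthesizes regional series from shared band-limited
(0.06–0.12 Hz) latent oscillators, with planted pairs sharing an extra
oscillator in high-label sessions, and exercises the full pipeline through
the wavelet coherence estimator. What the generator does **not** emulate:
hemodynamic response shapes, spatial autocorrelation between neighboring
regions, physiological confounds, scanner drift, or subject-level random
effects. Passing tests on this benchmark therefore demonstrate the
statistical machinery — recovery of a planted connected effect at realistic
effect size and FDR control under label permutation — not robustness to
fMRI artifacts.

# Problem sizes used by the test suite

The suite runs the full benchmark pipeline at the default conditions over
ten seeds for recovery, plus five label-permuted replicates at the same
scale for type-I control, and a separate fifty-replicate permutation study
at a reduced scale (8 regions, 10 sessions per class, 200 null samples per
size) to estimate the retained-fraction rate more stably. Oracle-equivalence
checks (miner versus exhaustive enumeration, dual components versus
original-graph connectivity, sampler versus enumeration) run on cliques of
up to 6 regions where exhaustive enumeration is exact. These sizes were
chosen so exact oracles exist and the planted effect is neither trivial nor
hopeless at the benchmark's sample size.

# Known limitations

* Two classes only; ordinal or continuous state labels would need a
  redesigned `A-` weighting and are out of scope.
* Coherence is static per session; time-resolved (dynamic) connectivity is
  not modeled.
* The dual is built from the clique topology; sparse input networks are not
  supported.
* The exact spectral estimator of the original acquisition pipeline is not
  reproduced; the wavelet estimator is a documented, validated substitute
  behind the same interface.
* Background accuracy distributions are recomputed per study; they are valid
  for the study's session count and fold scheme only and are not
  transferable across studies.
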