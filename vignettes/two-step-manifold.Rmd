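---
title: "A shared low-dimensional manifold of multi-subject brain dynamics"
author: "manifoldDyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shared low-dimensional manifold of multi-subject brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manifoldDyn)
```

## The model

Large-scale brain dynamics measured with fMRI are believed to move on a
latent space of much lower dimension than the number of recorded regions.
`manifoldDyn` recovers such a space from several subjects at once, under one
structural assumption: the subjects are *time-synchronized* — at frame $t$
every subject is experiencing the same experimental condition — so that a
frame is a meaningful group-level object. Data enter as a third-order tensor
$X \in \mathbb{R}^{M \times V \times T}$ (subjects × regions × frames),
held in a `GroupTensor`.

### Diffusion maps

The core primitive is the diffusion map. Given $n$ points, a Gaussian kernel
$S_{ij} = \exp(-\lVert x_i - x_j \rVert^2 / \varepsilon)$ is row-normalized
into a random walk $P = D^{-1} S$. The right eigenvectors $\psi_j$ of $P$
(eigenvalues $1 = \lambda_0 \ge \lambda_1 \ge \dots$), weighted as
$\lambda_j^t \psi_j$ and with the constant pair dropped, embed the points so
that Euclidean distance equals the *diffusion distance* — the
stationary-weighted $L^2$ distance between the points' $t$-step transition
distributions. The package normalizes eigenvectors to unit
stationary-weighted norm, which makes this identity exact for the full
spectrum; `diffusionDistance()` evaluates the defining sum by explicit
matrix powering and serves as the independent oracle the test suite checks
the spectral route against (agreement is at the $10^{-13}$ level).

Because the walk only trusts *local* similarities, the embedding follows
curved trajectories that linear projections fold over; this is the entire
reason a diffusion map, and not PCA, sits at the core.

### The two-step construction

Comparing raw activation patterns across subjects is unreliable without a
precise anatomical correspondence. The two-step construction sidesteps it:

1. **Stage 1** — each subject's $T$ frames (columns of a $V \times T$
   matrix) are embedded *independently* into $d_1$ dimensions.
2. **Concatenation** — the per-subject coordinates of each frame are stacked
   into a $T \times (M d_1)$ matrix: a frame is now described by how every
   subject's dynamics position it, not by raw activity.
3. **Stage 2** — a second diffusion map reduces these group descriptions to
   $d_2$ dimensions.

Distances in the stage-2 embedding approximate the per-subject diffusion
distances averaged over subjects, which is what makes the result a *group*
geometry. The defaults $d_1 = 7$, $d_2 = 3$ are the values used throughout;
the recovery tests show results change by less than 0.1 in correlation for
$d_1 \in \{5, \dots, 9\}$ and $d_2 \in \{2, 3, 4\}$.

`twoStepPCA()` is the deliberately matched linear baseline (per-subject PCA,
concatenate, PCA again). On a Swiss-roll latent its first coordinate cannot
track the unrolled arclength while the diffusion variant can; the acceptance
suite quantifies the gap (Spearman margin ≈ 0.4 at the study conditions
below).

## Tunable parameters

* **Kernel bandwidth $\varepsilon$** (unitless, squared-distance scale).
  Three strategies:
  * `"median"` (default): the median of all pairwise squared distances.
    Scale-free and right for gently curved trajectories (arcs, circles,
    slow task loops).
  * `"knn"`: median squared distance to the `knn`-th nearest neighbour
    (default `knn = 15`). A *local* scale, needed when the manifold folds
    back on itself so closely that the global median bridges separate
    sheets; the Swiss-roll benchmark uses it at both stages. Its failure
    mode is the opposite one: on strongly clustered data it can disconnect
    the kernel graph.
  * `"fixed"`: a user-supplied value, for reproducing a previous run.
  The bandwidth is chosen per stage and per subject: the two stages operate
  on entirely different scales.
* **Diffusion time $t$** (default 1). Larger $t$ damps small-eigenvalue
  directions as $\lambda^t$; useful to denoise, at the cost of flattening
  genuine fine structure.
* **Per-region z-scoring** (default on) removes region amplitude dominance
  before the kernel sees the frames. Disable (`zscore = FALSE`) only when
  amplitudes are already commensurable.
* **MTD window $w$** (default 14 frames, ≈ 10 s at TR = 0.72 s; use ~4 at
  TR = 2 s). The sliding window averages the derivative products; the
  derivative and the window together shorten the time axis to
  $T - 1 - w$ connectivity frames, and `frameMap()` records exactly which
  original frames survive rather than leaving the alignment implicit.
* **k-means restarts** (default 50) and the CH range $k = 2 \dots 10$:
  model selection by the Calinski–Harabasz index is unstable under
  single-initialization k-means, so every $k$ is fit with many seeded
  restarts.
* **Louvain seed and resolution** (default 1): community detection is
  stochastic; all partitions in this package are reproducible from the seed.

## Extending new data onto a trained manifold

A diffusion embedding has no explicit forward map, so new frames are placed
by the Nyström extension: evaluate the kernel row of a new point against the
training points *with the training bandwidth*, normalize it to transition
probabilities, and average the training eigenvectors,
$\hat\psi_j(y) = \lambda_j^{-1} \sum_i p(y, x_i)\, \psi_j(x_i)$. Re-using
the training bandwidth is required for self-consistency: extending a
training point then reproduces its coordinates exactly (machine precision in
the tests). The two-step version (`twoStepOOSE()`) chains a stage-1
extension per subject with a stage-2 extension of the concatenated result.

Resting scans are not synchronized across subjects, so before extension each
subject is rotated in time onto a reference subject with `brainSync()`: with
region series normalized to zero mean and unit norm, frames lie on a
hypersphere, and the best temporal alignment is the orthogonal Procrustes
rotation obtained from the SVD of the temporal cross-correlation (the Kabsch
solution). Row centering makes the constant time direction always
degenerate; the implementation solves the Procrustes problem on its
orthogonal complement and acts as the identity there, which makes the
solution canonical and recovers the identity when the scans are equal.
A scan aligned to its own hidden rotation is recovered to $10^{-14}$.

## Dynamics on the manifold

* **MTD connectivity**: the windowed product of derivative z-scores is an
  edge-weight series that tracks coupling changes at frame resolution.
* **Communities and participation**: Louvain modularity on the positive
  part of each slice gives time-resolved modules; the participation
  coefficient $B_i = 1 - \sum_s (k_{is}/k_i)^2$ (positive strengths only)
  measures how evenly a region's connections spread over modules, and its
  regional mean $B_T$ indexes whole-brain integration. Negative MTD weights
  are excluded from both steps: the coefficient is defined on positive
  strengths, and signed modularity would introduce an unrelated ambiguity.
* **States**: k-means on the embedding coordinates, with $k$ chosen by the
  Calinski–Harabasz index; extended (e.g. resting) frames inherit the state
  of their *nearest training frame*, not the nearest centroid, so state
  boundaries follow the data geometry.
* **Markov structure**: transitions are counted between temporally adjacent
  frames — never across run or task boundaries, which would fabricate
  transitions that never occurred — with self-transitions included, so the
  stationary distribution of the estimated chain is the dwell-time
  distribution. Entropy of each outgoing row (natural log, so nats;
  $0\log 0 = 0$) quantifies how predictable leaving a state is, from 0
  (deterministic) to $\log k$. States with fewer than 10 observed outgoing
  transitions are flagged as unreliable rather than silently reported.
  Uniformity of dwell times is tested with Pearson's chi-squared statistic
  against equal expectations ($df = k - 1$).

## What the synthetic generator emulates — and what it does not

`simulateGroupTensor()` produces the only data the test and acceptance
suites use: $M$ subjects sharing a latent trajectory (arc, circle,
Swiss roll, or a $k$-state Markov chain), pushed through subject-specific
mixing matrices with Gaussian noise calibrated so each region's
signal-SD/noise-SD ratio equals `snr`. Design choices worth knowing:

* Planted Markov states sit on a **regular simplex** (all pairs of state
  means equidistant, edge 8 × the within-state spread), randomly rotated.
  Randomly drawn means frequently produce two nearly coincident states,
  which collapses one cluster-separating eigenvalue and makes CH
  over-partition; equidistant means are what "well-separated discrete
  states" should mean in a ground-truth object.
* Noise is i.i.d. Gaussian per region and frame by default (an `arCoef`
  flag adds AR(1) temporal correlation). There is no hemodynamic response,
  no spatial autocorrelation, no motion artifact, and the mixing is linear.
  Passing tests therefore demonstrate that the *geometry recovery* machinery
  is correct, not that real fMRI satisfies its assumptions.
* `simulateUnsyncPair()` hides an exact orthogonal time rotation (chosen to
  fix the constant vector, so row normalization is preserved) and returns
  it, enabling exact-recovery tests of the synchronization step.

## Study conditions and problem sizes

The validation experiments run at sizes chosen to exercise the estimators
meaningfully while remaining quick on a single core: arc recovery at
$M = 8$, $V = 60$, $T = 300$, SNR 5 over 10 seeds (median recovery
correlation ≈ 0.98); the Swiss-roll contrast at $M = 5$, $V = 40$,
$T = 200$, SNR 5, roll $u \in [1.5\pi, 3.5\pi]$, height $\in [0, 6]$, over
20 seeds; chain estimation at $T = 10{,}000$ labels; the chi-squared
calibration over 1,000 multinomial replicates of 100 frames; and the
end-to-end planted-state pipeline at $M = 8$, $T = 1{,}000$ frames over
5 seeds. Those constants are stated here as the package's reference
conditions so results are comparable across runs.

## Numerical choices

* Eigendecomposition runs on the symmetric conjugate
  $D^{-1/2} S D^{-1/2}$ and converts back to right eigenvectors of $P$ — a
  stability contract with no observable effect.
* Eigenvector signs are fixed (largest-magnitude entry positive) so outputs
  are reproducible across platforms.
* The trivial eigenpair is identified via its closed form $D^{1/2}\mathbf 1$:
  when the top eigenvalue is numerically degenerate the returned basis of
  that eigenspace is an arbitrary rotation, so the implementation rotates
  the near-top group to expose the constant vector before dropping it, and
  errors if the constant vector is not in the span.
* Duplicate points are legal (kernel value 1); a kernel bandwidth of zero
  (all points identical) is an error.
* In two-step PCA, a rank-deficient subject is zero-padded to $d_1$
  components with a warning instead of aborting the whole group.
* CH model selection on diffusion coordinates can over-partition when
  cluster images are strongly anisotropic; at the reference conditions it
  selects the planted $k$ in ≈ 9 of 10 runs, and clustering *at* the true
  $k$ is essentially perfect (ARI ≈ 1). This mirrors the known sensitivity
  of dispersion-ratio criteria to cluster shape.

## Known limitations

* Frames are points: no temporal smoothness prior links adjacent frames, so
  very noisy single frames can drift across state boundaries.
* The group embedding assumes all subjects share $V$ and $T$; unequal
  lengths require synchronization or truncation upstream.
* The `"knn"` bandwidth can disconnect the kernel graph on strongly
  clustered data (the trivial-pair error above); the `"median"` default can
  fail to unroll tightly wrapped manifolds. Neither is universal — the
  bandwidth is the one genuinely data-dependent choice the user owns.
* Louvain communities are computed per window; temporal multilayer
  modularity is a known alternative the package deliberately does not
  implement.
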