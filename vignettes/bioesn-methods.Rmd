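---
title: "Connectome-constrained echo state networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained echo state networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioesn)
```

## Overview

`bioesn` builds echo state networks (ESNs) whose recurrent wiring is
dictated by an area-level connectome, so that the contribution of a
biological wiring diagram to working-memory performance can be isolated
from the contribution of weights, density and size. The package covers
the whole experimental loop: connectome handling and synthesis, five
surrogate connectivity conditions, neuron-level upscaling with weight
conservation, reservoir dynamics and readout training, the Memory
Capacity and Sequence Recall benchmarks, and a replicate/grid-search
harness.

Throughout, entry $W_{ij}$ of any connectivity matrix is the connection
from source $i$ to target $j$, and diagonals are zero (no self-loops at
any level).

## The reservoir model

The reservoir state $\mathbf r(t) \in \mathbb R^{N_r}$ is driven by an
input $\mathbf x(t) \in \mathbb R^{N_x}$ through dense input weights
$W_{in} \sim \mathrm{Uniform}[-1,1]^{N_r \times N_x}$:

$$
\mathbf r'(t) = f\!\left(W_{in}\,(\epsilon\,\mathbf x(t)) + W\,\mathbf r(t-1) + b\mathbf 1\right),
\qquad
\mathbf r(t) = \alpha\,\mathbf r'(t) + (1-\alpha)\,\mathbf r(t-1),
$$

with $f = \tanh$ (states bounded in $[-1, 1]$), leakage rate
$\alpha \in (0, 1]$, scalar bias $b$ and input scaling $\epsilon$.
States start at $\mathbf r = \mathbf 0$; the first 100 steps (the
washout transient) are discarded from both fitting and scoring because
they reflect the arbitrary initial condition. A variant of the leak term
that multiplies the retained state by $W$ once more is available via
`leakIntegration = "printed"`; at $\alpha = 1$, the value used for all
main experiments, the two forms are identical, and the standard
leaky-integrator form is the default because it is the established
convention and keeps $\alpha < 1$ interpretable as a low-pass filter.

The readout is linear on the concatenation $[\mathbf x(t); \mathbf r(t)]$:

$$
\hat{\mathbf y}(t) = g\!\left(W_{out}\,[\mathbf x(t); \mathbf r(t)]\right),
\qquad
W_{out} = Z^{+} Y,
$$

where $Z$ stacks the post-transient concatenated rows and $Z^{+}$ is the
Moore-Penrose pseudoinverse. The solution is computed by SVD with the
standard rank-revealing cutoff (singular values below
$\max(\dim Z)\cdot\varepsilon_{mach}\cdot\sigma_{max}$ treated as zero),
which makes it the minimum-norm least-squares solution and keeps the fit
well defined when $Z$ is rank deficient. No ridge penalty is applied by
default. The readout concatenates the *unscaled* input: least squares is
invariant to regressor scaling, and at $\epsilon = 10^{-5}$ the unscaled
column is far better conditioned. $g$ is the identity for Memory
Capacity and a rectifier for Sequence Recall, whose targets are
non-negative.

### Hyperparameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\rho$ | spectral radius imposed on $W$ | 0.99 | fixed post-tuning constellation; near the edge of stability, where memory is longest |
| $\epsilon$ | input scaling | $10^{-5}$ | keeps the reservoir in its near-linear regime, which favors pure memory tasks |
| $\alpha$ | leakage rate | 1 | no leakage performed best during tuning |
| $b$ | bias | 1 | fixed post-tuning constellation |
| transient | washout steps discarded | 100 | exceeds the longest default lag (40) and the mixing time at $\rho = 0.99$ |

`paperGrid()` enumerates the full 300-constellation tuning grid
($\rho \in \{0.91, 0.93, \ldots, 0.99\}$,
$\epsilon \in \{10^{-9}, \ldots, 10^{0}\}$, $\alpha \in \{0.6, 0.8, 1\}$,
$b \in \{0, 1\}$); `gridSearch()` trains each constellation with
independently generated reservoirs and selects the best mean validation
score. The validation split is not dictated by the protocol totals
(4000/1000 steps, 800/200 trials), so the harness carves the last 20% of
the training span as validation and reports that choice here.

## Connectivity conditions

Spectral scaling ($W \leftarrow \rho W / |\lambda|_{max}$) is applied
after construction in every condition, so conditions differ only in
*where* weights sit, not in global gain. A nilpotent wiring (for example
strictly triangular) has true spectral radius 0 and cannot be rescaled;
it is detected exactly by repeated squaring rather than by eigenvalue
magnitude, which is numerically unreliable for nilpotent matrices.

- **bio-rank** keeps the empirical binary mask and places freshly
  sampled $\mathrm{Uniform}[-1,1]$ weights so their rank order matches
  the empirical strengths (most negative sample on the weakest link,
  largest on the strongest; empirical ties broken by (source, target)
  index order, which makes the condition deterministic given the draw).
- **bio-no-rank** keeps the mask, permutes the sampled weights uniformly.
- **random-density** redraws the wiring uniformly with exactly the
  empirical link count.
- **random-k** wires a fixed fan-in of $k = 10$ incoming links per
  neuron. The direction of the constraint is a genuine gap in the
  protocol description; fixed fan-in is the sparse-ESN convention and is
  the default, with `degree = "out"` exposed.
- **random-full** connects all $n(n-1)$ ordered pairs.

Exact-zero uniform draws are resampled so the mask is always recoverable
from the weights.

## Upscaling areas to neuron populations

`upscaleConnectome()` maps each of $N$ areas onto $m$ neurons
(`neuronsPerArea`), giving $N_r = N m$. For every empirical link
$(i, j)$ all $m^2$ neuron pairs are connected and the empirical weight
is partitioned across them, so each interareal block sums exactly to
$w_{ij}$ (conservation is property-tested to $10^{-12}$ relative error
across scaling factors 1-30). Homogeneous mapping splits in equal
parts; heterogeneous mapping splits by random proportions. Intrinsic
(within-area) connectivity follows the empirical rule that within-region
strength is about 80% of a region's extrinsic between-region strength:
each area's intrinsic total is `intrinsicRatio` (default 0.8) times its
total *outgoing* interareal weight (the source-centric reading of an
ambiguous budget; `extrinsicBasis = "in"` selects the alternative), and
all $m(m-1)$ within-area pairs are formed by default
(`intraConnFraction = 1`). With $m = 1$ the result is the source
connectome unchanged.

**Random proportions.** The heterogeneous partition draws proportions
from a symmetric Dirichlet with concentration $\alpha_c = 0.1$
(`concentration`). This choice matters and was made deliberately. A
near-flat partition (e.g. normalized uniform draws) spreads each block's
entries only about two-fold around the block mean, so the neuron-level
weight *order* still mirrors the area-level order; a rank-preserving
surrogate of the upscaled network then inherits the area-level
organization at every scale, and its low-rank coherent structure
produces spectral outliers that pin the normalized spectrum and cap
memory regardless of size. A small concentration instead gives the
sparse, strongly skewed allocation that axonal projections show at
synapse level - a few neuron pairs carry most of a projection's weight -
and lets within-block randomness genuinely dominate the neuron-level
rank order at larger scales. $\alpha_c \to \infty$ recovers the
homogeneous split; $\alpha_c = 1$ is the flat Dirichlet.

For scaled experiments the pipeline is: upscale first (non-negative
neuron-level weights), then apply the surrogate condition to the
upscaled matrix, then rescale the spectrum. This order keeps all five
conditions well defined at every size; for bio-rank, ranking against the
upscaled neuron-level weights is the default and ranking against the
area-level block weights is exposed (`rankBy = "area"`).

## Tasks and scoring

**Memory Capacity.** A single stream
$x(t) \sim \mathrm{Uniform}(-0.5, 0.5)$ with one readout per lag $\tau$
trained to reproduce $x(t - \tau)$; 4000 training and 1000 subsequent
test steps, states re-initialized to zero at the start of the test split
and the first 100 test steps discarded. The per-lag score is the squared
Pearson correlation $\rho^2(y_\tau, \hat y_\tau)$ (the forgetting curve)
and $\mathrm{MC} = \sum_\tau \rho^2$. A constant series is scored 0 - a
constant prediction has no memory content - rather than leaving the
correlation undefined. The lag set is not part of the printed protocol;
the default 1-40 spans the forgetting-curve decay at the sizes studied
here and is configurable.

**Sequence Recall.** Two channels: a value stream
$x_1(t) \sim \mathrm{Uniform}(0, 1)$ and a cue $x_2 \in \{0, 1\}$. A
trial is a fixation period (cue 0, target 0) followed by $L$ recall
steps (cue 1) during which the target replays the last $L$ fixation
values in order; $L$ sets the difficulty. 800 training and 200 test
trials, concatenated into one continuous series per split with a single
100-step washout each. Scoring is the pooled $R^2$ over post-transient
recall steps only, because the fixation phase is trivially easy and
would inflate the score. Choices the protocol leaves open, fixed here:
the fixation period defaults to $L$ steps (trials of length $2L$);
$x_1$ is silenced during recall so that incoming values do not interfere
with replay (configurable); and trials are pooled into a single $R^2$
rather than averaged per trial.

## The synthetic connectome generator

No accession information accompanies the published primate connectivity
datasets, so the package ships a generator whose defaults stand in for
them in every experiment and test. `synthConnectome()` produces a
directed graph over $N$ areas with: a modular mask (contiguous modules,
intra-module ordered pairs filled before inter-module pairs, realized
link count within one link of `round(density * N(N-1))`); strictly
positive, heavy-tailed weights with an exactly log-normal marginal
(meanlog 0, sdlog 1, times `weightScale`); and two weight-placement
rules that emulate how strength and topology covary in real cortical
connectomes:

1. intra-module links receive the largest draws (strong projections
   concentrate within modules and over short distances);
2. the two directions of a connected area pair receive adjacent ranks,
   hence near-identical strengths (strong projections are strongly
   reciprocal).

The second rule is the one the rank-preserving condition is sensitive
to: placing signed weights by empirical rank on a reciprocally
correlated connectome yields a nearly symmetric signed reservoir, and
symmetric reservoirs - whose spectra collapse toward the real axis -
have markedly lower memory capacity than asymmetric ones. If instead
weights were placed independently of topology, rank-preserving and
rank-free placement would be indistinguishable in distribution and no
synthetic connectome could express a topology effect at all. What
passing tests show is therefore conditional: they demonstrate that the
pipeline detects the consequences of strength-topology structure when
it is present, not that any particular species' connectome has it to a
particular degree. Features of real data the generator does not emulate
include distance-dependent weight decay, broad in-/out-degree
heterogeneity and hubs, partial (rather than near-total) reciprocity,
and inter-subject variability.

The experiment-scale defaults used by the test suite are a 30-area,
3-module connectome at density 0.35 - in the density range of dense
primate parcellations and modular enough that the mask is meaningfully
biological - with 20 replicate networks per condition, upscaling factors
1-8, and the full 4000/1000-step task protocol.

## Numerical and degenerate-input conventions

- Seeded functions restore the caller's RNG state; experiment cells
  derive independent seeds from the base seed by integer mixing, so
  replicates use newly instantiated weights while whole sweeps are
  bit-reproducible.
- Diagonal entries found in loaded matrices are zeroed with a warning
  (tolerant loading of real exports); negative or non-finite entries are
  rejected.
- Delimited output uses 17 significant digits, which round-trips doubles
  exactly.
- Degenerate inputs raise typed conditions (`bioesnFormatError`,
  `bioesnValidationError`, `bioesnDegenerateError`) so callers and the
  command-line interface can distinguish usage from data problems; sweep
  cells that fail are recorded and skipped rather than aborting the
  sweep.

## Known limitations

- The empirical connectomes themselves are out of scope; users supply
  their own matrices (no normalization is applied on load, and none is
  assumed).
- Only the five listed surrogate conditions are provided - no
  degree-preserving rewiring or geometry-aware null models.
- No ridge regularization, feedback connections or online training.
- The command-line interface is a thin script over the package
  (`system.file("cli", "bioesn.R", package = "bioesn")`), not an
  installed binary.
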