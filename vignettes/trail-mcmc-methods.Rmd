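---
title: "Trail MCMC and collective-exploration analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trail MCMC and collective-exploration analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailmc)
```

## The problem

A central-place forager — an ant leaving its nest, or equally a
Metropolis–Hastings walker on a probability landscape — wastes effort
revisiting ground it has already found unprofitable. A colony compounds the
problem: many walkers leave the same origin with no central controller to
divide the space between them. One evolutionary answer is stigmergy: each
walker deposits a cheap chemical mark wherever it goes, and later walkers
read the accumulated field as "already explored" and steer elsewhere. The
same trick works for samplers. `trailmc` implements both sides of this
analogy: a self-avoiding MCMC sampler driven by an externalized memory, and
an analysis pipeline that quantifies how efficiently a cohort of walkers
(real or simulated) covers its arena.

## The trail sampler

The sampler operates on a 2D lattice with periodic boundaries. A proposal
adds an independent uniform draw from $\{-1, 0, +1\}$ to each coordinate, so
each of the nine Moore-neighbourhood cells (the current one included) is
proposed with probability $1/9$. Plain Metropolis–Hastings accepts with
probability $\min(1, P(\text{prop})/P(\text{curr}))$ and targets $P$.

The trail variant keeps a memory field $M$, initialized to a Dirichlet prior
of $\alpha$ pseudo-counts per cell (default $\alpha = 1$) and incremented by
one at the walker's cell after every step — including steps whose proposal
was rejected, just as a stationary ant keeps marking the ground beneath it.
Its acceptance ratio is

$$
\frac{P(\text{prop})}{P(\text{curr})}\times
\frac{P(\text{prop})/M(\text{prop})}{P(\text{curr})/M(\text{curr})},
$$

so the chain targets $P^2/M$ (renormalized). The squared term makes a cell
of probability 0.2 four times — not twice — as attractive as a cell of 0.1,
sharpening the pull toward high-probability regions; the $1/M$ term repels
the walker from ground it has covered. Because deposits accumulate in
proportion to visits, $M/\sum M \to P$ in the long run and the objective
relaxes back to $P$ itself: the bias is transient by construction.

Numerical choices:

* **Lazy normalization.** $M$ enters the ratio only through
  $M(\text{curr})/M(\text{prop})$, which is invariant under global rescaling
  of the field. We therefore keep raw counts and never renormalize, which is
  mathematically identical to renormalizing after every deposit but costs
  O(1) per step instead of O(cells). The ratio is grouped as
  $(P_p/P_c)^2 \cdot (M_c/M_p)$ so the invariance holds bit-for-bit, not
  just in exact arithmetic.
* **Zero-mass target cells.** Sparse random targets can contain cells whose
  gamma draw underflowed to zero. A proposal into such a cell from positive
  support has ratio 0 (never accepted); a walker *starting* on null support
  accepts any positive-mass proposal (ratio $\infty$) and treats $0/0$ as 1,
  diffusing freely until it finds support. This keeps the chain from
  stalling at initialization without ever biasing it afterwards.
* **Tie rule.** A ratio of exactly 1 is accepted with probability 1 (the
  `ratio > rand` branch), matching the strict inequalities of the
  accept/reject rule.
* **Cleaning.** `cleaning_times` resets the deposit field to the pure prior
  after the named steps, modelling the removal of accumulated marks between
  successive walkers; deposits keep accumulating between resets.
* **Decay.** With decay constant $\lambda > 0$, the deposit excess above the
  prior is multiplied by $e^{-\lambda}$ once per step before the deposit.
  The prior floor never decays, keeping $M$ strictly positive; as
  $\lambda \to \infty$ the memory collapses to the prior and the kernel
  reduces exactly to Metropolis–Hastings on $P^2$.
* **Start state.** Uniform-random by default (seedable); the start is not
  part of the model, only of a run.
* **RNG discipline.** One seeded stream per chain; proposal and acceptance
  draws are consumed in a fixed order, so traces replay exactly.

### Measuring convergence

Convergence is scored by the cross-entropy (in nats)
$\mathrm{CE}(P, Q) = -\sum P \log Q$ between the target and an estimate
built from the chain. By Gibbs' inequality $\mathrm{CE} \ge H(P)$ with
equality iff $Q = P$ on $P$'s support, so the entropy of the target is the
floor every curve converges to. The logarithm base is natural throughout:
the base only rescales curves, and nats are the entropy literature's
default.

Two estimates are supported, because either can be meant by "the sample":
the default is the smoothed empirical visit histogram (counts plus one
pseudo-count per cell, normalized — the smoothing guarantees the positivity
cross-entropy requires); the alternative is the normalized memory field.
Without cleaning or decay the two coincide exactly (the memory *is* the
visit count plus the prior), so the choice only matters for cleaned or
decaying runs.

## The trajectory pipeline

The analysis half turns tracked paths — columns
`ant_id, colony, treatment, order, t_s, x_mm, y_mm`, points every 0.1 s in a
90 × 90 cm arena centred on the nest — into density targets and convergence
curves.

1. **Mask removal.** Points strictly inside the central 15 × 15 cm mask
   (half-width 75 mm) are dropped: walkers mill around their entrance and
   edge-follow the mask before true exploration begins. The boundary itself
   is kept.
2. **Log-polar transform.** $(x, y) \mapsto (\theta, \ln r)$ about the nest,
   $\theta \in (-\pi, \pi]$, radii in mm. The transform equalizes visit
   density across radii — a plain spatial histogram has effectively larger
   bins far out and tiny, densely revisited bins near the centre — which
   makes comparisons between trajectories more powerful. Points with
   $\ln r$ outside the open interval $(4.3, 6.5)$ (roughly 74 mm to 665 mm,
   the arena's radial extent beyond the mask) are dropped and counted, as
   are zero-radius points whose log is undefined. Both the mask cut and the
   lower radial cut are applied even though they overlap; they are two
   distinct pipeline steps.
3. **Periodic padding.** Every point is copied once across the angular
   seam ($\theta \le 0 \to \theta + 2\pi$; $\theta > 0 \to \theta - 2\pi$),
   extending the data onto $[-2\pi, 2\pi]$ so the blur sees periodic data
   and no ringing appears at $\pm\pi$.
4. **Histogram, blur, truncate, normalize.** Points are binned to the
   nearest node of the padded lattice — with the default steps (0.01 rad,
   0.0025 ln-mm) that lattice is 1257 × 881 nodes — convolved with an
   isotropic Gaussian of $\sigma$ cells (default 30), truncated back to
   $\theta \in [-\pi, \pi]$ (629 × 881 nodes) and normalized to total mass
   one. In log-radial space a constant lattice $\sigma$ is a growing
   physical blur: roughly 6 mm near the nest and 40 mm at the arena edge,
   matching the scale at which a millimetre-sized walker "covers" ground.
   The kernel is truncated at $4\sigma$ and boundaries are handled by mirror
   reflection, so the blur conserves mass exactly and leaves uniform fields
   unchanged.

Pooling all walkers of a cohort through this pipeline gives the empirical
target; pooling walkers $1..k$ of one colony and scoring against that target
gives the cumulative convergence curve by release order. Colony curves are
averaged within treatment, with the standard error across colonies. Because
a partial density can be exactly zero where the target is positive (the
kernel has finite support), each cumulative density is mixed with a uniform
field at weight $10^{-6}$ before scoring — small enough that the identity
case (a curve scored against the target its own pooling built) sits within a
millinat of the entropy floor.

Two null/summary tools complete the pipeline. **Markov ants** resample the
pooled movement vector: 1-second segments (10 consecutive displacement
vectors) are drawn uniformly and concatenated, rejecting segments that
would leave the arena — walkers with the same movement statistics but no
memory of any kind, internal or external. **Exit sides** finds, per walker,
the first linearly-interpolated crossing of a centred square's boundary and
tallies the four sides; walkers that never leave are reported separately
rather than dropped (ties at a corner break in the fixed order right, left,
top, bottom).

## Inference

Three procedures cover the pipeline's significance claims:

* **Paired sign-flip permutation test.** The treatment contrast is paired by
  construction — the same colonies and release orders under two treatments —
  so the null swaps labels within each (colony, order) pair independently,
  i.e. flips the sign of each paired difference. The statistic is the mean
  difference; enumeration is exhaustive whenever $2^{n}\le 2^{20}$ (15 pairs
  is 32,768 flips), removing Monte Carlo noise; otherwise the add-one Monte
  Carlo estimate $p = (1 + \#\{|T^\*| \ge |T|\})/(1 + n_{\text{perm}})$ is
  used. Two-sided by default. The first-released walker is excluded from
  testing (orders 2 and up): both treatments are equivalent until a
  predecessor has marked the arena.
* **Chi-square goodness of fit** for exit-side counts against stated
  proportions, with $k-1$ degrees of freedom.
* **Exact multinomial test** for the small exit samples where the
  chi-square approximation is unreliable: full enumeration of compositions,
  summing the probability of every outcome at most as probable as the
  observed one (point-probability ordering), guarded by an enumeration
  budget with the chi-square test suggested beyond it.

## The synthetic cohort generator

No tracking data ships with the package, so a generative model stands in
for it. It is deliberately the simplest mechanism that realizes stigmergic
avoidance — a correlated random walk coupled to a repulsive scalar field —
and makes no claim to model real ant kinematics.

Each walker starts at the arena centre with step interval 0.1 s. Its
heading persists with concentration `turning_kappa` (wrapped-normal turn
noise of sd $1/\sqrt{\kappa}$ per step; default $\kappa = 30$), step lengths
follow a truncated normal speed model (default mean 7 mm/s, sd 4 — a 45 min
walk then covers roughly 19 m of path, the scale a small ant manages), and
walls reflect. A weak pull (default 0.05 rad per step at full misalignment)
draws the walker toward its colony's preferred direction, drawn once per
colony from quadrant weights (default favouring quadrant 2 and disfavouring
quadrant 4, the heterogeneity real cohorts display) with a small per-walker
jitter. The preference is environmental — a property of the colony's arena,
not of the individual — which is why it is shared within a colony and, via
`colony_pref_seed`, can be shared between the two cohorts of a treatment
pair, mirroring a paired design in which the same colonies experience both
treatments.

Every walker deposits one mark per step into a 20 mm lattice field; when it
finishes, its deposits join the shared field under a Gaussian spread
(`deposit_sigma_mm`, default 60 — markers are sensed well beyond the
millimetre trail itself). Later walkers feel the local relative gradient of
the shared field plus their own fresh marks and are steered down it with
weight `avoidance_strength` (default 2), saturating at one radian-unit so
the repulsion reweights exploration rather than hard-walling it. The
cleaned treatment (`clean_between_ants = TRUE`, labelled `"C"`) wipes the
shared field before each release: only information from *predecessors* is
removed, each walker still lays and reacts to its own marks while walking —
exactly what cleaning an arena between releases leaves intact. Setting
`avoidance_strength = 0` removes the coupling altogether.

The avoidance defaults were chosen by a calibration sweep of the planted
effect size: at these values the uncleaned-vs-cleaned contrast, run through
the full pipeline and the paired permutation test on orders 2–6, is
detected in at least 8 of 10 replicate cohort pairs at $\alpha = 0.05$,
while exchangeable (no-effect) cohorts reject at the nominal 5% rate. What
passing those tests shows is that the *pipeline and test* recover a planted
avoidance effect of plausible magnitude; it says nothing about whether real
ants show the effect, and the generator omits much that real data contain —
stops and movement events, speed–turn coupling, thigmotaxis along mask and
walls, individual heterogeneity, and any chemistry of the markers
themselves.

## Experiment drivers and problem sizes

`run_experiment()` packages three reproducible drivers: the sparse-target
sampler benchmark (`fig3_sparse`: plain M–H vs trail vs trail with the
memory cleaned at each of five episode boundaries, 60,000 steps, sparse
gamma target of shape 0.1 on a 50 × 50 lattice), the same conditions on an
empirical-style target (`fig4_empirical`, any grid file; by default a
synthetic stand-in built by running the pipeline on a simulated cohort), and
the synthetic treatment contrast (`fig2_synthetic`).

The test suite exercises these at sizes chosen to keep the full run in
minutes while leaving every conclusion stochastic-test-stable: sampler
oracles on 3 × 3 lattices (where single-step kernels are compared entry-wise
to enumeration at $10^{-12}$), convergence checks on 10 × 10 targets over
$2\times10^5$ steps, the sparse benchmark at its full 50 × 50 / 60,000-step
size over 20 seeds, and the cohort contrast at full duration (2700 s per
walker) on a coarsened log-polar lattice (steps 0.05 rad / 0.0125 ln-mm,
blur $\sigma = 10$ cells — a slightly broader physical blur than the
full-resolution default, which keeps colony-level densities smooth at this
resolution). The full-resolution 1257 × 881 lattice is exercised directly in
the geometry and target-construction tests.

## Known limitations

* On extremely heavy-tailed sparse targets (gamma shape 0.1), neighbouring
  cells differ by many orders of magnitude and both samplers are nearly
  immobile at a 60,000-step budget; the trail variant's advantage is large
  on average but seed-to-seed variance is of the same order, so orderings
  asserted per-seed at that sparseness are unreliable even though the mean
  separation is clear (at shape 0.5 the per-seed ordering is essentially
  deterministic).
* The sampler is single-walker; simultaneous interacting walkers are out of
  scope.
* Cross-entropy against a *finite* sample never reaches the floor exactly;
  the smoothing pseudo-count biases it slightly upward, identically across
  compared conditions.
* The exact multinomial test enumerates compositions and is practical only
  for small samples; its budget guard suggests the chi-square test beyond
  roughly a million outcomes.
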