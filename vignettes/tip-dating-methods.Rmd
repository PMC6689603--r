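---
title: "Bayesian tip dating with partitioned morphological clocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian tip dating with partitioned morphological clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`morphclock` estimates time-calibrated phylogenies and per-branch
evolutionary rates from discrete morphological character matrices in
which fossils appear as dated tips. Three model components are joined in
one posterior: the Mkv substitution model for the characters, the
fossilized birth--death (FBD) process as the prior on the dated tree, and
a reparametrized white-noise (independent gamma) relaxed clock that gives
every branch its own relative rate in every character partition.
Inference is by Metropolis-coupled MCMC with reversible-jump moves for
fossil-ancestor placement.

# The character model

Characters are discrete with states coded `0..k-1`. Unordered characters
change between any two states at equal rates; ordered characters change
only between adjacent states. Both rate matrices are normalized so that
one unit of branch length equals one expected change per character at the
uniform stationary distribution; for an ordered k-state chain the
adjacent rate is therefore `k/(2(k-1))` (3/4 for k = 3).

Rate variation across characters follows a discrete gamma distribution
with shape `alpha` and (by default) four equal-probability categories
summarized by their means. `alpha` has an exponential(1) prior. Four
categories are the de facto standard of Bayesian phylogenetics software
and changing `ncat` is a configuration option.

Because morphologists code only variable characters, the likelihood of
every character is conditioned on variability (the Mkv acquisition-bias
correction): each character's likelihood is divided by one minus the
summed likelihoods of the constant columns of its state-count/ordering
class, computed with the same gamma averaging. The correction is applied
per class, not per observed pattern, which is the conditioning the model
definition implies. On a tree whose branch distances are all zero the
corrected likelihood is `-Inf` (no character could vary).

Missing (`?`) and inapplicable (`-`) cells both contribute a partial
likelihood of 1 for every state: the Mk family has no machinery for
inapplicability, so the gap symbol is treated as full ambiguity.
Polymorphic cells contribute 1 for each listed state.

Likelihoods are computed by Felsenstein pruning with uniform 1/k root
frequencies and per-node rescaling against underflow; a plain R
implementation serves as the reference, and a C++ kernel evaluates the
same quantity in the samplers. The unit tests hold both paths to a
brute-force enumeration oracle at 1e-8 relative tolerance on 4-taxon
trees.

# The tree model

The FBD process starts at the root with two lineages: each lineage
speciates at rate `lambda`, dies at rate `mu`, is fossil-sampled at rate
`psi` and is removed upon sampling with probability `r`; extant lineages
are sampled with probability `rho` (fixed, default 0.0002). With `r < 1`
a fossil may be a *sampled ancestor*: it sits on a lineage with sampled
descendants and is represented as a tip attached by a zero-duration
branch. Setting `r = 1` forbids ancestors and needs no reversible jump.

For inference the rates are reparametrized as net diversification
`d = lambda - mu - r*psi` (exponential prior, mean 0.01; negative
diversification is excluded), turnover `v = (mu + r*psi)/lambda` and
fossil-sampling proportion `s = psi/(mu + psi)`, both uniform(0, 1).

The density of the sampled tree follows the standard constant-rate
derivation with removal. Conditioning is a genuinely open choice; the
package conditions on the root age (the root-age prior is explicit, an
offset-exponential with default offset 153 Ma and mean 169 Ma) and, by
default, on at least one lineage being sampled
(`condition = "sampling"`); `condition = "root"` drops the survival
factor. Fossil ages have uniform priors over their stratigraphic ranges;
an optional normal calibration can be placed on the age of a constrained
clade.

An important and easily overlooked property of *any* FBD implementation
over a fixed taxon set: the joint prior's marginal distributions of the
root age and of (d, v, s) are **not** the assigned priors. The density
is not normalized over the slice of trees with exactly the observed
samples, so it acts as data for those parameters (the induced-prior
effect). For a minimal two-extant-taxon dataset under `r = 1` we measured
by importance sampling a shift of E[v] from 0.50 to about 0.09 and of
the root-age mean from 169 to about 172; larger fossil sets tilt more.
The `alpha`, `c` and `sigma_j` marginals are exact (their conditionals
integrate out of the joint), and prior-only MCMC recovers them to within
Monte-Carlo error, which is the package's main sampler-correctness check.

# The clock model

Branch lengths in the likelihood are distances
`b_ij = t_i * c * r_ij`: time duration times mean clock rate times the
branch-and-partition relative rate. Each `r_ij` has a gamma prior with
mean 1 and variance `sigma_j / (t_i * c)` (shape and rate both
`t_i * c / sigma_j`), so long branches are clock-like and short branches
may deviate wildly; `sigma_j -> 0` recovers a strict clock. The mean
rate `c` has a gamma(2, 200) prior (mean 0.01 changes per character per
Myr, sd ~0.007) and each `sigma_j` an exponential(10) prior. With n
partitions the clock has n + 1 free hyperparameters plus the relative
rates.

Zero-duration branches (sampled-ancestor attachments) carry no rate
variable and contribute zero distance. Across topology proposals,
relative rates stay attached to their node index, so unaffected branches
keep their rates; reversible-jump moves that create a fossil's subtending
branch draw its rates from the prior and account for the density in the
acceptance ratio. A single shared `alpha` is the default
(`alpha_per_partition = TRUE` estimates one per partition).

# MCMC design

The sampler is a random-scan Metropolis(-coupled) chain over topology,
node ages, fossil ages, ancestor flags, relative rates and all scalars.
Several moves deserve comment because the posterior has two awkward
geometries:

* **The clock funnel.** The density of `r_ij` at 1 grows like
  `sqrt(t_i c / sigma_j)`, so states with tiny `sigma_j` and all rates
  pinned at 1 form high-density spikes that plain random-walk moves
  enter and cannot leave. Three moves address this: an independence
  redraw of single rates from their prior (a Gibbs update in prior-only
  runs), a quantile-preserving `sigma_j` scaler that maps every rate
  through its gamma CDF so the prior terms cancel analytically, and
  prior-drawn initial rates (an all-ones start sits exactly on the
  spike).
* **The time--rate ridge.** Ages and the mean rate trade off almost
  freely where fossils do not pin the tree. A joint rescaling move
  multiplies all free internal ages by m and divides `c` by m, moving
  along the ridge; a whole-tree age scaler handles the root. Both use
  small step sizes (fossil-pinned trees reject large ones) with an
  occasional four-fold stride, and the same two-scale trick is applied
  to all scalar multipliers. The `alpha` move additionally mixes in a
  prior-independence proposal, which is what lets chains cross between
  strong and weak rate-variation regimes.

Burn-in is annealed: every chain's posterior power ramps linearly from
`anneal_start` (default 0.5) to its target heat across the burn-in
window. Annealed iterations are discarded with the burn-in, so retained
samples come from the exact target; the ramp exists purely to make the
basin choice at initialization robust. Metropolis coupling uses
incremental heats `1/(1 + 0.1 i)` and proposes adjacent-pair swaps.

Initialization builds a compact constraint-respecting tree (random joins
a little older than the younger child, fossil ages drawn in their
windows), scalars from their priors, rates from the clock prior; states
are re-drawn until the posterior is finite.

The production sampler is written in C++ and mirrors a plain-R reference
implementation move for move; the tests verify that recorded log
posteriors from the C++ engine equal independent recomputation through
the R likelihood and prior functions at every checked sample.

# The synthetic-data generator

`simulate_fbd_tree()` runs the FBD process forward from two root
lineages, prunes to sampled lineages with ancestors flagged, and rejects
until both root children are sampled (so the root age is the nominal
one) and the sample count lies in a band. `simulate_branch_rates()` and
`simulate_characters()` then draw white-noise rates and evolve
characters, discarding invariant ones (and, for multistate characters,
those with fewer than three observed states) to emulate coding practice.
Stratigraphic windows are centered on true fossil ages, half-width 5 Myr
by default, truncated at zero.

`make_bird_scale_scenario()` targets the structure of a comprehensive
Mesozoic-bird matrix: six partitions of sizes 53/36/48/65/23/55, exactly 193 binary
and 87 multistate characters of which 36 are ordered (deterministic
composition), a ~160-Ma tree with a taxon band of 50-90 (68 reachable by
exact rejection), a handful of extant samples at `rho`-style sampling,
and FBD rates (0.04, 0.03, 0.08 with r = 0) chosen so the median tree
lands in that band.

What the generator does *not* emulate: geographic or stratigraphic
non-uniformity of the fossil record, correlated characters,
inapplicability structure, and the real matrix's missing-data pattern
(synthetic matrices are fully scored). Tests passing on synthetic data
therefore validate the statistical machinery, not the paleontological
difficulty of real matrices.

# Calibration experiments

The test suite's parameter-recovery experiment uses simulation-based
calibration: every replicate draws the root age, (d, v, s), `c`,
`sigma_j` and `alpha` from the model's own priors, simulates a 14-26
taxon tree (rejected unless an old fossil spans at least 60% of the root
age, mirroring the bird matrix where the oldest bird nearly reaches the
root), evolves two 40-character partitions, elevates one mid-length
internal branch's rate tenfold in partition 1, and runs the standard
two-independent-runs protocol at 100k iterations each. Coverage of the 95% HPDs is
then compared with its nominal rate, and the elevated branch is checked
to be the partition's highest posterior-mean rate among well-supported
internal branches. Truths drawn from the priors are the only design
under which nominal coverage is the mathematically expected outcome; the
residual gap (the fixed-taxon-set conditioning of the tree prior, and
the single designed rate outlier) is discussed with the results.

Problem sizes throughout the suite are chosen for desk-scale runs: the
oracle likelihood checks use 3-4 taxa where enumeration is exact, the
prior-recovery run uses a 10-ish-taxon fossil dataset with millions of
prior-only iterations, and the recovery suite uses the reduced scale
above. The full-scale schedule (tens of millions of iterations,
four chains, two runs) is available through `mcmc_config()` unchanged.

# Numerical choices and degenerate inputs

* Transition probabilities come from the symmetric eigendecomposition
  (closed form for unordered matrices); negative round-off entries are
  clamped at zero.
* Partial likelihoods are rescaled per node; log-sum-exp combines gamma
  categories.
* The Mkv denominator `1 - P(constant)` at an all-zero-distance tree is
  zero and yields `-Inf` rather than an error, so such states are simply
  rejected in sampling.
* HPD intervals use the shortest-window-on-sorted-samples rule with ties
  broken toward the lower start.
* Majority-rule consensus keeps clades above frequency 0.5 (mutually
  compatible by construction); branch-level summaries are conditional on
  the samples containing the bipartition, which is the only coherent way
  to average rates across topologies.
* Zero-width calibration windows are treated as fixed ages and excluded
  from tip-age moves.

# Known limitations

* Single constant-rate FBD regime: no skyline rates, no
  diversified-sampling correction.
* No autocorrelated clocks; no correlated characters; no
  inapplicable-state machinery.
* The rjMCMC ancestor toggle mixes slowly when partitions are many and
  characters few, as reported for the original analyses; partitioned
  runs default to fossils-as-tips (`removal_prob = 1`) in the examples.
* Moderate-scale matrices (hundreds of taxa) would need the pruning
  kernel's partial-likelihood caching to be extended across iterations.
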