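# morphclock

Bayesian tip dating of discrete morphological matrices with partitioned
relaxed clocks.

`morphclock` is for paleontologists and systematists who want to estimate
*when* clades diverged and *how fast* morphology evolved, directly from a
character matrix in which dated fossils are tips of the tree. It joins
three model components in one posterior:

* **Mkv likelihood** — the k-state Markov model for discrete characters
  with discrete-gamma rate variation across characters (shape α,
  exponential(1) prior), ordered multistate characters restricted to
  adjacent-state change, and the acquisition-bias correction for
  matrices that code only variable characters.
* **Fossilized birth–death (FBD) tree prior** — speciation λ, extinction
  μ, fossil sampling ψ, removal-on-sampling probability r and extant
  sampling ρ; reparametrized for inference as net diversification
  d = λ − μ − rψ ~ exponential (mean 0.01), turnover v = (μ + rψ)/λ and
  fossil-sampling proportion s = ψ/(μ + ψ), both uniform(0, 1). With
  r < 1, fossils may be *sampled ancestors* placed on lineages by
  reversible-jump MCMC. Fossil ages get uniform priors over their
  stratigraphic ranges; the root age an offset-exponential prior.
* **Partitioned white-noise relaxed clock** — branch length (distance)
  is b<sub>ij</sub> = t<sub>i</sub> · c · r<sub>ij</sub>: time duration ×
  mean clock rate × a branch-and-partition relative rate. Each
  r<sub>ij</sub> is gamma distributed with mean 1 and variance
  σ<sub>j</sub>/(t<sub>i</sub> c), so each partition j (for instance each
  anatomical region) has its own rate-heterogeneity level σ<sub>j</sub>.
  Priors: c ~ gamma(2, 200), σ<sub>j</sub> ~ exponential(10).

Inference is Metropolis-coupled MCMC (compiled core, annealed burn-in,
constraint-respecting tree moves, funnel- and ridge-aware proposals).
Posterior summaries include majority-rule consensus trees with clade
probabilities and node-age HPDs, per-branch per-partition relative-rate
summaries keyed by bipartition, and sampled-ancestor probabilities. A
synthetic-data module simulates the whole generative process —
FBD trees, white-noise rates, Mk characters with acquisition-bias
filtering, stratigraphic windows — for end-to-end validation.

## Worked example

Simulate a small fossil dataset from the model, then infer ages and
rates back:

```r
library(morphclock)
set.seed(7)

fbd  <- fbd_params(lambda = 0.1, mu = 0.05, psi = 0.05, r = 0, rho = 0.9)
tree <- simulate_fbd_tree(fbd, root_age = 40, taxon_range = c(12, 20))
rates <- simulate_branch_rates(tree, c_rate = 0.01, sigma = c(0.05, 0.05))
mat  <- simulate_characters(tree, rates, c_rate = 0.01, alpha = 1.8,
  partitions = list(
    cranial     = list(n = 40, p_binary = 0.7, k_multi = 3L, p_ordered = 0.4),
    postcranial = list(n = 40, p_binary = 0.7, k_multi = 3L, p_ordered = 0.4)))
dat <- tip_dating_data(mat, stratigraphic_windows(tree, half_width = 5))

cfg <- mcmc_config(n_runs = 2, n_chains = 1, n_iter = 50000,
                   sample_every = 100, seed = 7, removal_prob = 0,
                   root_offset = 35, root_mean = 45)
res  <- run_tip_dating(dat, cfg)
post <- combined_samples(res)
hpd_interval(post$t_mrca)
majority_rule_consensus(combined_trees(res))
```

Output of this exact script:

```
character_matrix: 12 taxa x 80 characters (8 ordered), partitions: cranial, postcranial
time_tree: 12 tips (6 fossil, 5 sampled ancestors), root age 40.00 Ma
tip_dating_result: 2 run(s), 501 samples each (125 burn-in)
  post-burn-in t_mrca mean 42.60 Ma, c mean 0.0128
root age: mean 42.6 Ma, 95% HPD (35.2, 50.6); truth 40.0
mean clock rate c: 0.0128 (truth 0.010)
gamma shape alpha: 1.74 (truth 1.8)
fossil-ancestor fraction: 0.48
consensus_tree: 12 tips, 9 resolved clades, root age (median) 42.16 Ma
```

The root-age HPD brackets the generating value (40 Ma), the mean clock
rate is recovered near its true 0.01 substitutions per character per
Myr, and about half of the fossil samples are placed as ancestors in
this ancestor-rich simulation. `clade_table()` gives per-clade posterior
probabilities, age HPDs and branch rates; `clade_rate_distribution()`
summarizes rate heterogeneity within a clade as boxplot statistics.

Real data enter through `read_character_matrix()` (NEXUS),
`read_tip_calibrations()` (TSV of stratigraphic ranges) and
`read_analysis_config()` (YAML partitions / ordered characters /
monophyly constraints); `inst/scripts/morphclock-cli.R` wraps the same
functions as a shell tool (`simulate` / `run` / `summarize`).

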