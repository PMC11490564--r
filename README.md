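# gransucc

Ecological inference for two-kingdom microbial succession in granulating
bioreactors.

Aerobic granular sludge grows out of floccular activated sludge in
sequencing batch reactors, and over a year of operation both the
prokaryotic (16S) and micro-eukaryotic (18S) community fractions pass
through distinct successional stages — floccular, intermediate, granular —
while the balance between deterministic assembly (environmental selection)
and stochastic assembly (drift, random colonization) shifts. `gransucc`
implements the full inference chain used to characterize such time series
from paired ASV count tables, rooted phylogenies and reactor metadata, and
ships a synthetic two-kingdom community generator with known ground truth
so that every step is testable without sequencing data.

## What it computes

* **Diversity** — Hill numbers $^qTD = (\sum_i p_i^q)^{1/(1-q)}$ for any
  order (richness, exp-Shannon, inverse Simpson at $q = 0, 1, 2$), and
  pairwise beta dissimilarity bounded in [0, 1] from the multiplicative
  decomposition $\beta = \gamma/\alpha \in [1, 2]$ of two equally weighted
  samples, evaluated between successive time points.
* **Assembly null models** — environmental optima (abundance-weighted
  means) with a Mantel-correlogram phylogenetic-signal test; NRI/NTI
  (negated standardized effects of abundance-weighted MPD/MNTD against
  taxa-label shuffles); betaNTI (beta-MNTD against 999 tip shuffles,
  $|\beta NTI| > 2$ = deterministic turnover); Raup–Crick on Bray–Curtis
  (richness- and depth-preserving null assembly, $|RC| \le 0.95$ =
  consistent with drift).
* **Networks** — dual-method consensus co-occurrence networks (Spearman
  and SparCC both $|r| > 0.6$ with FDR-corrected $p < 0.05$), walktrap
  modules with temporal completeness/abundance dynamics, per-time-point
  network properties, and the core (>75% prevalence) inter-kingdom
  bipartite network of positive associations. SparCC (log-ratio variances
  under a sparsity assumption, Dirichlet-posterior draws, iterative
  strongest-pair exclusion, bootstrap pseudo p-values) is implemented in
  the package.
* **Ordination** — distance-based RDA on Bray–Curtis with permutation
  forward selection and three-way variance partitioning (abiotic
  parameters | the other kingdom's alpha diversity | granulation stage)
  by inclusion–exclusion on adjusted $R^2$.
* **Simulation** — `scenario()` / `simulate_reactor_series()`: Yule trees,
  guild-structured Brownian environmental optima, a stage-structured
  latent reactor state with derived covariates, replicator-with-immigration
  dynamics observed through multinomial read sampling, and unidirectional
  prokaryote-to-eukaryote coupling, with per-ASV ground truth recorded.
  Presets `paper_like`, `selection` and `neutral` encode calibrated
  assembly regimes.

## Worked example

```r
library(gransucc)

# simulate a reduced paper-like reactor run: 26 samples, 72 + 36 ASVs
sc <- scenario("paper_like", n_samples = 26, n_prok = 72, n_euk = 36,
               depth_prok = 3000, depth_euk = 2000, seed = 11)
sim <- simulate_reactor_series(sc)
sim$prok_table
#> <count_table> prokaryote: 26 samples x 72 ASVs, depth 3000-3000

# alpha diversity collapse after reactor start-up
hp <- hill_profile(sim$prok_table)
rich <- hp$qTD[hp$q == 0]
cat(sprintf("richness: %d (day 0) -> %d (minimum)\n", rich[1], min(rich)))
#> richness: 65 (day 0) -> 26 (minimum)

# successive-pair null models (999 null iterations per pair)
to <- turnover_series(sim$prok_table, sim$prok_tree, n_null = 999, seed = 1)
stage <- sim$env$stage[-1]
aggregate(cbind(bnti, rc_bray) ~ stage, data.frame(to, stage), mean)
#>          stage       bnti    rc_bray
#> 1    floccular  9.0840449  0.9259259
#> 2 intermediate  1.9190980 -0.4879165
#> 3     granular -0.3054079 -0.9878702
```

The mean betaNTI far above +2 in the floccular stage is the deterministic
start-up transient — the inoculum community being filtered by the new
reactor environment; by the granular stage betaNTI sits inside the null
band (drift-dominated turnover) while Raup–Crick below −0.95 reflects the
now strongly repeatable composition of successive samples.

## Analysis workflow

The `analysis/` directory holds the numbered end-to-end workflow, each a
thin driver over the package that prints what it finds and writes tidy
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic two-kingdom reactor series
Rscript analysis/02_diversity.R      # Hill profiles + successive beta series
Rscript analysis/03_assembly_nulls.R # phylogenetic signal, NRI/NTI, betaNTI, RCbray
Rscript analysis/04_networks.R       # consensus networks, modules, bipartite core
Rscript analysis/05_ordination.R     # forward selection, dbRDA, variance partitioning
```

`run_pipeline(pipeline_config(...))` runs the same graph in one call, from
a scenario or from on-disk TSV/Newick/CSV inputs, and writes a JSON summary
that is byte-identical across reruns with the same seed.

## Documentation

The methods vignette (`vignettes/granular-biofilm-ecology.Rmd`) documents
the models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate, the
numerical choices (null-model conventions, SparCC solver details,
degenerate-case handling), and known limitations.
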