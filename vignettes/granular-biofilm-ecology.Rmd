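---
title: "Ecological inference for granular-biofilm succession: models, null models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological inference for granular-biofilm succession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gransucc)
```

# The scientific problem

Aerobic granular sludge develops from floccular activated sludge in
sequencing batch reactors over months, passing through a floccular, an
intermediate, and a granular stage. Along the way the prokaryotic (16S) and
micro-eukaryotic (18S) community fractions succeed in parallel:
sub-communities adapted to each stage rise and fall, and the balance between
deterministic assembly (environmental selection) and stochastic assembly
(drift, random colonization) shifts. `gransucc` implements the quantitative
machinery used to read those dynamics out of paired ASV count tables,
phylogenies, and reactor metadata:

* Hill-number diversity profiles and bounded beta dissimilarity between
  successive samples;
* phylogenetic-signal testing and the null-model battery (NRI/NTI, betaNTI,
  Raup--Crick on Bray--Curtis);
* dual-method (Spearman + SparCC) consensus co-occurrence networks, their
  walktrap modules, temporal module dynamics, and a core inter-kingdom
  bipartite network;
* distance-based redundancy analysis with permutation forward selection and
  three-way variance partitioning.

Because deep amplicon datasets are impractical to ship, the package carries
a fully specified synthetic generator for two-kingdom reactor communities
with known ground truth. Every downstream method is exercised and validated
against that generator.

# Diversity

For one sample with relative abundances $p_i$, the Hill number of order $q$
is

$$^qTD = \Big(\sum_i p_i^q\Big)^{1/(1-q)},$$

with the $q \to 1$ limit $\exp(-\sum_i p_i \log p_i)$. $q=0$ is richness,
$q=1$ the exponential Shannon entropy, $q=2$ the reciprocal Simpson
concentration. For a pair of equally weighted samples the package uses the
multiplicative decomposition $\beta = \gamma/\alpha \in [1, 2]$, where
$\gamma$ is the Hill number of the averaged composition and $\alpha$ the
two-assemblage alpha
$\frac{1}{2}\big(\sum_{ij} (p_{ij}/2)^q\big)^{1/(1-q)}$. $\beta$ is mapped
onto $[0,1]$ by the Sørensen-type local overlap complement
$1 - C_{q2}$ with
$C_{q2} = [(1/\beta)^{q-1} - (1/2)^{q-1}]/[1 - (1/2)^{q-1}]$
(default), or the Jaccard-type regional variant behind a flag; at $q=1$
both reduce to $\log\beta/\log 2$. The index family admits both variants
and we found no basis to prefer the regional one, so the local transform is
the default and all internal comparisons use it.

# Null models of community assembly

All null models run on the rarefied, *unfiltered* tables: the 10%
prevalence / 0.1% abundance filter exists to stabilize correlation
estimates and is applied only in the network stage.

**Phylogenetic signal.** Using environmental optima defined as
abundance-weighted means of a reactor variable, a Mantel correlogram
correlates pairwise optimum differences with membership in equal-frequency
phylogenetic-distance classes, with permutation p-values (ASV identities
shuffled) and progressive Holm correction. The statistic is sign-flipped so
that positive values at short distances mean close relatives share
preferences — the premise that justifies phylogenetic null models. With a
single class the statistic degenerates to the plain Mantel correlation.
Equal-frequency classes were chosen over equal-width ones because
unit-depth trees concentrate many pairs at the maximal distance.

**Alpha dispersion.** Abundance-weighted MPD
($\sum_{i \ne j} f_i f_j d_{ij} / \sum_{i \ne j} f_i f_j$) and MNTD
($\sum_i f_i \min_{j \ne i} d_{ij}$) are compared against a taxa-labels
null that shuffles the distance-matrix labels across the full ASV pool;
NRI/NTI are the negated standardized effects, so positive values mean
clustering. Note one convention detail: some implementations average MPD
over all ordered pairs including the zero self-pairs; ours excludes
$i = j$. The two differ by the constant factor $1 - \sum_i f_i^2$, which
cancels exactly in the standardized effect size. Degenerate nulls (zero
variance, e.g. star phylogenies or a community equal to the pool) return
SES 0 with a flag rather than an error so time series stay aligned.

**Turnover.** Between successive samples, beta-MNTD
$\tfrac12 [\sum_{i \in A} f_{iA} \min_{j \in B} d_{ij} + \sum_{j \in B}
f_{jB} \min_{i \in A} d_{ij}]$ (shared ASVs contribute zero) is judged
against 999 shuffles of the ASVs across the tips of the whole tree;
$|\beta NTI| > 2$ flags deterministic turnover, with negative values
indicating homogeneous selection and positive ones variable selection.
Raup--Crick on Bray--Curtis rebuilds each sample 999 times preserving its
richness and read total, drawing identities with probability proportional
to occupancy and filling reads by a one-read seed plus a multinomial with
dataset-wide relative-abundance weights (uniform weights behind a flag);
ties count half, and the rescaled index lies in $[-1, 1]$ with
$|RC| \le 0.95$ consistent with drift.

# SparCC and consensus networks

SparCC estimates basis correlations from log-ratio variances
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ under the sparsity approximation
$\sum_{j \ne i} r_{ij} \approx 0$. Each estimate averages (by median) 20
Dirichlet-posterior draws of the fractions; after solving the linear system
for the basis variances $\omega$, the most strongly correlated pair above
0.1 is excluded and the system re-solved, for up to 10 rounds. Two
numerical choices matter:

* the exclusion corrections are exactly rank-one updates
  $(e_i + e_j)(e_i + e_j)^\top$ of the base matrix $(d-2)I + J$, so the
  solve uses the closed-form base inverse plus the Woodbury identity —
  at hundreds of ASVs this is the difference between seconds and minutes;
* when the sparsity system returns a non-positive variance (common in
  small, shuffled, or heterogeneous data) that component falls back to its
  raw log-fraction variance; clamping near zero would explode the implied
  correlation to $\pm 1$ and poison the bootstrap null.

Significance comes from a bootstrap null that permutes each ASV's counts
independently across samples. The pseudo p-value floor is $1/(B+1)$, and
after Benjamini--Hochberg correction over $m$ pairs the smallest attainable
q-value is about $m/((B+1)\,k)$ for $k$ discoveries. With the conventional
$B = 100$ this exceeds the 0.05 gate for any realistic network, so the
pipeline default is $B = 999$ null datasets (with 5 Dirichlet draws each —
the null only feeds a tail count, which needs less posterior averaging than
the point estimate). The operation-level default remains 100 for
compatibility with the original algorithm's description.

A consensus edge requires $|\rho| > 0.6$ and $|r_{\text{SparCC}}| > 0.6$
with both FDR-corrected p-values below 0.05; sign disagreements are dropped
with a warning. Walktrap community detection runs on the positive-edge
subgraph with the maximum-modularity cut: a negative edge joins taxa that
exclude each other, and walking across it (even at absolute weight) merges
anti-correlated successional sub-communities into one module — the
opposite of what the modules are for. Negative edges stay in the network
as attributes. Modules are numbered by summed node
abundance, and per-sample properties (edge density, global clustering,
modularity of a fresh walktrap run) are computed on the subgraph induced by
the ASVs detected in that sample (restriction of the global labels is
available behind a flag, but re-detection matches the cited time-step
method more closely). The bipartite core network restricts each kingdom to
ASVs present in more than 75% of samples, computes cross-kingdom Spearman
on per-kingdom closed compositions and SparCC on the concatenated counts
with kingdom-blocked Dirichlet draws, FDR-corrects the cross-kingdom pool
separately, and keeps positive consensus edges only.

# Ordination

dbRDA embeds the Bray--Curtis matrix by principal coordinates (negative
eigenvalues are reported but excluded from the site scores; no
Lingoes/Cailliez correction by default), regresses the positive-axis scores
on internally standardized predictors, and reports the constrained fraction
of positive inertia with Ezekiel's adjustment and a permutation p-value.
Forward selection adds, at each step, the candidate with the smallest
permutation p-value for its marginal pseudo-F, provided $p \le \alpha$ and
the adjusted $R^2$ increases. Variance partitioning fits the seven models
formed by the non-empty subsets of {abiotic, biotic, stage} and decomposes
adjusted $R^2$ by inclusion--exclusion; fractions may be individually
negative and always sum to 1 with the residual. The biotic set is the
other kingdom's alpha diversity at $q \in \{0, 1, 2\}$; stage enters as
treatment-coded dummies. Inside `variance_partition()` aliased columns are
dropped (overlapping sets are the point there), whereas `dbrda()` treats
rank deficiency as a user error.

# The synthetic generator

`simulate_reactor_series()` generates both kingdoms over a 52-sample,
343-day schedule split into the three granulation stages. Its moving parts:

* **Trees.** Pure-birth trees rescaled to unit root-tip depth.
* **Guilds.** ASVs are grouped into successional guilds that are unions of
  clades: the cophenetic dendrogram is cut into 24 clades, the largest
  clades seed the guilds, and every remaining clade joins its
  phylogenetically nearest seed under a soft size cap. (A single cut at
  k = guilds routinely yields one-member guilds on Yule trees; arbitrary
  size balancing scatters guilds across the tree and destroys the
  coherence that selection-based signatures rely on.)
* **Optima.** Brownian deviations (rate `trait_lambda`) are recentered on
  per-guild centers, so optima are conserved at short phylogenetic
  distances but guild-structured at long ones.
* **Environment.** A single latent reactor state with a distinct mean per
  stage plus AR(1) noise; nitrate, VSS, phosphate and TOC are affine
  transforms with observation noise (nitrate and VSS rise with
  granulation, phosphate and TOC fall), so the ordination stage has a
  realistic candidate pool.
* **Dynamics.** A discrete-time replicator with immigration: the previous
  *observed* composition is mixed with a fixed lognormal immigration pool
  at rate $m$, multiplied by the Gaussian fitness
  $w_i = \exp(-(E_t - o_i)^2 / 2\sigma^2)$, renormalized, and read counts
  are drawn multinomially at the kingdom's depth — drift enters purely
  through finite sampling. The first sample is the unselected inoculum,
  which is what makes the start-up transient (and its deterministic
  turnover signal) visible, exactly as a reactor seeded with activated
  sludge shows it. Eukaryote fitness is additionally multiplied by
  $1 + \kappa \cdot$ (relative abundance of the coupled prokaryote guild),
  giving true, unidirectional prokaryote-to-eukaryote associations.
  An optional `imm_concentration` knob makes immigration bursty
  (Gamma-normalized with expectation $m \cdot$ pool); the calibrated
  presets do not need it and default to continuous inflow.

## Preset calibration

The three presets are calibrated so each regime reproduces its qualitative
assembly signature; the settings below were frozen after that calibration
and are not tuned per test.

* `paper_like` — stage means (0, 1, 2), selection widths (0.25, 0.5, 2.0)
  (deterministic early, drift-dominated once granules are established),
  $m = 0.05$, $\kappa = 1.5$, lognormal pool (sdlog 1.5), depths
  43329/31420, 411/125 ASVs. Signatures: guild g dominates stage g; the
  stage-3 guild's network module gains completeness and abundance in the
  granular stage; the fraction of successive pairs with $|\beta NTI| > 2$
  is highest in the floccular stage.
* `selection` — constant environment at the guild-1 center, width 0.15,
  near-clade-constant optima (rate 0.005), high immigration churn
  ($m = 0.8$), moderate pool spread (sdlog 1.2), low read depth (200).
  The high churn plus low depth keep a phylogenetically conserved rare
  tail flickering around the detection threshold; that turnover is what
  makes homogeneous selection legible to betaNTI (mean NTI 3--5 and
  $\beta NTI < -2$ for roughly 90% of successive pairs). With a constant
  dominant core and deep sequencing, successive samples share every taxon
  and betaNTI has nothing to measure — an instructive dead end we document
  rather than hide.
* `neutral` — flat fitness, even-ish pool (sdlog 0.8), $m = 0.1$, depth
  2000. Composition follows immigration plus multinomial drift;
  $|\beta NTI| \le 2$ for $\ge 95\%$ of pairs. Because a drifting time
  series holds one frozen composition, its per-run mean NRI/NTI is itself
  a random draw of order $\pm 1$; the neutral-dispersion check therefore
  averages across replicate simulations rather than trusting one run.

## What the generator does not emulate

Real amplicon data bring features the generator deliberately omits:
compositional overdispersion beyond multinomial noise, chimeras and
spurious ASVs, copy-number variation, uneven library sizes before
rarefaction, taxon-specific PCR bias, and trees with the clumpy
genus-level structure of real 16S phylogenies (pure-birth trees are more
uniform, which makes phylogenetic-dispersion effect sizes conservative).
Passing tests therefore demonstrate that the machinery measures what it
claims on data whose generating process is known — not that any particular
biological conclusion transfers to a given reactor.

# Problem sizes used in the tests

The test-suite scenarios run at reduced sizes chosen as the smallest
communities in which each signature is statistically comfortable: regime
presets at their native 411-ASV pool with 24--30 samples; network and
coupling checks at 26--52 samples with 48--72 prokaryote and 24--36
eukaryote ASVs and depths 2000--3000; the end-to-end determinism check at
52 samples with 199 null iterations and 499 SparCC bootstraps. The
acceptance script runs the full-size paper-like scenario (52 samples,
411/125 ASVs, depths 43329/31420, 999 nulls).

# Known limitations

* SparCC p-values are bootstrap pseudo p-values with floor $1/(B+1)$;
  detecting a handful of edges among many tested pairs at FDR 0.05
  requires $B \gtrsim 20 \cdot$ (pairs per discovery).
* SparCC itself is unreliable below ~20 ASVs; the basis-variance fallback
  keeps estimates bounded but cannot make tiny systems well-posed.
* The Raup--Crick null seeds each selected ASV with one read before the
  multinomial fill; for samples whose richness approaches their read total
  the null is nearly degenerate.
* betaNTI compares one pair at a time against tip shuffles of the whole
  tree; with community sizes approaching the pool size the null loses
  contrast and SES magnitudes shrink toward zero.
* `walktrap` is deterministic, but module *numbering* depends on node
  abundances; comparisons across runs should match modules by membership,
  as the tests do.
* Correlation networks inherit the exchangeability assumptions of their
  significance tests. Slowly drifting compositions are mean-reverting
  random walks, and cross-kingdom rank correlations between two drifting
  kingdoms show classic spurious-nonstationarity associations that the
  count-shuffling bootstrap cannot distinguish from real ones; the
  coupling-detection null therefore uses a well-mixed (high-immigration)
  community whose samples are close to exchangeable.
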