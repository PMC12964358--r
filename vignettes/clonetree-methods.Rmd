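---
title: "Model and inference methods in clonetree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and inference methods in clonetree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk DNA sequencing of one or more tumour samples measures, for each somatic
SNV, the number of reads supporting the variant allele. Clones — genomically
distinct cell sub-populations — mix in each sample, so a mutation's variant
allele frequency (VAF) reflects the fraction of malignant cells that carry it
(its *cellular prevalence*), corrected for copy number and tumour content.
`clonetree` infers the clonal phylogeny: a rooted tree whose nodes are
clusters of mutations that arose in the same clonal expansion, together with
the posterior over such trees.

# The model

**Prior over trees.** Mutations are partitioned by a Chinese restaurant
process with concentration $\alpha$ (default 1). A rooted forest over the $K$
clusters is drawn uniformly at random — there are $(K+1)^{K-1}$ of them, in
bijection with labelled trees on $K+1$ vertices — and attached below an empty
dummy root. For each sample, clonal prevalences $\rho$ (the fraction of cells
*originating* at each node, dummy root included) are drawn from a symmetric
Dirichlet with parameter $\kappa$ (default 1, i.e. uniform on the simplex).
Cellular prevalences follow bottom-up:
$\bar\rho_v = \rho_v + \sum_{c \in \mathrm{children}(v)} \bar\rho_c$, the
infinite-sites assumption in prevalence form.

**Likelihood.** Each mutation–sample pair contributes
$f(x \mid \bar\rho)$, a copy-number and tumour-content corrected count
density: the bulk is a mixture of normal cells, cancer cells without the
mutation, and cancer cells with it, mixing allele counts as
$(1-t)c_N : t(1-\bar\rho)c_R : t\bar\rho c_V$. The number of mutated copies
ranges over $1..\text{major CN}$ with equal weight (the major-copy-number
parsimony prior; the fuller genotype-elicitation menus of the PyClone family
are deliberately out of scope). Counts follow a beta-binomial (default
precision 400, fixed — the reference protocol names the density but no
precision, and a moderate fixed overdispersion is the family convention) or a
binomial.

**Outliers.** A mutation lost to a sub-clonal deletion violates additivity
and fits no tree position. Each mutation gets a prior outlier probability
$\nu_n$: 0.4 if it is flagged as lying in a deletable region, else $10^{-4}$.
An outlier leaves the partition and the tree and is scored by its emission
marginal under a per-sample uniform prevalence prior,
$\sum_s \log \int_0^1 f(x_{ns}\mid\rho)\,d\rho$.

# Marginalizing clonal prevalences

The collapsed target integrates $\rho$ out over the simplex per sample. On an
equally spaced prevalence grid of $G$ points (default 101), each node's
clonal mass becomes a grid variable. The integral is iterated over the $K$
free node coordinates, each carrying a trapezoid quadrature weight times the
Dirichlet factor $\rho^{\kappa-1}$; the dummy root's mass is the dependent
coordinate and carries the Dirichlet factor only. A bottom-up dynamic program
computes, for each node, the distribution of its subtree's total (cellular)
mass: the node's data term multiplies the truncated grid convolution of its
children's messages with its own clonal-mass weights. Reading the top entry
(total mass one) at the dummy root and normalizing by the data-free sum gives
the marginal likelihood. Cost is $O(|V| G^2)$ per sample.

Choices worth noting:

* **Self-normalization.** The discrete composition prior is normalized by its
  own data-free sum, so a data-free tree scores exactly zero and a one-node
  tree reduces exactly to the trapezoidal uniform marginal. As $G$ grows the
  ratio converges to the continuous Dirichlet integral.
* **$\kappa < 1$ is rejected**: the density's boundary singularity cannot be
  represented by point masses on a grid cell; $\kappa \ge 1$ covers the
  supported uses.
* **Support-windowed convolutions.** Log-space convolutions only visit
  entries within 80 nats of each column maximum; clipped entries are floored
  500 nats below the maximum rather than set to $-\infty$, so that states
  whose mass constraints conflict badly remain finitely comparable for the
  samplers. The induced relative error is below $10^{-30}$.
* **Prevalence reinstatement** re-runs the DP in max-product (exact grid MAP)
  or sum-product (posterior draw) mode and backtracks through stored prefix
  convolutions, sample by sample.

# Inference

The sampler targets the collapsed posterior over (tree, partition, outlier
set). Bottom-up SMC builds a rooted forest one pre-clustered block at a time
in a data ordering $\sigma$: a block either joins an existing root, starts a
new node adopting a uniformly random subset of the current roots as children,
or becomes an outlier. The kernel is *semi-adapted*: join-vs-outlier choices
are Gibbs (proportional to the resulting partial target), the new-node
children subset is blind — the stated compromise between proposal quality and
cost.

A fixed $\sigma$ cannot reach every tree, so $\sigma$ is an auxiliary
variable: alternately, $\sigma$ is drawn uniformly among orderings that could
rebuild the current state (every descendant block before its ancestor's
first block — sampled exactly by recursive uniform shuffle-merges), and a
*conditional* SMC sweep with the current state as the retained reference path
draws the next state (particle Gibbs). Because $\sigma \mid (T,b)$ is uniform
over the $e(T,b)$ valid orderings, the sweep's target divides the joint by
$e(T,b)$, computed in closed form from factorials over subtree block counts.
Omitting this factor biases the sampler toward trees with many valid
orderings; the invariance tests in `test-acceptance.R` are the arbiter that
the implemented kernel is exact. Within conditional sweeps the non-reference
particles are resampled multinomially (the provably valid conditional
resampling); unconditional sweeps use systematic resampling, triggered at
ESS below half the particle count.

Two further moves run each iteration, neither changing the node count:
subtree prune-regraft (uniform subtree, Gibbs over reattachment points) and a
node-reassignment scan (each block whose removal would not empty its node is
Gibbs-moved over all nodes and, when outlier modelling is on, the outlier
state). Runs interleave all three; the reported tree is the joint-probability
argmax over the pooled post-burn-in trace. Reference defaults mirror the
benchmark protocol: 4 chains, 100 burn-in, 5000 iterations, 100 particles.

# The synthetic world

`simulate_fscrp` draws exactly from the model's prior (optionally with a
fixed partition, e.g. six equal pre-clusters); `simulate_tssb` draws node
assignments from tree-structured stick breaking (defaults $\gamma = 1$,
$\lambda = 0.5$, no depth decay — unstated upstream; chosen to give a handful
of nodes at 100 SNVs) with Dirichlet prevalences over occupied nodes.
`emit_reads` emits binomial counts for diploid heterozygous mutations
(sequencing error $10^{-3}$, a standard short-read scale). `inject_loss`
removes `round(p N)` mutations from one origin node (uniform among nodes with
enough mutations and a proper descendant), places them on one shared
chromosome, picks the loss node uniformly among the origin's proper
descendants, and sets their effective prevalence to
$\bar\rho_{\text{origin}} - \bar\rho_{\text{loss}}$.

What a green test does and does not establish: the generator matches the
model's own assumptions (diploid-heterozygous, clonal copy number, binomial
noise, ISA except for injected loss). Real data add sub-clonal copy number,
mapping artifacts and overdispersion beyond the beta-binomial; performance
there is not claimed by these tests.

Tests emulate the upstream pre-clustering step (a separate tool, consumed as
input) with an oracle clustering by observed prevalence profile: true node
refined by lost status — what an accurate prevalence-mixture clustering of
the VAFs would return.

# Identifiability of single-origin loss

A lost block's prevalence vector is
$\bar\rho_{\text{origin}} - \bar\rho_{\text{loss}}$. When the loss node is
the origin's only child this equals the origin's clonal mass exactly, so
placing the lost block as a *new child* of the origin reproduces every read
count — the likelihood cannot distinguish loss from a sibling clone, and the
prior difference (one extra node) is far cheaper than the outlier cost,
which scales as the per-mutation-per-sample uniform marginal
($\approx \log\frac{1}{\text{depth}}$ below the peak density). Roughly half
of eligible draws from the forest-CRP loss generator have this geometry, so
the outlier state is provably recovered only in the remaining, genuinely
tree-incompatible draws. The outlier-recall acceptance bound is therefore
not attainable in this stated world; the corresponding acceptance test is
left red with this analysis rather than weakened. Median accuracy still
improves with outlier modelling, because in the incompatible draws the naive
model distorts the whole topology while the outlier model drops the lost
block cleanly.

# Numerical and runtime choices

* Grid size 101 balances the $O(|V|G^2)$ DP cost against quadrature error;
  the refinement test doubles $G$ and bounds the change.
* Acceptance simulations run scaled samplers (1 chain, 10 particles, 50–60
  iterations) and reduced Monte Carlo sizes; each scaling is noted beside
  the test. Posterior-agreement thresholds are unchanged from the criteria.
* All randomness flows through R's RNG; `run_sampler` seeds chain $c$ with
  `seed + c - 1`, so results are bit-reproducible for a given seed
  regardless of scheduling.
* Gibbs menus use log-space proposal probabilities throughout; zero-weight
  trajectories keep $-\infty$ weights rather than producing NaNs.

# Known limitations

Sub-clonal copy number is not modelled (a stated limitation of the emission
model); $\kappa < 1$ is unsupported on the grid; the RRE metric enumerates
topologies only up to 8 clones; pre-clusters are hard constraints (blocks
can merge within a node but never split).
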