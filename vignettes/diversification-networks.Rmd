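---
title: "Estimating diversification parameters from phylogenies with ensemble neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversification parameters from phylogenies with ensemble neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(divnn)
```

## The inference problem

A reconstructed, time-calibrated phylogeny of extant species carries
information about the process that generated it: how fast lineages speciate,
how fast they go extinct, whether diversification slows as a clade fills its
niche space, and whether speciation itself takes time. `divnn` implements a
simulation-based, likelihood-free route to those parameters. Networks are
trained on trees simulated under a known process and then applied to new
trees; a crown-age-conditioned birth--death maximum-likelihood estimator
provides the classical baseline for comparison.

Three diversification scenarios are covered:

* **BD** — constant-rate birth--death with speciation rate $\lambda$ and
  extinction rate $\mu$ (2 parameters).
* **DDD** — diversity-dependent diversification: the per-lineage speciation
  rate declines linearly with standing diversity $n$,
  $\lambda_n = \max(0,\; \lambda_0 - (\lambda_0-\mu_0)\,n/K)$, reaching the
  extinction rate at the clade-level carrying capacity $K$ and zero at
  $K' = K\lambda_0/(\lambda_0-\mu_0)$ (3 parameters).
* **PBD** — protracted birth--death: speciation initiates (creating an
  incipient lineage) and completes at a finite rate. Good species initiate
  at $\lambda_1$ and die at $\mu_1$; incipient lineages initiate at
  $\lambda_3$, complete at $\lambda_2$, and die at $\mu_2$ (5 parameters).

All training trees share a fixed crown age of 10 time units. Because the
simulation is scale-invariant, rates are interchangeable with the time unit;
10 units keeps the sampled rate boxes in a numerically comfortable range.

## Simulators and their conditioning

Trees are simulated by an exact Gillespie algorithm on a lineage table: each
lineage is one edge, born at a branching event (or at the crown) and ended
by speciation, extinction, or the present. Waiting times are exponential in
the summed per-lineage rates and the event lineage is chosen
proportionally. The BD/DDD event loop is compiled code driven by R's RNG,
so `set.seed()` (or the `rng_seed` of `sim_config()`) makes whole tree sets
bit-reproducible.

The training distributions over generating parameters are uniform boxes
with extinction bounds proportional to the drawn speciation rate
($0.9\lambda$ for BD, $\min(0.9\lambda_0, 1.5)$ for DDD, $0.8\lambda$ for
the two PBD extinction rates) and a log10-uniform completion rate
$\lambda_2 \in [10^{-3}, 10]$. Proportional bounds keep whole-clade
extinction rare; the absolute cap of 1.5 keeps event counts bounded.

Reconstructed trees are obtained by pruning all extinct lineages
(`prune_extinct()`), suppressing the degree-2 nodes this creates. A tree is
*conditioned on survival of both crown lineages*: if either basal lineage
leaves no extant descendant, the realisation is flagged rejected and, in
batch simulation (`sim_trees()`), replaced by a fresh draw under the same
parameter vector. The delivered parameter distribution is therefore the
training box conditioned on crown survival, which is also the conditioning
the likelihood uses. For PBD, the species tree keeps one representative
extant lineage per species, chosen uniformly at random among conspecific
lineages (an incipient lineage belongs to its parent's species until its
own completion, at which point it founds a new species).

Reconstructed trees with fewer than 5 or more than 3000 total nodes are
removed by `filter_trees()`: three tips are the minimum for which all
encodings are defined, and the upper bound caps the size of graph tensors.

## Encodings

`encode_dataset()` produces the three views consumed by the networks:

1. **Graph tensor** (`phylo_to_graph()`): a directed edge index (2 × m,
   parent over child, m = N − 1) and an N × 3 node-feature matrix holding
   each node's distance to its ancestor and to its two descendants, zeros
   where a neighbour does not exist. Node numbering follows the `ape`
   convention (tips first, root, then internal nodes), which makes the
   encoding deterministic; message passing and pooling make the network
   itself invariant to any renumbering.
2. **Branching times** (`branching_times()`): the n − 1 internal-node ages,
   ordered past to present so the crown age comes first. The recurrent
   model consumes a consistent temporal direction; the direction itself is
   a convention and order sensitivity is part of the test suite.
3. **54 summary statistics** (`tree_summary_stats()`): a fixed, named set
   drawn from the standard families — size and scale, branch-length
   moments for all/external/internal branches, branching-time moments,
   lineage-through-time slopes and the Pybus--Harvey gamma, imbalance
   (Colless, Sackin, cherries, pitchforks, ladders, "stairs"), tip-depth
   dispersion. The exact membership of such statistic sets varies across
   studies; this set fixes the 54-dimensional input contract, is
   label-invariant, and is finite for every bifurcating tree with at least
   three tips (standard deviations of single-element sets are defined as
   zero, ratios are guarded against zero denominators). Parameter recovery
   through the dense network depends on this concrete list, so its names
   are frozen in `SUMMARY_STAT_NAMES`.

No feature scaling happens at encoding time; standardisation of summary
statistics and targets is a training-time transform whose constants are
stored in the fitted model.

## Architectures

All three models regress the scenario's parameter vector. The carrying
capacity $K$ and the completion rate $\lambda_2$ are learned on the natural
log scale (they span orders of magnitude) and exponentiated at readout;
targets are additionally standardised with training-split statistics so the
Huber loss acts on comparable scales.

* **DNN** (`build_dnn()`): five linear layers, each followed by batch
  normalisation and GELU; the outputs of all five layers are concatenated
  into a single linear readout. Default width 64.
* **LSTM** (`build_lstm()`): five stacked LSTM layers over the
  branching-time sequence; the final hidden state passes through a
  GELU-activated linear layer and a linear readout. Sequences in a batch
  are padded and masked — a finished sequence carries its state through
  unchanged, so padding provably cannot affect the output. Default hidden
  size 32; forget-gate biases start at 1.
* **GNN** (`build_gnn()`): five GraphSAGE-style modules of two
  mean-aggregation operators each (operator outputs concatenated within a
  module, each operator followed by normalisation and GELU). Two
  differentiable-pooling (DiffPool) coarsenings assign nodes softly to 8
  and then 4 clusters and contribute link-prediction and assignment-entropy
  auxiliary losses; a final module, global mean pooling, and a two-layer
  readout (GELU after the first layer only) emit the predictions. Two
  operators per module are used throughout: deeper message passing on
  tree-shaped graphs oversmooths and destabilised training in our
  experiments, consistent with the known over-smoothing/over-squashing
  trade-off of deep graph networks.

Design notes on genuinely open points:

* *Cluster counts.* Soft assignment matrices require a fixed number of
  output clusters per level for the weights to be shared across graphs, so
  the cluster counts are per-model constants (defaults 8 and 4) rather
  than a function of tree size; both are exposed in the constructor.
* *Normalisation in the graph network.* The operators normalise each
  feature over the **nodes of the current graph**, at training and at
  inference alike (graph-instance normalisation). Classic batch
  normalisation with frozen running statistics behaves erratically here
  because node-feature distributions shift strongly with tree size, making
  inference-time behaviour diverge from training; per-graph statistics keep
  the two identical, keep predictions deterministic and batch-size
  independent, and preserve permutation invariance. The dense network, whose
  batch rows are i.i.d. trees, keeps classic batch normalisation with
  running statistics (momentum 0.1, frozen at inference).
* *DiffPool auxiliary losses.* The link-prediction term is the Frobenius
  norm of $A - SS^\top$ divided by the number of adjacency entries, the
  scaling used by the reference DiffPool implementation; the entropy term
  is the mean row entropy of the assignment. Both levels contribute, with
  a single weight (`aux_weight`, default 1).

The numerical core is a small reverse-mode autodiff tape (C++/Armadillo)
whose every operator carries its adjoint; all gradients are verified
against central finite differences in the test suite at tolerance 1e-4.

## Training

`fit_model()` shuffles and splits the dataset once (default 90/10), then
runs mini-batch AdamW (defaults: learning rate 1e-3, betas 0.9/0.999,
weight decay 0.01) on the total loss: the Huber penalty (delta 1 on the
standardised target scale) plus the weighted auxiliary terms where the
model provides them. Batches default to 64 trees; for sequence models an
additional token cap (`max_tokens`) shrinks batches of very long
branching-time series, bounding backpropagation memory, and batches are
bucketed by sequence length so padding stays small. Per-epoch training
loss, validation loss and per-parameter validation MAE (natural scale) are
recorded; `diagnose_fit()` flags the canonical overfitting (training falls
while validation rises) and underfitting (both high, declining in
parallel) shapes. Early stopping is off; training runs its configured
length and, by default, the weights of the best-validation epoch are
restored (`keep_best`). Runs are bit-reproducible from `rng_seed` under
single-threaded execution.

At initialisation the networks predict near the training-mean — equivalent
to the mid-range constant predictor — which is also their fallback when
the input carries little signal; recovery claims are therefore always made
*against* that baseline, not against zero error. A capacity note: the
dense and graph networks memorise a 50-tree fixture to below 1% of their
epoch-1 loss within 200 epochs, while the five-layer recurrent stack
optimises much more slowly on whole-sequence regression (about an order of
magnitude over 600 epochs); this slow optimisation of sequence models is a
known practical limitation, not a defect of the gradient computation
(which is finite-difference-verified).

## Ensembles

* **Bagging** (`bag_predictions()`): element-wise mean/median/max/min over
  independently trained learners; the median is the default, the others
  are markedly less accurate in practice.
* **Stacking** (`build_stack()`): the three base architectures without
  their readouts feed their concatenated penultimate features (graph
  representation, dense features, recurrent features) into a single linear
  meta-learner; all four components train jointly through one tape. The
  meta-learner depth is exposed implicitly through its single linear form;
  experiments with deeper meta-learners did not change the picture at desk
  scale.
* **Boosting** (`boost_fit()`): the graph network makes the initial
  prediction; correctors are then trained sequentially on residuals, each
  from its own view of the same trees — a dense network on summary
  statistics ("SS") or an LSTM on branching times ("BT"). Residuals are
  defined as truth − prediction on the network output scale and corrections
  are *added*, so perfect correctors recover the truth exactly; this is the
  same composition as subtracting prediction − truth residual terms, with
  the sign convention fixed and tested (zero correctors reproduce the base
  bit-exactly, staged contributions sum exactly to the final prediction,
  truncating Boost SS+BT after one stage equals Boost SS). Corrections are
  learned on the log scale for $K$ and $\lambda_2$ so they stay additive.

## The maximum-likelihood baseline

`bd_loglik()` evaluates the reconstructed-process constant-rate
birth--death likelihood of the branching times, conditioned on the crown
age and (by default, matching the simulator's acceptance rule) on survival
of both crown lineages; the conditioning is switchable. The implementation
is the closed-form product of per-edge propagators
$g(t) = e^{-rt}/(\lambda-\mu e^{-rt})^2$ with one factor $\lambda$ per
non-root branching, written via `expm1` so the near-critical limit
$\lambda \to \mu$ stays accurate; labelling constants are omitted. It is
verified to 1e-6 against an independent lineage-probability ODE oracle.

`bd_mle()` maximises this likelihood by Nelder--Mead simplex over
$(\log\lambda,\ \mathrm{logit}(\mu/\lambda))$, which enforces
$0 \le \mu < \lambda$ without constraint handling (relative tolerance
1e-8, at most 2000 evaluations). Two starting protocols mirror the two
benchmark regimes: `"best"` starts at the true parameters (an upper bound
on real-world performance), `"naive"` at a random point of the training
box. Optimisation failures are data (`converged = FALSE`), never errors.
Likelihood estimators for the diversity-dependent and protracted models
are not implemented; `register_estimator()` lets external implementations
participate in every evaluation protocol on the same footing.

## Evaluation protocols

Residual analysis (`residual_table()`) works on truth − estimate residuals
joined with the size class of the tree (`size_bin()`: small < 200 nodes,
medium 200–500, large > 500, counting root + internal + tips); extreme
estimates can be excluded from MAE summaries by an explicit threshold, off
by default, with excluded counts always reported. The strength of the
diversity feedback is summarised by `cc_effect()` $= (\lambda-\mu)/K$.
`robustness_grid()` repeats identical parameter combinations (default: the
full 80-cell factorial $\lambda \in \{1,\dots,3\}$,
$\mu \in \{0.2,\dots,0.8\}$, $K \in \{200,\dots,800\}$ with 1000 trees per
cell) and reports per-cell MAE per method, with seeded subsampling for
expensive estimators. For misspecification analysis — applying
diversity-dependent estimators to constant-rate trees, where the true
$K = \infty$ — `expected_nodes()` gives
$\mathbb{E}[N_{nodes}(t)] = 2e^{(\lambda-\mu)t} - 1$ and
`misspec_classify()` places a $\hat K$ against the tree's node count into
left-closed bands $[2N,5N)$, $[5N,20N)$, $[20N,\infty)$, exactly infinite,
or below $2N$ (made explicit rather than silently dropped).

Empirical trees are prepared by `prepare_empirical()`: branch lengths are
rescaled so the crown age matches the training value (estimates are then
on the rescaled time axis) and, when ultrametricity fails within
tolerance — typically branch-length precision noise — every tip branch is
extended so all tips end exactly at the present.

Uncertainty comes from a parametric bootstrap
(`bootstrap_uncertainty()`): simulate under the point estimates (default
1000 trees), re-estimate each, and summarise the empirical distributions.

Composite parameters (`composite_params()`) are often better identified
than the raw rates: net diversification $\lambda-\mu$ and the
extinction-to-speciation ratio $\mu/\lambda$ for BD/DDD, and the mean
duration of speciation for PBD. The duration closed form,
$\tau = \frac{2}{D-\varphi}\log\frac{2D}{D+\varphi}$ with
$\varphi = \lambda_2-\lambda_3+\mu_2$ and
$D = \sqrt{(\lambda_2+\lambda_3)^2 + 2(\lambda_2-\lambda_3)\mu_2 + \mu_2^2}$,
was validated against a stochastic first-completion simulation and
numerical integration of the duration density before being frozen into the
tests; it reduces to $1/\lambda_2$ without branching and extinction and
vanishes as completion becomes instantaneous.

## What the generator does and does not emulate

The synthetic trees embody the study conditions: fixed crown age,
complete extant sampling, the three generating processes above, and
conditioning on crown survival. Real phylogenies additionally carry
incomplete and non-random sampling, dating error, rate heterogeneity
across clades and time, and model misspecification beyond the three
scenarios. Passing tests therefore demonstrate that the estimators recover
parameters *of these processes under these conditions*; on empirical trees
the appropriate reading is comparative (networks versus likelihood, and
bootstrap spread), not absolute.

## Problem sizes used by the checks

The test-suite and the acceptance script run at desk scale, chosen so the
whole battery completes on one CPU core: recovery uses 2000–3000 trees
per scenario with width-16 graph networks (8–25 epochs) and hidden-16
correctors (4–5 epochs); simulator means use 10,000 replicates;
distributional comparisons 1500 per arm; the likelihood oracle 20
parameter points on 10 trees; the reduced robustness grid 4 cells × 50
trees; bootstrap calibration 50 trials × 100 bootstrap trees. Full-scale
studies (100,000 trees per scenario, wide networks, long training) use
the same code paths with larger configuration values.

## Known limitations

* Only the constant-rate birth--death likelihood ships; DDD and PBD
  likelihoods must be plugged in externally.
* The 54-statistic list is a documented stand-in for a supplementary-only
  specification; dense-network results depend on it.
* The recurrent stack under-optimises relative to its capacity at desk
  scale (see Training).
* The protracted parameters are only weakly identified by species trees;
  this is a property of the inference problem — the mean duration of
  speciation is the recommended summary.
* No fossil, sampling-fraction, time-varying-rate or trait-dependent
  models.
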