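---
title: "Biophysics-pretrained protein language models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysics-pretrained protein language models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`biophyslm` implements a transfer-learning workflow for protein engineering:
a small transformer encoder is first *pretrained* to predict dozens of
simulated biophysical score terms for sequence variants of a base protein,
and the resulting backbone is then *finetuned* (or used as a frozen feature
extractor) on a handful of experimental sequence–function measurements from
deep mutational scanning (DMS) assays. Around that core the package
provides the full supporting workflow: variant parsing and generation,
contact-graph construction from structures, a seeded synthetic biophysics
simulator that stands in for a molecular-mechanics scoring pipeline,
robust preprocessing, replicated benchmark splits, epistasis scoring, and
simulated-annealing sequence design.

Everything runs at desk scale on one CPU. The neural network — forward pass
and backpropagation — is implemented directly in RcppArmadillo; gradients
are verified against finite differences in the test suite rather than
trusted by construction.

# The model

## Encoder

The encoder follows the original transformer with two deliberate changes:

* **pre-layer normalization** (each sublayer normalizes its input rather
  than its output), which stabilizes training of small models without a
  warmup-sensitive output scale;
* **relative position embeddings (RPE)** in place of the sinusoidal
  absolute encoding: learnable key and value vectors indexed by the
  relative distance between two positions, added to the attention keys and
  values. The tables are per layer and shared across heads, the convention
  of Shaw et al.'s formulation.

No absolute positional signal exists anywhere: with the RPE tables zeroed,
the model is a pure bag-of-residues encoder. This is asserted as a test
(`1d` and `3d` models with identical remaining weights produce identical
outputs once their RPE tables are zeroed).

Relative distances come in two flavours:

* **1D**: the signed sequence offset `j - i`, clipped to ±8, giving 17
  distance classes. Precise offsets beyond ±8 are unlikely to be
  informative, and clipping bounds the table size.
* **3D**: the shortest-path length between residues i and j in the contact
  graph, where residues are connected when their beta-carbons (alpha-carbon
  for glycine or any residue without a beta-carbon) lie within 8 Å,
  inclusive. Distances are clipped at 3: 0 is self, 1 a direct contact,
  2 a second-degree neighbour, and 3 everything else — including pairs in
  disconnected components, which simply fall into the catch-all class.

After the encoder: a final layer normalization, mean pooling over residues,
one ReLU fully-connected layer, and a linear output with one node per
pretraining task (55 score terms, or 72 when binding terms are enabled).
Three presets reproduce the published model sizes — `local`
(256/3 layers/4 heads/1024 ff, ~2.5M parameters), `global`
(512/6/8/2048, ~19.2M) and `global_xl` (`global` with 16 layers, ~50.8M).
The vocabulary is the 20 canonical amino acids plus one padding token;
stop-codon variants are removed upstream, so no stop or mask token exists.

A note on the middle preset: the exact parameter total of the `global`
architecture as printed (including Shaw-style per-layer RPE tables of
head-dimension width) is 19,230,007. We report it as computed; coarser
descriptions of this architecture sometimes round it up to 20M.

## Target models

A target model reuses the pretrained backbone and replaces the multi-task
output with a randomly initialized linear head behind a dropout layer
(rate 0.5). For `local`-style models the head attaches after the final
fully-connected layer; for `global`-style models directly after pooling —
the global fully-connected layer is specific to the pretraining tasks,
whereas a local model's is part of its protein-specific representation.

Two training strategies are provided:

* **dual-phase finetuning**: 250 epochs of head-only training with the
  backbone frozen (asserted bit-identical in tests), then 250 epochs of
  full-network training at one tenth of the learning rate; each phase uses
  linear warmup (1% of steps) and cosine decay to zero. Model selection
  takes the epoch with the lowest validation loss — across both phases —
  but only when the validation set has at least 32 examples (128 for
  global-style models); smaller validation sets are too noisy to select
  on, and the last epoch is returned instead.
* **ridge feature extraction**: the backbone's features are frozen and the
  head is the closed-form ridge solution `(XᵀX + αI)⁻¹Xᵀy` with α = 1 and
  an unpenalized intercept, solved via Cholesky factorization and tested
  against a direct normal-equations solve at 1e-8.

## Optimization

Pretraining minimizes the *sum over tasks* of the per-task batch MSE — not
the grand mean — so each score term contributes a full unit of gradient
regardless of how many tasks there are; this is why the tables must be
standardized first (the trainer rejects tables whose training rows are far
from mean 0, sd 1). AdamW is used throughout with β = (0.9, 0.999),
ε = 1e-8, decoupled weight decay (0.01 pretraining, 0.1 finetuning,
applied to all tensors), gradient-norm clipping at 0.5, and linear warmup
over 2% of pretraining steps starting from a rate of exactly 0. Every batch
holds variants of a single base structure, so the relative-distance map is
constant within a batch; multi-protein tables are handled by a per-protein
batch sampler whose batches jointly cover each epoch exactly once.
Large effective batch sizes are reproduced on one process by gradient
accumulation; tests assert that chunked and unchunked gradients agree to
floating-point tolerance.

# The synthetic simulator

The simulator exists so that every downstream stage can be tested against
a *known* ground truth without external structures, scoring software, or
GPUs. It emulates the interface of a molecular-mechanics pipeline — named
score-term vectors per variant — not its physics.

A toy structure is either a straight 3.8 Å chain or a "globule": residues
packed uniformly into a sphere whose radius scales as the cube root of the
length (protein-like constant density), with a 3.8 Å exclusion distance.
The sphere radius is chosen so the mean contact degree sits near 6 before
edge effects; measured over seeds and lengths 20–100 it stays within 2–10.

Each sequence has energy

$$E(a) = \sum_i \big[h(a_i) + b(a_i)\,\mathrm{deg}_i\big]
       + \sum_{(i,j) \in \mathrm{edges}} J(a_i, a_j),$$

with per-amino-acid field energies `h`, burial weights `b` multiplied by
contact-graph degree (a burial proxy), and a symmetric pair-interaction
table `J` evaluated on contact edges. All tables are drawn once from
seeded standard normals; there are no hand-tuned constants. The three
energy components (field, burial, pair) are mixed into each of the 60
named score terms through a row-normalized random mixing matrix plus
optional Gaussian observation noise; `total_score` is the plain component
sum. Five catalog terms are engineered to be degenerate (constant residue
count, zero chain-break and disulfide terms, duplicated aggregate) so the
preprocessing exclusions operate on meaningful input. Seventeen optional
binding terms are computed analogously from interface-restricted analogues
of `h` and `J` over edges touching a designated interface residue set.

Two properties make the simulator a useful oracle:

* with `J = 0` the energy is exactly additive over substitutions, so
  epistasis is identically zero;
* with `J` active, epistasis arises *only* at contacting position pairs —
  and the `coupled_pairs` option restricts the interaction to chosen
  edges, letting tests plant a single coupling and demand that positional
  epistasis finds exactly it.

Synthetic experimental datasets assign latent fitness `-E` (lower energy =
fitter), optionally through a monotone sigmoid link, add Gaussian assay
noise, normalize so the wild type scores exactly 0, and round to 7 decimal
places — the same contract the preprocessing applies to real tables.

What the simulator does **not** emulate: real energy-term covariance
structure, length-dependent scaling, structural relaxation, multi-chain
binding partners, or measurement artefacts beyond the injected
NaN/duplicate/outlier faults. Passing tests therefore demonstrate that the
machinery is correct on a landscape with known structure, not that any
particular accuracy will be reached on real assay data.

# Preprocessing

Raw attribute tables are cleaned in a fixed order: rows with NaN in any
score column are dropped; duplicates per (structure, variant) are resolved
by a seeded random lottery keeping exactly one row; then, per base
structure, the modified z-score of `total_score`,

$$s_i = \frac{|x_i - \tilde{x}|}{\mathrm{MAD}},$$

flags rows with `s_i > 6.5` for removal, where x̃ is the group median and
MAD the median of absolute deviations from it. Two numerical decisions are
worth stating: the numerator is taken in **absolute value** (a signed
numerator would never flag low-side outliers, and the MAD itself is
defined from absolute deviations), and **no 0.6745 consistency constant**
is applied — the threshold is calibrated to the plain ratio. Groups with
MAD = 0 skip outlier removal with a warning, since the score is undefined
there. Filtering uses `total_score` only, never the other terms.

Standardization subtracts the mean and divides by the standard deviation
per (structure, term), with statistics computed on **training rows only**
and reused for held-out rows; statistics are never pooled across base
structures. Constant terms (sd = 0) are centered but not rescaled.

Experimental tables are normalized by removing stop-codon variants,
converting indexing to 0-based (parsers take an explicit `offset` because
published variant strings are usually 1-based), log-transforming where the
scores are not already on a log scale, subtracting the wild-type score,
and rounding to 7 decimals.

# Splits and evaluation

Small-training-size benchmarks share one global 10% test set across all
dataset sizes (10 to 20480 by doubling) and replicates
(101, 23, 11, 11, 11, 11, 7, 7, 5, 5, 3, 3 — many replicates at small
sizes where sampling luck dominates); each sampled set splits 80/20 into
train/validation. Four extrapolation constructions probe generalization:
by held-out **positions**, held-out **mutations** (variants straddling
train- and test-designated units are discarded outright), mutation-count
**regime** (singles to doubles, or singles-and-doubles to triples-and-up),
and **score** (below wild type to above wild type; exact zeros belong to
neither pool). Position, mutation and score splits first resample datasets
above 50,000 rows down to 50,000. Regime extrapolation samples a 10% test
set from its test pool while the others use the full pool — an asymmetry
kept as specified. Nine replicates per construction is the default.

Metrics are Spearman correlation and top-k recall (k = 100 by default),
with ties broken by stable index order; recall is invariant to monotone
transforms of the predictions. Constant true scores yield NA with a
warning rather than an arbitrary number.

Epistasis for a variant S is `E(S) = w(S) - Σ w(m)` over its constituent
single mutations, where `w` is the score effect relative to wild type;
positional epistasis is the mean |E| over variants with mutations exactly
at a given position pair.

# Sequence design

Simulated annealing maximizes any scoring function over variants with an
exact mutation count under an Observed/Unobserved constraint on
(position, amino acid) substitutions. The temperature follows a
logarithmic gradient from 10 down to 0.01; proposals draw the number of
mutations to change from a Poisson distribution (rate 1 by default —
small steps dominate near convergence; the rate is configurable since the
choice is heuristic), keep a random subset of current mutations, and
refill at unused positions from the constraint-legal set. Improvements
and neutral moves are always accepted (`exp(0/T) = 1`); worsenings with
probability `exp(Δ/T)`.

Candidate selection clusters the run endpoints (final states — one design
per run; best-seen states are also returned for inspection) with
complete-linkage agglomerative clustering under a BLOSUM62-derived
dissimilarity `d(x,y) = Σ (B(a,a) + B(b,b) - 2B(a,b))/2`, chosen because
it is nonnegative, symmetric and zero exactly for identical sequences —
a raw negated similarity, which lacks those properties, is available
behind a flag. Clusters below 100 members (or a configurable fraction of
runs) are dropped; each survivor is represented by its medoid (lowest mean
within-cluster distance); selection starts from the largest cluster and
greedily adds the cluster whose representative is farthest on average from
those already selected, prioritizing diversity on the rationale that broad
basins of repeated convergence tolerate more model error.

# Problem sizes used in tests

The test and acceptance suites run the full pipeline end to end on
deliberately small instances chosen as the smallest that exercise each
claim: a length-20 globular toy protein, 2,000 noiseless pretraining
variants, a mini encoder (embedding 32, 2 layers, 2 heads), 30 pretraining
epochs, and 100+100-epoch dual-phase finetuning on 64 examples with 500
held-out variants; design tests use a length-8 protein where the
2-mutation optimum is enumerable. The low-N transfer comparison is
repeated over 5 dataset/seed replicates and asserted as a majority
outcome (at least 4 of 5), since individual replicates share the
stochasticity of real finetuning.

# Known limitations

* The simulator's score terms are linear mixtures of three energy
  components; real score terms are many nonlinear functionals of
  structure. Multi-task pretraining here is therefore easier than in
  practice.
* Single-process training only; distributed data parallelism is mimicked
  by gradient accumulation, not implemented.
* Checkpoints are R serializations: reload-equivalent on one platform,
  not guaranteed bit-identical across platforms.
* `load_structure` requires complete single-chain standard-residue PDB
  inputs; missing residues are an error, not a remodeling trigger.
* Indexing: variant positions are 0-based everywhere (strings and parsed
  objects); R matrices remain 1-based, so position p corresponds to row
  p + 1.
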