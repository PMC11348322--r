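---
title: "Scoring protein co-condensation with a pair-representation transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein co-condensation with a pair-representation transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Membraneless organelles — nucleoli, P-bodies, stress granules — form by
protein phase separation (PPS): sets of proteins demix from the nucleoplasm
or cytosol into liquid-like condensates. Which proteins end up in the *same*
condensate is only partially catalogued, and single-protein phase-separation
predictors say nothing about the pairing. `codroplet` scores the
**co-condensation propensity of a protein pair**: the probability that two
proteins partition into a common condensate.

The model consumes AlphaFold2-style residue representations rather than raw
sequence, on the premise that conformational information (including for
disordered regions) carries much of the signal that drives condensation.
Each protein brings three arrays:

* a single-sequence representation `f_msa` (`L x 384`), the linear
  projection of the first MSA row produced by the Evoformer trunk;
* a pair representation `f_pair` (`L x L x 128`), the Evoformer's
  inter-residue feature tensor;
* a structure representation `f_struc` (`L x 384`) from the final structure
  module layer.

Running AlphaFold2 itself (and its sequence-database searches) is outside
the package's scope: the package defines an adapter contract (the
`feature_bundle`) for externally computed arrays, plus a surrogate
generator used for all desk-scale training and validation (below).

## Architecture

Each protein is encoded independently, the two encodings are merged into
one two-chain residue graph, and an eight-layer transformer with pair-bias
attention exchanges information between the chains before a pooled head
emits the probability.

**Transition block.** Layer normalisation followed by a two-layer MLP with
ReLU whose hidden width is `n_expand = 4` times the input channel count.
The canonical block is dimension-preserving; the encoder also uses it as a
re-projection, in which case the second linear targets the new channel
count. This resolves the tension between the block's dimension-invariant
definition and its use with changed output dimensions at encoding time in
the minimal way consistent with both.

**Protein encoder.** `f_msa` and `f_struc` each pass through a transition
block followed by layer normalisation, are concatenated residue-wise
(768 channels) and re-projected by a transition block to the node dimension
`c_n = 256`. `f_pair` passes through a transition block and layer
normalisation and is re-projected to `c_e - 1 = 31` edge channels. The
pseudocode's pair-branch line is garbled in its published form; we apply
the same `LayerNorm(Transition(.))` composition as the two residue
branches, which is the only reading that treats the three inputs uniformly.

**Combination.** Residues of the two chains are concatenated
(`N = L_A + L_B`); intra-chain edge blocks carry the 31 encoded channels,
inter-chain residue pairs are padded with zeros there, and the reserved
32nd channel holds the binary relative positional encoding: 1 when the two
residues belong to different chains. A homodimer (a protein paired with
itself) still marks the two copies as different chains — the indicator
encodes chain membership, not sequence identity.

**Gated self-attention with pair bias.** Per head `h`, queries, keys and
values come from the layer-normalised nodes (no bias terms), a scalar
pair bias `b_ij` comes from the layer-normalised edges, and a sigmoid gate
from the nodes. Raw logits are `q_i . k_j / sqrt(c_n / N_head)`. Two
outputs leave the block:

* the **edge update** is computed from the *pre-bias, pre-softmax* logits:
  the per-head logits are concatenated and passed through a two-layer MLP.
  The published pseudocode computes the edge output one line before the
  bias is added, and we implement exactly that, although the AlphaFold2
  convention would bias first; fidelity to the stated algorithm wins.
  The MLP's hidden width is unspecified; we use `c_e`.
* the **node update** softmaxes `logits + bias` over partners `j`,
  aggregates values, gates them per head and mixes heads linearly.

**Transformer stack.** Eight blocks; each adds the attention output to
nodes and edges through dropout, then adds a node transition (applied to
layer-normalised nodes) and an edge transition residually, each through
dropout. The stated block applies layer normalisation before a transition
that itself begins with layer normalisation; we keep the double
normalisation as written.

**Prediction head.** Per residue: layer norm, dropout, a two-layer MLP;
mean pooling over *all* residues of the complex yields the whole-complex
representation; a three-layer MLP with sigmoid emits the probability. The
published head signature is ambiguous about whether the two proteins are
pooled separately; we pool the combined residues together, the reading
consistent with the single mean in its pooling step. Hidden widths of the
output MLP (64, 32) are unspecified in the source material and are
configurable.

**Loss.** Binary cross-entropy, plus an L2 penalty `lambda * sum(W^2)`
over weight matrices (biases and layer-norm gains are not decayed;
decaying offsets fights the normalisation for no regularising benefit).

**Symmetrization.** Whether the published score is order-free is not
stated. A co-condensation propensity is physically order-free, so
`predict_pair()` defaults to averaging the two chain orders
(`symmetrize = TRUE`), with a flag to disable.

## Dataset construction

From a condensate membership table (CD-CODE-like TSV):

* **Positives**: all unordered member pairs of every condensate with at
  most `n_max = 50` members (components of larger condensates are the
  least reliable annotations). Pairs shared by several condensates are
  deduplicated with their source condensates unioned.
* **Negatives**: all pairs of proteins drawn from condensates with at most
  `m = 12` members that co-occur in *no* condensate of the full table.
  `m = 12` is the published operating point; a figure caption elsewhere
  reports `m = 5` for one experiment, so `m` is exposed as a flag rather
  than hard-coded.
* **Self-pair expansion**: `(P, P)` positives for every condensate
  protein; negative self-pairs from proteins outside every condensate
  *and* without a direct protein-protein interaction edge to any
  condensate protein (interaction neighbours are likely false negatives).
  Both pools pass a greedy 50% sequence-identity filter (longest-first;
  global Needleman–Wunsch identity = matches / alignment length via
  `Biostrings::pairwiseAlignment`; the comparator is pluggable because the
  original filtering tool is unnamed). Whether self-pairs join the initial
  training or a continuation phase is not fully specified; the trainer
  supports continuation training from a checkpoint for this purpose.
* **Length filter**: proteins longer than 1,024 residues are excluded
  (not truncated); the boundary is inclusive.
* **Condensate-aware split**: condensates are shuffled and assigned to the
  training side until its share of positive pairs reaches the 0.8 target.
  A positive pair enters a side only if *all* its source condensates sit
  on that side; straddling pairs are dropped rather than assigned, because
  assigning them would let `(b, c)` reach the test set while `(a, b)` and
  `(a, c)` from the same condensate trained the model. Negatives split at
  the same fraction without a condensate constraint.
* **Rebalancing**: the minority class is oversampled with replacement to
  exact parity, re-drawn each epoch.

## Training and evaluation

Minibatches of 4 pairs; per-batch mean gradients; an Adam-style optimiser
(`beta1 = 0.9`, `beta2 = 0.999`); 40 epochs by default with a 20-epoch
continuation convention for expanded datasets. The published training
procedure names only "gradient of the loss"; Adam is this package's
choice, standard for the model family. The default learning rate is 1e-4,
configurable; `cross_validate()` selects hyperparameters by
condensate-disjoint k-fold AUC. Dropout rates (attention, transition,
head) default to 0.1 — unstated in the source, common transformer
practice. All randomness (initialisation, rebalancing, shuffling, dropout)
derives from one integer seed; evaluation mode is deterministic.

Evaluation thresholds scores at 0.5 (configurable) for the confusion
matrix and reports accuracy, precision, recall, F1, MCC and the ROC curve
swept over all distinct scores with trapezoidal AUC (equal to the
normalised Mann–Whitney statistic, which the tests assert). Ratios of the
form 0/0 are reported as `NaN` and flagged, never silently zeroed.

## The surrogate feature generator

Desk-scale work cannot run AlphaFold2, so the package generates surrogate
bundles with a *planted pairwise-compatibility structure*:

* every protein carries a latent compatibility vector (`d_lat = 8`);
  proteins in the same synthetic condensate (cluster) share it;
* `f_msa` and `f_struc` embed one-hot residue identity plus the latent
  vector through fixed random projection bases derived from the dataset
  seed (so all proteins share bases, and with zero noise the latent vector
  is exactly linearly decodable from the residue-mean of `f_msa` — a
  property the tests verify with a least-squares probe);
* `f_pair` is built from outer products of per-residue embeddings, giving
  the pair-bias attention genuine pairwise structure to exploit, analogous
  in role to Evoformer pair output;
* Gaussian noise (`noise_sd = 0.1` by default) is added with a per-protein
  seed, making every bundle a deterministic function of
  `(sequence, profile, seed)`.

The generator emulates the *shapes*, the planted compatibility signal and
per-protein determinism of real AlphaFold2 features. It does **not**
emulate their statistics: no coevolutionary structure, no realistic
inter-residue geometry, no length-dependent feature drift. A model that
recovers planted labels here demonstrably has a working signal path from
features through attention to the head — nothing more. Passing these
checks says the machinery is correct, not that real-data accuracy would be
reproduced; the published real-data metrics additionally require the
curated condensate data, genuine AlphaFold2 features and the original
trained weights.

## The planted recovery experiment

`surrogate_experiment()` is the package's end-to-end validation: 60
proteins in two latent clusters, lengths 6–10, 200 balanced pairs
(within-cluster positives, cross-cluster negatives), a random 80/20
pair-level holdout, 20 epochs at batch size 4, and a label-permutation
negative control (20 permutations of the trained scores, mean AUC).

Two protocol choices deserve a note:

* **Pair-level holdout.** With two planted clusters, a condensate-disjoint
  split would put one entire cluster in the test set, making the task
  unidentifiable by construction (the training data would contain no
  positive example of the held-out cluster's latent vector). The
  condensate-disjoint protocol is the right one for real condensate data
  and is implemented and tested in `split_by_condensate()`; the recovery
  experiment asks a different question — can the architecture learn the
  planted equality structure at all — and uses a pair-level holdout.
* **Learning rate.** The label is an equality test on the latent vectors,
  which mean pooling alone cannot linearly separate; the network must use
  attention, and gradient descent can stall in the constant-output
  optimum (predicting the base rate) if the step size is wrong for the
  model width. No learning rate is stated in the source material, and
  hyperparameter selection on the training task is part of the published
  procedure; the experiment's schedule (3e-4) was chosen by a pilot
  learning-rate scan on the surrogate training task and then fixed.
  `train_config()` itself keeps the conservative 1e-4 default.

Problem sizes throughout the test suite (tiny channel counts for oracle
comparisons, 60 proteins / 200 pairs / 20 epochs for recovery) were chosen
so the whole validation runs on a single CPU in minutes while still
exercising the full-size architecture where it matters.

## Numerical choices and degenerate inputs

* Layer normalisation uses `eps = 1e-5` inside the square root.
* Weights initialise as Gaussians with standard deviation
  `1/sqrt(fan_in)`; biases and layer-norm offsets at zero, gains at one.
* Cross-entropy is clamped with `eps = 1e-12` inside the logarithms.
* Softmax subtracts the row maximum before exponentiation.
* A single-residue chain is legal everywhere (a softmax row of one is 1).
* Canonical pair order is lexicographic; deduplication and score lookup
  are order-free.
* Ties in quintile ranking break by protein id, making the partition
  deterministic.
* A single-class evaluation set yields `auc = NA` with an explanatory
  error field; threshold metrics are still reported.

## Limitations

* The surrogate generator's simplicity means desk-scale results are a
  mechanism check, not a performance claim (see above).
* Only two-chain complexes are supported; no multi-protein condensate
  stoichiometry.
* The sequence-identity filter is quadratic in the pool size; for large
  pools substitute a clustering comparator through the pluggable
  interface.
* Checkpoints store parameters as an R serialization with a JSON
  architecture header; they are not interchangeable with other runtimes.
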