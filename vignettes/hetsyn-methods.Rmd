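---
title: "Multi-task heterogeneous-network learning for drug synergy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task heterogeneous-network learning for drug synergy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetsyn)
```

## The problem

Anticancer drug combinations are screened on cell-line panels and scored
with synergy metrics (Loewe, Bliss, HSA, ZIP) that quantify how much the
pair's joint effect exceeds a null model of non-interaction. Predicting
these scores for untested drug–drug–cell-line triples is a regression
problem whose hardest part is representing *how* two drugs interact
mechanistically. `hetsyn` couples that regression with a second, auxiliary
supervision signal: binary adverse-effect (AE) labels observed for drug
pairs. The working hypothesis is that therapeutic synergy and
polypharmacy adverse effects share mechanisms of action — overlapping
targets and downstream protein networks — so learning both tasks with a
shared encoder injects mechanism information into the synergy predictor
that the synergy labels alone, which are few and noisy, do not provide.

## The model

### Heterogeneous network and meta-paths

Drugs and protein targets form a typed graph with three binary relations:
drug–target interactions (DTI), protein–protein interactions (PPI), and
drug–drug therapeutic-effect (DD) edges obtained by thresholding observed
synergy scores (strictly positive synergy ⇒ edge, by default). Mechanisms
are represented by meta-path instances — concrete node sequences that
follow one of four schemas ending at the drug being encoded:

| schema | pattern | meaning |
|--------|---------|---------|
| DTD    | drug–target–drug | the two drugs share a target |
| DTTD   | drug–target–target–drug | their targets interact |
| DTTTD  | drug–target–target–target–drug | their targets are bridged by a third protein |
| DD     | drug–drug | a direct therapeutic-effect relationship |

Length-5 paths grow combinatorially, so DTTTD instances are first
restricted — the bridging protein must itself be a drug target somewhere
in the network — and then uniformly subsampled at 50 % (once per run,
with the run seed; the enumeration order is lexicographic, so the draw is
platform-reproducible). Within an instance no target may repeat, and the
start drug must differ from the end drug: a degenerate or self-looping
path carries no pathway meaning. Both choices are configurable.

### Encoder

Every node starts from its type-specific one-hot identity, mapped by a
trainable per-type matrix \(W^t\) to a shared dimension \(d'\), so a
meta-path instance becomes a short feature sequence. A per-schema
bidirectional GRU reads each instance in both directions;
\(h^f\) (the concatenated final hidden states of the two directions)
represents the whole instance, and \(h^l\) (the per-position output at
the final, central-node position) represents the central drug in the
context of that instance. Reading instances as *sequences* rather than
bags is the point: an interaction pathway has a direction, and the same
set of nodes traversed the other way is different evidence.

A graph-attention extractor then aggregates a drug's instances of one
schema: each instance gets a logit
\(\mathrm{LeakyReLU}(a_m^\top [h^l \| h^f])\), the weights are
softmax-normalized over the drug's instances, and K independent heads
project \(h^f\) and sum it under those weights (ELU on each head,
outputs concatenated). A drug with no instances of a schema receives a
trainable per-schema null embedding instead — the combiner below needs
all four schemas present, and an all-zero placeholder would not let the
model learn what "no evidence of this kind" should mean.

The four schema embeddings are fused by type-level semantic attention:
each schema's importance is the mean over drugs of
\(q^\top \tanh(W h + b)\), softmaxed over the four schemas, and every
drug's summary is the resulting convex combination, followed by a
projection with ReLU. The schema weights are shared across drugs: which
*kind* of mechanism evidence matters is a property of the data set, not
of the individual drug. Finally the chemical fingerprint (ECFP6, Morgan
radius 3; precomputed bits, or computed from SMILES through OpenBabel) is
concatenated to give the integrated drug embedding.

### Heads and losses

The AE head is a linear decoder with a logistic output on the ordered
concatenation of the two integrated embeddings, trained with the global
mean binary cross-entropy over all labels (probabilities clamped at
\(10^{-7}\) before the logs). The synergy head is a conic feed-forward
network — each hidden layer half the width of its predecessor, ReLU and
dropout on hidden layers — whose input concatenates both drug embeddings,
a learned affine embedding of the cell line's expression vector, and the
AE head's probability vector *treated as a constant*: the stop-gradient
keeps the synergy loss from back-propagating into the AE decoder, so the
auxiliary head is shaped only by its own labels while the synergy head
may still condition on its output. The total loss is
\(\ell = \alpha\,\ell_{MSE} + (1-\alpha)\,\ell_{BCE}\); \(\alpha = 1\)
recovers single-task training, and the weight is searched on validation
data over the ratio grid \(R = \alpha/(1-\alpha) \in
\{0.01, 0.05, 0.1, 0.5, 1, 5, 10\}\).

### Evaluation protocol

Samples are split 6:2:2 by *unordered drug pair*, not by triple: if the
same pair appeared in training and test under different cell lines, the
model would have "seen" the combination and the test score would be
over-optimistic. All triples of a pair follow the pair (largest-remainder
rounding of the pair counts). For the same reason the DD edges of the
network are built, by default, only from training-split pairs — otherwise
the graph itself would encode held-out labels (a flag restores the
all-pairs behaviour, which some published setups appear to use). Training
samples are duplicated in both drug orders; validation and test
predictions are the arithmetic mean of the two orders, which makes them
exactly order-invariant. Metrics are MSE, MAE and Pearson correlation,
averaged over independently re-split repeats (five by default).

## Training machinery

No automatic-differentiation framework is available to this package, so
it ships a small reverse-mode engine (`R/autograd.R`): dense-matrix
tensors on an implicit tape with the ~25 primitive operations the model
needs (including segmented softmax and grouped sums, so all drugs'
instances of a schema are processed in one vectorized pass). Its
gradients are validated against central finite differences in the test
suite. Optimization is Adam (learning rate 1e-3, weight decay 1e-5) with
early stopping on validation MSE (patience 20 by default); a parameter
whose gradient is exactly zero in a step is left untouched, which is what
makes "an \(\alpha=1\) run leaves the AE decoder bit-identical" hold
exactly rather than approximately.

## The synthetic-data generator

`generate_synth_data()` emulates the structure of a compiled
synergy/AE/network dataset at desk scale with a *planted shared
mechanism*. Each drug gets a latent vector \(u_d\), each cell line a
latent \(v_c\); a pair's shared factor \(s_{ij}\) combines latent
similarity with the pair's shared-target count in the generated DTI
table, standardized across pairs. AE labels are Bernoulli with logistic
probabilities in \(s_{ij}\) (per-label slopes 1.5–3); synergy is
`shared_effect`·\(s_{ij}\) plus a pair-by-cell-line interaction and
Gaussian noise. Fingerprints are random hyperplane bits of \(u_d\) with
bit-flip noise — correlated with, but far from determining, the latents —
and expression rows are logistic transforms of \(v_c\) clipped to
\([0,1]\). Coupling \(s_{ij}\) to the network's shared-target count is
deliberate: it makes the meta-path features genuinely informative, not
just the fingerprints, mirroring the mechanism-of-action rationale the
model is built on.

Defaults (20 drugs, 30 targets, 5 cell lines, 8 AE labels, 50 genes,
`p_dti` 0.12, `p_ppi` 0.08, `shared_effect` 2, `noise_sd` 1) give ≤ 950
triples, non-empty instance sets of all four schemas, and a
signal-to-noise ratio typical of synergy screens (observation noise on
the order of the mechanism effect). Drugs left without any target are
resampled so every drug has at least one DTI edge; the degenerate
empty-instance path is exercised by dedicated tiny fixtures instead.
What the generator does **not** emulate: real chemistry (bits are not
substructures), the heavy-tailed marginals of public synergy databases,
batch structure, or measurement artefacts — so passing tests show the
machinery works and the multi-task mechanism is recoverable when present,
not that any particular accuracy carries over to real screens.

## Problem sizes and numerical choices

Training-based tests and the acceptance script run a reduced
configuration chosen to keep the whole suite desk-scale: \(d' = 16\),
hidden 16, \(K = 4\), head dimension 4, 64 fingerprint bits, conic base
width 128 (depth 3, dropout 0.2). The full-size defaults of
`hetsyn_config()` (\(d' = 64\), hidden 64, \(K = 8\), base width 2048,
dropout 0.5, 1024 bits) are conventional values for this model family;
the exact sizes used by published variants are not pinned in their main
texts. Training is full-batch by default at these sizes — with a few
hundred symmetrized triples, per-epoch minibatching only adds encoder
recomputation; `batch_size` enables it when data grow. The multi-task
benefit experiment runs on the default fixture with `shared_effect = 3`
and `noise_sd = 1.5` (a high planted signal, as that comparison is about
recovering a mechanism that is present) and selects \(\alpha\) per seed
on validation over the full R grid; the single-task baseline
(\(\alpha = 1\)) also drops the AE input block, so it is a true
no-auxiliary variant. At this scale the validation-MSE trajectory is
non-monotone — an early dip, a plateau of a few dozen epochs, then the
main descent — so mid-run patience would return undertrained models on
*both* sides of the comparison; every arm therefore trains a fixed
60-epoch budget at learning rate 5e-3 and restores the
best-validation-epoch parameters, the early-stopping-free form of
validation selection.

Other numerical choices: probabilities clamped at \(10^{-7}\) before
logs; attention logits stabilized by max-subtraction inside every
softmax; Glorot-uniform initialization, zero biases, null embeddings
drawn at sd 0.1; undefined Pearson (constant predictions) reported as
`NA` with a warning and excluded from repeat averages; DD binarization
threshold 0 with *strict* inequality, so an exactly-zero score —
the additivity boundary — never creates an edge.

## Open design points, resolved

Several details are unspecified in the model family this package
implements; the choices here are:

- **\(h^l\)**: the BiGRU per-position output at the final (central-node)
  position — the central drug's contextual representation.
- **Head projection**: attention heads aggregate a per-head linear
  projection of \(h^f\) (the alternative — aggregating raw \(h^f\)
  K times — makes the heads redundant up to the shared weights).
- **Activations**: LeakyReLU (0.01) for attention logits, ELU for head
  outputs, ReLU for the final projection; all configurable.
- **BCE reduction**: one global mean over all sample × label elements.
- **DTTTD sampling**: drawn once per run (seeded), not redrawn per epoch,
  so the training objective is stationary; "targets of involved drugs"
  is read as targets of *any* drug in the network.
- **Multiple cell-line scores per pair**: a pair gets a DD edge if *any*
  in-scope sample clears the threshold (edges are pair-level, scores are
  triple-level).

## Limitations

The engine is plain-R dense linear algebra: adequate for desk-scale
studies and the test suite, not for hundred-drug screens at full model
width. Only the four wired schemas are supported end-to-end (the schema
type generalizes; the encoder does not). AE probabilities are not
calibrated and no per-label thresholds are fitted — the auxiliary task
exists to shape the encoder, not as a production AE classifier. The
command-line wrapper (`inst/cli/hetsyn.R`) covers dataset synthesis,
training, evaluation and the R-grid sweep; programmatic use through the
functions shown above is the primary interface.
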