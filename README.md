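# hetsyn

Multi-task heterogeneous-network learning for drug-combination synergy.

`hetsyn` predicts the therapeutic synergy score of a drug–drug–cell-line
triple (regression on Loewe, Bliss, HSA or ZIP scores) while
simultaneously learning the pair's adverse-effect labels (multi-label
classification) as an auxiliary task. The two tasks share one drug
encoder built on a heterogeneous network of drugs and protein targets,
so mechanism-of-action information carried by the adverse-effect labels
shapes the synergy predictor.

## The model in brief

Drugs and targets form a typed graph 𝒢 = (𝒱, ℰ, ℛ) with drug–target
(DTI), protein–protein (PPI) and thresholded drug–drug therapeutic-effect
(DD) edges. Each drug is encoded from the instances of four meta-path
schemas ending at it — DTD (shared target), DTTD (interacting targets),
DTTTD (bridged targets, restricted and 50 %-subsampled) and DD:

1. nodes get one-hot identities mapped to a shared dimension by
   per-type matrices *W*ᵗ;
2. a per-schema **BiGRU** reads each instance in both directions
   (whole-instance state *h*ᶠ, central-node output *h*ˡ);
3. a multi-head attention extractor weights the drug's instances,
   α = softmax over instances of LeakyReLU(*a*ₘᵀ[*h*ˡ‖*h*ᶠ]), and
   aggregates per-head projections of *h*ᶠ;
4. semantic attention fuses the four schema embeddings with weights
   β shared across drugs, and the ECFP6 fingerprint is concatenated.

The AE head is a logistic decoder on the ordered pair of integrated
embeddings (binary cross-entropy). The synergy head is a conic DNN
(each hidden layer half the width of the last) on both embeddings, a
learned cell-line expression embedding, and the AE probabilities passed
through a **stop-gradient**. Training minimizes
ℓ = α·ℓ_MSE + (1 − α)·ℓ_BCE end-to-end; α is selected on validation
data over the ratio grid R = α/(1−α) ∈ {0.01, 0.05, 0.1, 0.5, 1, 5, 10}.
Evaluation is leakage-free: samples are split 6:2:2 **by drug pair**,
training samples are duplicated in both drug orders, and held-out
predictions average the two orders.

Because no autograd framework is available in this R stack, the package
includes a small reverse-mode differentiation engine (validated by
finite-difference tests) that trains the whole model.

## Worked example

```r
library(hetsyn)

# seeded synthetic dataset: 20 drugs, 30 targets, 5 cell lines,
# 8 AE labels, with a planted mechanism shared by AE labels and synergy
d <- generate_synth_data(synth_config(seed = 7))

cfg <- hetsyn_config(d_prime = 16, hidden = 16, K = 4, d_head = 4,
                     d_att = 16, d_cell = 8, n_bits = 64,
                     dnn_base_width = 128, dnn_depth = 3, dropout = 0.2,
                     n_ae = 8, alpha = 0.5, epochs = 100, patience = 100)
m <- train_model(d, cfg, seed = 3)
evaluate_model(m, d, "test")
```

Output from the run above:

```
$mse
[1] 1.971289

$mae
[1] 1.115791

$pearson
[1] 0.7983316

$n
[1] 175
```

The test synergy scores have variance ≈ 6.3, so a pair-grouped test MSE
of ≈ 2.0 (Pearson ≈ 0.80) means the model recovers most of the planted
mechanism from drug pairs it has never seen. The training log
(`m$log`) tracks per-epoch ℓ_BCE, ℓ_MSE, ℓ_total and validation MSE;
here ℓ_total fell from 3.70 (epoch 1) to 1.16 (epoch 100).

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/cli/hetsyn.R synth --seed 7 --out data/
Rscript inst/cli/hetsyn.R train --data data/ --seed 3 --model-dir run1/
Rscript inst/cli/hetsyn.R evaluate --data data/ --model-dir run1/
Rscript inst/cli/hetsyn.R sweep-alpha --data data/ --seed 3
Rscript inst/cli/hetsyn.R export-instances --data data/ --drug-pair DRUG001,DRUG002 --out paths/
```

## Package layout

- `R/hetnet.R` — heterogeneous network construction, table loading
- `R/metapath.R` — schema definitions, instance enumeration, DTTTD
  restriction/sampling, tensorization, TSV export
- `R/encoder.R` — BiGRU/GRU/mean aggregators, attention extractor,
  semantic combiner, ECFP6 fingerprints
- `R/heads.R` — AE decoder, conic synergy DNN, BCE/MSE/total losses
- `R/pipeline.R` — pair-grouped splits, symmetrization, training,
  evaluation, repeated runs, the R-grid sweep
- `R/synthdata.R` — seeded synthetic data with a planted shared factor
- `R/autograd.R` — the reverse-mode engine and Adam
- `vignettes/hetsyn-methods.Rmd` — model, assumptions, design decisions
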