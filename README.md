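# ppistack

Residue-level prediction of protein–protein interaction (PPI) sites
from sequence alone, for computational biologists who need interface
annotations where no structure exists.

Each residue is described by a **targeted residue feature** f_tr and a
**context feature** f_ctx — the matrix of per-residue features over a
sliding window of 2W+1 positions, zero-padded at sequence ends. Six
encoders (one-hot, entropy density, physicochemical descriptors,
hydropathy indices, PSSM profile rows, windowed pseudo amino acid
composition) are paired into three feature modules. Each module feeds
one base classifier:

    f_ctx → [conv(5) → ReLU → maxpool(3)] × 3
          → masked multi-head self-attention   E = mask(QKᵀ/√d_m)
          → S = [Z | A], f_agg = mean over non-padded rows
    [f_agg | f_tr] → FC(1024) → BN → ReLU → dropout
                   → FC(256)  → BN → ReLU → dropout
                   → FC(1)    → sigmoid

Class imbalance (interaction sites are ~10–18% of residues) is handled
by splitting the majority class into M = ⌊N_neg/N_pos⌋ disjoint parts;
each part plus all positives forms one training subset (ratio < 2),
cycled round-robin with per-epoch subsampling to exact 1:1. The three
base networks are combined by **stacking**: a meta-learner (logistic
regression by default; decision tree, random forest, nearest neighbor,
voting, averaging and a least-squares rule are available) is fitted on
the bases' validation-split probabilities. Final call: probability ≥
0.5. Metrics: ACC, Pre, Rec, F1, MCC, AUROC, AUPRC and per-class
accuracies.

The network, its backpropagation and the Adam optimizer are
implemented in R on BLAS matrix operations and verified against
finite-difference gradients in the test suite. A synthetic
planted-motif generator (with mock PSI-BLAST PSSMs) makes the full
pipeline runnable and testable with no external data.

## Worked example

```r
library(ppistack)

# 60 synthetic sequences with a planted CHWYK motif, 15% site labels,
# 5% label noise, plus mock PSSMs for feature module 2
sc   <- synthetic_config(n_sequences = 60, seed = 42)
recs <- attach_mock_pssms(generate_dataset(sc), sc)
sp   <- split_dataset(recs, ratio = c(3, 1, 1), seed = 42)

ens <- train_stacked_ensemble(
  split_records(recs, sp, "train"),
  split_records(recs, sp, "validation"),
  rule = "logistic_regression", window = 8,
  train_cfg = train_config(max_epochs = 15, seed = 42))

te   <- split_records(recs, sp, "test")
pred <- ensemble_predict(ens, te)
evaluate_predictions(unlist(lapply(te, `[[`, "labels")), pred$score)
```

```
        ACC       Pre       Rec        F1       MCC     AUROC     AUPRC
1 0.8993435 0.7213115 0.6027397 0.6567164 0.6016079 0.8252711 0.6569014
    acc_pos   acc_neg
1 0.6027397 0.9557292
```

Reading the row: on the held-out test sequences 89.9% of residues are
called correctly; of residues called sites, 72.1% are true sites
(precision); 60.3% of true site labels are recovered (recall = site
accuracy); MCC 0.60 summarizes the confusion matrix on the imbalanced
data; AUROC/AUPRC rank the raw probabilities. Label noise (5% flips)
bounds what is attainable against these labels — against the planted
motif truth the same scores rank essentially perfectly (AUROC 0.98).

A thin command-line wrapper over the same functions lives at
`inst/cli/ppistack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ppistack.R", package="ppistack"))')" \
    simulate --out sim --n 50 --seed 1
```

with subcommands `simulate`, `featurize`, `train`, `stack`, `predict`,
`evaluate` and global flags `--config`, `--seed`, `--log-level`.

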