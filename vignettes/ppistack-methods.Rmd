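---
title: "Predicting protein-protein interaction sites with stacked context-attention networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interaction sites with stacked context-attention networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppistack)
```

## The problem

A residue is a protein-protein interaction (PPI) site when it lies in a
physical interface with a partner protein. Predicting these sites from
sequence alone is useful because interface annotations from structures
cover only a small fraction of known proteins. The task has two
stubborn properties: the signal is contextual (whether a residue sits
in an interface depends on the stretch of sequence around it), and the
classes are severely imbalanced (curated benchmarks run at roughly
10-18% interaction sites).

`ppistack` addresses both. Each residue is described twice: by a
*targeted residue feature* $f_{tr}$, and by a *context feature*
$f_{ctx}$, the ordered matrix of the same per-residue features over a
sliding window of $2W+1$ positions centered on it, zero-padded past the
sequence ends. Keeping $f_{tr}$ on its own untransformed path prevents
the much wider context block from drowning out the residue actually
being classified.

## Feature modules

Six per-residue encoders are paired into three fixed feature modules;
each module drives one base classifier:

| Module | Encoders | Dimension |
|---|---|---|
| 0 | one-hot (20) + entropy density (20) | 40 |
| 1 | physicochemical descriptors (21) + hydropathy indices (2) | 23 |
| 2 | logistic-squashed PSSM row (20) + windowed pseudo amino acid composition (30) | 50 |

Entropy density attaches to every residue the vector
$u \mapsto -p_u \log_2 p_u$ of its sequence's composition. The windowed
pseudo amino acid composition is Chou-type PseAAC computed on the
$2K+1$ subsequence centered on the target ($K = 10$): 20 normalized
composition terms plus $\lambda = 10$ sequence-order correlation
factors $\theta_j$, where $\Theta$ is the mean squared difference of
standardized hydrophobicity, hydrophilicity and side-chain mass scales,
the correlation weight is $w = 0.05$, and $\theta_j$ is clamped to 0
when the subsequence is shorter than $j+1$ (an edge-of-sequence case
the formula leaves open; the clamp keeps every component defined and
the vector still sums to 1). PSSM rows come from PSI-BLAST ASCII files
via `parse_pssm()`; the package never runs PSI-BLAST itself. The raw
log-odds are mapped through the logistic function, a conventional
monotone squashing to (0,1); the profile literature describes these
columns as occurrence probabilities but fixes no transform, so the
choice is stated here as the package's own.

Unknown residues (`'X'`) are accepted and encode as zeros everywhere;
any other non-standard letter is rejected at read time, because silent
coercion hides upstream data bugs. The 21-column physicochemical table
bundled with the package is a synthetic stand-in (see
`?phychem_table`): it reproduces the dimensionality of descriptor sets
derived from large amino-acid property collections, but its values are
a deterministic polynomial expansion of published hydropathy,
hydrophilicity and mass scales. It is configuration, not logic — every
pipeline mechanism is independent of the particular finite values.

## The base classifier

Each base network consumes $(f_{ctx}, f_{tr})$ for one residue:

1. **Convolution block** — three stages of 1-D convolution (kernel 5,
   8 kernels, stride 1, same-length zero padding), ReLU, and max
   pooling (size 3, stride 1, same-length padding), preserving the
   window length $L = 2W+1$.
2. **Masked multi-head self-attention** — per head $h$ of 4, with
   dimension $d_m = 16$: $Q = W_Q Z$, $K = W_K Z$, $V = W_V Z$;
   energies $E = \mathrm{mask}(QK^\top / \sqrt{d_m})$, where the mask
   subtracts $10^9$ at padded positions of the summed-over index;
   weights are a column-normalized softmax (each column sums to 1); the
   head output at position $j$ is $\sum_i w_{ij} v_i$; heads are
   concatenated with no output projection.
3. **Aggregation** — rowwise concatenation $s_i = [z_i, a_i]$ (row
   dimension $8 + 4 \times 16 = 72$), then the arithmetic mean over
   non-padded rows only, consistent with the masking intent.
4. **Predictor head** — $[f_{agg}, f_{tr}]$ through
   affine(1024) / batch-norm / ReLU / dropout(0.5), affine(256) /
   batch-norm / ReLU / dropout, affine(1) / sigmoid. Batch
   normalization sits between affine map and nonlinearity; inference
   uses running statistics and disables dropout.

Padded window rows are forced to zero at network entry. Together with
the attention mask and the masked mean, this makes the output provably
invariant to whatever content padded rows might carry — otherwise the
convolution would leak neighbouring pad content. The softmax direction
follows the formulation exactly as stated (normalization over the
summed-over index); ablation configurations with a single head
(`heads = 1`) and without attention (`attention = FALSE`, aggregation
over the convolution output alone) are first-class configurations.

The whole computational graph, its backpropagation and the Adam
optimizer are implemented in R on BLAS matrix operations — the network
is the package's scientific core, and its gradients are verified
against central finite differences in the test suite.

## Imbalance handling

With $N_n$ non-sites and $N_p$ sites, the majority class is split into
$M = \max(1, \lfloor N_n / N_p \rfloor)$ disjoint, seeded-shuffled,
near-equal parts; each part joined with all positives forms one
training subset. Flooring (rather than rounding) is what guarantees
every subset's negative:positive ratio stays below 2; a ceiling could
starve parts. Training cycles round-robin through the subsets, one per
epoch, and within each epoch the subset's negatives are subsampled
without replacement to exactly the positive count, re-drawn per epoch
(seed XOR epoch). Over one $M$-epoch cycle every negative is eligible
exactly once while every positive is seen $M$ times — mild
oversampling of the minority class without synthetic samples.

## Training and stopping

Base networks minimize mean binary cross-entropy (predictions clipped
to $[10^{-7}, 1-10^{-7}]$ before the logarithm) with Adam at default
moments, learning rate 0.001, batch size 64, at most 50 epochs.
Early stopping monitors the validation loss (validation data never
enters gradient updates): training stops when the trailing-3-epoch
mean loss has strictly increased for 5 consecutive epochs — ties do
not count, and the trailing mean uses whatever epochs exist before
epoch 3. Minibatches of fewer than two samples are skipped because
batch statistics are undefined for them.

## Stacking

Three base networks — one per feature module — are trained
independently on the training split. Their predicted probabilities on
the *validation* split form a three-column meta-feature matrix on
which the decision rule is fitted; the meta-learner is trained on
held-out predictions precisely so it does not inherit the bases'
training-set optimism. Supported rules: logistic regression (default),
decision tree, random forest, nearest neighbor ($k = 5$; the reference
setup names no $k$), majority voting (no combined probability, so no
AUROC/AUPRC), probability averaging, and a least-squares linear
combination (`linear_mse`) honoring the squared-error formulation of
the ensemble objective. The final call is `probability >= 0.5`.

## Evaluation

`evaluate_predictions()` reports ACC, precision, recall, F1 and the
Matthews correlation coefficient directly from the confusion counts
(zero denominators report 0 rather than NaN, so extreme imbalanced
runs stay tabulable), plus AUROC in the rank/Mann-Whitney formulation
with half-credit ties and AUPRC as uninterpolated average precision —
PR integration conventions differ, so the convention is fixed and
stated. Per-class accuracies (recall and specificity) accompany them.

## The synthetic data generator

Because the public benchmarks require structure-derived labels and
PSI-BLAST profile databases, the package ships a generator whose
planted mechanism every module can be tested against. Sequences are
drawn from a uniform background over the 20 residues; a 5-residue
motif (`CHWYK` by default) is planted at non-overlapping random
positions; motif-covered residues are labeled 1; each label then flips
independently with probability 0.05. The planting rate is solved from
the noise level, $(p - \nu)/(1 - 2\nu)$, so the *final* prevalence
matches the 0.15 target — the imbalance regime of the curated
benchmarks. Mock PSSMs give motif positions an elevated integer score
on the residue's own column, emulating conservation; integer scores
also make the PSI-BLAST ASCII round trip exact.

What the generator does *not* emulate: evolutionary correlation
structure in profiles, solvent accessibility, length distributions of
real proteins (default lengths 30-50 keep the simulation study
tractable on one CPU; the recovery study uses $W = 8$ and 200
sequences for the same reason), or interface labels that arise from
3-D geometry rather than a literal sequence motif. Passing tests
therefore demonstrate that the pipeline recovers a planted sequence
mechanism under class imbalance and label noise — not benchmark-level
biological accuracy.

One consequence of flip noise matters for interpretation: against
noisy test labels, even a perfect motif detector cannot exceed an
AUROC of about 0.848 at these settings, since 5% of test labels are
wrong by construction. Mechanism recovery is therefore scored against
the planted motif truth (kept as an attribute on each record), while
training and validation only ever see the noisy labels — the standard
design of a simulation study. The trained module-0 network reaches the
noisy-label ceiling and scores far higher against the truth; the
label-permutation ablation (training labels shuffled, truth untouched)
collapses to chance, showing that signal rather than leakage drives
the result.

## Numerical choices and limitations

* Mask penalty $10^9$; softmax stabilized by subtracting the maximum
  energy before exponentiation.
* Parameter initialization is fan-in-scaled Gaussian with a recorded
  seed; every training run is bit-reproducible from its configuration.
* Batch-norm running statistics use momentum 0.1 and are frozen at
  inference.
* Splits are by sequence (floor sizes, remainders to train first), so
  residue-level leakage across splits is structurally impossible.
* The predictor is residue-wise: no CRF-style coupling between
  neighbouring calls.
* Training on CPU in R is practical at simulation scale; applying the
  package to genome-scale collections would call for a compiled
  backend behind the same interfaces.
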