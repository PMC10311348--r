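---
title: "Sequence-to-sequence signal peptide prediction: model, training, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-to-sequence signal peptide prediction: model, training, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Signal peptides (SPs) are short N-terminal segments that route newly
synthesized proteins into a translocation pathway and are cleaved off by a
signal peptidase (SPase). Predicting whether a protein carries an SP, which
kind, and where the cleavage site (CS) lies is a residue-labeling problem:
every residue $a_i$ of the N-terminal window receives one of eight labels

> Sec/SPaseI, Sec/SPaseII, Sec/SPaseIV, TAT/SPaseI, TAT/SPaseII,
> intracellular, transmembrane, extracellular.

The five SP labels distinguish the translocation pathway (general secretory
Sec vs twin-arginine TAT) and the cleaving peptidase (SPase I, II or IV).
Each sequence also carries its organism group (eukarya, gram-negative
bacteria, gram-positive bacteria, archaea) as a categorical input. A call is
derived from a predicted label sequence by a fixed rule (`extract_sp_call()`):
the SP type is the label of residue 1; the CS index is the first position
$c > 1$ labeled with a non-SP class, i.e. the first mature residue — the
cleavage site lies between residues $c-1$ and $c$. When position 1 is an SP
label but later SP labels disagree in type, the call's type still comes from
position 1 alone and the disagreement is surfaced as a flag; when predicted
SP labels never terminate inside the window, the CS is reported absent with a
`runs_off_window` flag rather than guessed.

## The model

`sigpept` implements a transformer encoder-decoder that *translates* a
residue sequence into a label sequence, rather than tagging each position
independently.

**Encoder.** Residues are one-hot encoded into 21-dimensional vectors (20
amino acids plus one shared padding/unknown token, onto which the ambiguous
codes X, B, Z, U, O are mapped). The initial embedding adds a learned linear
positional table:
$$E_0 = W_a A + W_P, \qquad W_a \in \mathbb{R}^{d \times 21},\; W_P \in \mathbb{R}^{d \times N}.$$
$L_{enc}$ transformer blocks follow, each with $H$-head scaled dot-product
attention ($Q_h = E^\top W_{Q,h}$ etc., per-head scaling $\sqrt{d/H}$), an
output projection, a two-layer ReLU feed-forward expansion to $e_d$, and two
post-residual layer normalizations. Attention projections carry no bias;
feed-forward layers do.

**Memory assembly.** The encoder output $E_L$ is extended along the sequence
axis with a learned organism-group embedding $g = W_G\,\mathrm{onehot}(g)$
and along the feature axis with a *fixed* sinusoidal table
$$W_S(2k+1, i) = \sin\!\big(i / 10000^{2k/d_S}\big), \quad
  W_S(2k+2, i) = \cos\!\big(i / 10000^{2k/d_S}\big),$$
giving the memory $E = (E_L \oplus g) \oplus W_S$ of width $d + d_S$. The
*same* $W_S$ is concatenated to the decoder inputs, so query and key carry
identical positional codes at matching positions — this is what lets
cross-attention align a label position with "its" residue.

**Decoder.** Label tokens (8 labels + BOS) are embedded with $W_y$, prefixed
with BOS, concatenated with $W_S$, and processed by $L_{dec}$ blocks of
causally masked self-attention (an additive mask, $-\infty$ above the
diagonal), cross-attention against the memory, and a feed-forward block,
each with post-residual layer normalization. The output rule concatenates
the decoder state of the *previous* label position with the one-hot of the
residue being labeled:
$$p(y_k) = \mathrm{Softmax}\big((D_{L,k} \oplus c(k))^\top W_O\big),
  \qquad W_O \in \mathbb{R}^{(d + d_S + 21) \times 8},$$
so the exact residue identity is available to the classifier even when
contextualization has blurred it. At inference the decoder is greedy and
autoregressive: step $k$ conditions on its own argmax emissions (BOS alone
at step 1), ties break to the lowest label id, and since the 8-class output
has no stop symbol, the output length always equals the input length.

**Configurations.** Two presets share one code path
(`model_config()`):

| preset      | $d$  | $d_S$ | width | $H$ | $L_{enc}/L_{dec}$ | $e_d$ | use |
|-------------|------|-------|-------|-----|-------------------|-------|-----|
| compact     | 64   | 16    | 80    | 4   | 2 / 2             | 256   | default; trainable from scratch on one CPU |
| full-scale  | 1024 | 128   | 1152  | 16  | 30 / 3            | 4096  | dimensional reference for the published setup |

The full-scale encoder corresponds to fine-tuning a 30-layer pretrained
protein language model; that is GPU-scale work and outside what this package
runs, but all dimension bookkeeping (notably the decoder token width
$d + d_S = 1152$) is preserved and checked. The compact encoder is trained
from scratch with the same architecture and a learned positional table.

**Window length.** All sequences are truncated/padded to $N = 70$ residues.
Canonical SP architectures (N/H/C regions, lipobox, basic region) fit
comfortably inside 70 residues, and a short window keeps desk-scale training
cheap. Pad positions are excluded from every attention and from the loss;
computation is trimmed to the real length, which is exact for this masking
scheme.

## Training

Teacher forcing: the decoder sees gold labels shifted right by BOS, and the
loss is mean per-position cross-entropy over non-pad positions (class
re-weighting is exposed in `train_config()` but off by default). The
optimizer is Adam with *constant* per-component learning rates; the
published recipe protects a pretrained encoder with $10^{-5}$ while the
decoder trains at $10^{-4}$, and those are the package defaults. When the
compact encoder is trained from scratch there is no pretrained component to
protect, and the informative gradient signal (SP type at position 1,
region-boundary transitions) is a small fraction of the per-position loss,
so the from-scratch preset uses $4\times10^{-4}$ for both components, small
batches (4 sequences per update, maximizing the number of Adam steps per
pass) and Adam $\beta_2 = 0.98$, the transformer-standard value that adapts
faster to such sparse signals. Dropout 0.1 is applied on the decoder side
(attention outputs and feed-forward activations); encoder dropout is
configurable and defaults to 0. Decoder parameters are Xavier-uniform
initialized (the compact encoder uses the same rule); the sinusoidal table
is fixed and never trained.

Stochastic weight averaging (SWA) maintains the exact arithmetic running
mean of all trainable parameters, updated once after every epoch from the
first epoch onwards. Checkpoints keep three parameter sets: the last epoch,
the SWA mean, and — when a validation fold is supplied — the epoch with the
highest validation cleavage-site F1 (`best_params`). Greedy-decoded CS-F1
fluctuates by a few points between late epochs even while the teacher-forced
loss decreases monotonically (decoding conditions on the model's own
outputs, so small parameter changes can move block boundaries), and at
desk scale the SWA mean still includes poor early-epoch snapshots; headline
evaluations therefore use the validation-selected epoch, with SWA and
last-epoch results reported alongside.

## The synthetic generator

`grammar_spec()` + `sample_dataset()` emit labeled sequences from an
explicit grammar of the canonical SP architectures, so that training,
evaluation and saliency are exercised end-to-end without any downloads:

* **Sec/SPaseI, TAT/SPaseI** — basic N-region (K-enriched), hydrophobic
  H-region (A/L/I/V/F/M/W), polar C-region whose last three residues carry
  the Ala-X-Ala SPase I consensus (the near-universal small-residue rule at
  positions $-3$ and $-1$); TAT variants insert the twin-arginine RR
  dipeptide at the N/H boundary and allow a longer N-region.
* **Sec/SPaseII, TAT/SPaseII** — N- and H-regions followed by a
  three-residue lipobox (L-[A/S]-[G/A]) and an invariant Cys as the first
  mature residue.
* **Sec/SPaseIV** — only a short basic region, ending in the G|F prepilin
  processing motif.
* **Negatives** — all-intracellular, all-extracellular, and TM-containing
  sequences (an internal hydrophobic block labeled transmembrane).

Mature/background residues are uniform over the 20 amino acids; region
length ranges default to N 2–10 (TAT up to 14), H 7–15, C 3–7, basic region
2–8. Classes and organism groups are drawn from equal mixture weights, and
total sequence length from 40–70. A chance "RR" dipeptide inside a non-TAT
SP is rejected and redrawn so that the twin-arginine motif remains the
defining TAT feature — the synthetic analogue of the biological contrast the
saliency analysis is meant to recover.

What the generator does **not** emulate: real organism-specific amino-acid
statistics, homology structure between sequences (partitions are assigned at
random), length distributions of real proteins, and annotation noise.
Passing the recovery tests therefore demonstrates that the architecture,
training loop, decoding and metrics are correct and that the model can learn
motif-anchored labeling rules from data alone — it does not certify
performance on real proteomes.

## Evaluation suite

* **Tolerance-windowed CS precision/recall/F1** per (SP type, organism
  group, tolerance $\in \{0,1,2,3\}$): a prediction is correct iff the
  predicted type matches and $|i_p - i_c| \le tol$; a correct-type call
  outside the window counts as both FP and FN for that type; a wrong-type
  call counts as FP for the predicted type and FN for the true type; a
  missed SP is an FN; a false alarm on a no-SP record is an FP.
  $F_1 = 2PR/(P+R)$; the average F1 is the unweighted mean over populated
  cells and the weighted F1 weights cells by their occurrence count. Cells
  with no positive truth and no positive call are undefined: they are
  excluded from averages and counted in the report's `excluded_cells` flag.
* **MCC1/MCC2** per (type, group): binary SP-type detection with negatives
  restricted to no-SP records (MCC1) or additionally including other SP
  types (MCC2); a zero denominator yields 0 with a flag.
* **Expected calibration error** over 10 equal-width bins, with confidence
  defined as the predicted probability of the emitted label at the CS
  position (or of the position-1 label for type-only calls) and correctness
  as type-correct with CS within tolerance 0 (both choices are package
  conventions; the confidence scalar is not defined by the evaluation
  protocol itself).
* **Learning curve**: subsample the training pool without replacement at
  fractions 25/50/75/100%, retrain, evaluate CS-F1 on a fixed fold, repeat.

## Saliency

Input importance is the gradient of a prediction probability with respect
to the initial embedding rows $E_0$ — the last non-contextualized residue
representations — with the decoder conditioned on its own greedy labels.
For type saliency the objective is the probability of the position-1 label;
for CS saliency, of the emitted label at the called CS position. The
per-residue gradient vector is reduced to a non-negative scalar by the mean
of absolute components (an L2 option exists; the absolute mean is
scale-stable across $d$). Profiles are aligned on a motif anchor — the first
exact RR dipeptide inside the called SP region, or the Cys at the first
mature position — normalized each by its own maximum (relative importance;
a no-normalization option exists), and averaged per relative offset. On
synthetic data a trained compact model shows the two expected signatures:
high mean importance at the RR offsets for TAT type predictions, and a Cys
spike at offset 0 for SPase II CS predictions that Sec/SPaseI lacks.

## Numerical choices

* Layer normalization uses $\epsilon = 10^{-5}$ and population variance,
  applied post-residual.
* Additive attention masks use $-10^{30}$ rather than literal $-\infty$ so
  a fully masked row can never produce NaN (no such row exists after
  trimming, but the guard is kept).
* Greedy decoding caches per-layer keys/values and processes one stream
  position per step; it is bit-identical to the teacher-forced forward pass
  conditioned on the same labels.
* Argmax ties break to the lowest label id, making decoding fully
  deterministic; there is no sampling anywhere at inference.
* Gradients are exact reverse-mode derivatives of the forward pass,
  verified against central finite differences in the test suite.
* Training is deterministic given the seed: initialization, shuffling and
  dropout all derive from it; dropout uses a dedicated counter-based seed
  per step so results do not depend on R's global RNG state.

## Problem sizes used by the shipped runs

The recovery runs train the compact model on 3000 generated records and
evaluate on 500 held-out records, with a 300-record validation fold for
epoch selection (22 epochs); the learning-curve harness uses an 800-record
pool, a 150-record fold, fractions 25% and 100%, three seeds, ten epochs.
These sizes were chosen as the smallest at which the learned behavior is
stable enough to assert on; all of them are function arguments, not limits.

## Known limitations

* The pretrained-encoder path of the published setup (a 30-layer protein
  language model fine-tuned end-to-end) is out of scope; the compact
  encoder is trained from scratch, so absolute benchmark numbers on real
  data are not comparable.
* The synthetic grammar is deliberately separable; real SPs overlap in
  composition with transmembrane helices and have noisier cleavage-site
  context.
* SWA at short from-scratch schedules underperforms the last-epoch
  parameters (see above); both are stored.
* The three-line reader checks record structure strictly but does not
  attempt to repair inconsistent annotations; violations are reported via
  `validate_record()` flags.
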