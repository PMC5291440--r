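---
title: "Promoter recognition with convolutional networks: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter recognition with convolutional networks: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Promoters — the regions around transcription start sites (TSS) that direct
transcription initiation — are hard to recognize computationally because
their structure is gene-specific: short functional motifs (a TATA-box
roughly 30 bp upstream of the TSS in a subset of eukaryotic promoters, the
bacterial −10 and −35 hexamers, initiator elements straddling the TSS)
occur in varying combinations and are rarely intact. `promcnn` implements
a sequence-only approach: a convolutional neural network (CNN) trained to
separate fixed-length, TSS-anchored windows into promoter and non-promoter
classes, plus a *random-substitution* procedure that interrogates a
trained network to localize the positionally conserved elements it relies
on.

All windows are anchored at the TSS. Two conventions cover the usual
cases: 81-nt bacterial windows spanning −60..+20 (TSS at 1-based position
61) and 251-nt eukaryotic windows spanning −200..+50 (TSS at position
201). The TSS-relative coordinate of 1-based position $p$ is
$r = p - \mathrm{tss\_index}$, so position 171 of a 251-nt window is −30.

## Model

Each sequence is one-hot encoded in the column order A, T, G, C —
A = (1,0,0,0), T = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1) — giving an
$n \times 4$ input. The ambiguous base N encodes as the all-zero row, so
it contributes nothing to any filter dot product (the neutral choice
under $W x + b$).

A model is a stack of convolutional layers described by triplets
`n_filters, filter_length, pool_size`, the dialect used throughout the
package (`"200, 21, 4"`; `/` separates layers, as in
`"100,7, 0 / 150, 21, 12"`). Convolution is *valid* (no padding) with
stride 1: a length-$n$ input and length-$L$ filters give an activation
map of length $n - L + 1$. Filters compute $W x + b$ at every position
and are shared across positions; activations pass through ReLU.
Max-pooling with size $p > 0$ keeps the maximum over non-overlapping
windows (stride = $p$, trailing remainder dropped); $p = 0$ means no
pooling after that layer. These conventions make the
single-layer geometry `"300, 21, 231"` on a 251-nt input exactly a
global pool: the 231-length map collapses to one position. The final map
is flattened (position-major within filter) into a fully connected ReLU
layer (128 neurons by default) and a two-neuron sigmoid output, one
neuron per class: (promoter, non-promoter).

A sequence is called a promoter iff its promoter-neuron output strictly
exceeds the non-promoter output; ties break to non-promoter, the
conservative call. The reported score is always the promoter neuron's
output, so the decision rule is well-defined even though two independent
sigmoids need not sum to one.

## Training

Training minimizes categorical cross-entropy with the Adam optimizer at
batch size 16. Because the output neurons are sigmoids rather than a
softmax, the loss is computed on the sum-normalized outputs
$p_i = s_i / (s_1 + s_2)$ — the way mainstream frameworks apply
categorical cross-entropy to a non-softmax head.

Two numerical choices stabilize this head, and both are the package's own
decisions, recorded in model metadata:

* **Zero-initialized output layer.** The normalized loss is flat wherever
  both sigmoids saturate together (there $\sigma'(z) \to 0$ on both
  neurons and training dies at 50% accuracy). With the output weights and
  biases starting at exactly zero, both neurons start at 0.5 and the
  class gradients grow them anti-symmetrically, which keeps the common
  mode near zero. Conv and dense layers use seeded He-normal
  initialization ($\mathrm{sd} = \sqrt{2/\mathrm{fan~in}}$), the standard
  scheme for ReLU stacks.
* **Gradient clipping.** Each minibatch gradient is clipped to a global
  L2 norm of 1 (`clip_norm` in `train_config()`), preventing early Adam
  overshoot into the same saturated region.

The Adam step size defaults to $10^{-3}$ with the canonical moment decays
(0.9, 0.999); none of these are claims about the original
implementation — the source work states the optimizer and batch size but
not its step size or epoch budget.

Datasets are split 70/10/20 (train/validation/test) as fractions of the
full set, stratified by class so each part preserves the class ratio
within rounding, deterministically per seed. (The alternative reading
"70% of the remainder" does not sum to one; fractions of the full set is
the only consistent interpretation.) The validation part controls the
number of learning epochs: after every epoch the model is scored on it,
and the returned parameters are those of the epoch with the highest
validation accuracy — earliest on ties — rather than the final epoch.
Training stops after `patience` epochs (default 8) without improvement.
This is the over-fitting guard: on small corpora training accuracy
reaches 1.0 while validation accuracy plateaus earlier, and epoch
selection returns the plateau model.

Class imbalance is left as-is by default, with an optional
`class_weights` argument for reweighting the loss.

## Performance measures

With $TP$/$TN$ correct promoter/non-promoter calls and $FP$/$FN$ the
errors, the package reports

$$Sn = \frac{TP}{TP+FN}, \qquad Sp = \frac{TN}{TN+FP}, \qquad
AC = \frac{TP+TN}{TP+TN+FP+FN},$$

$$CC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

$Sp$ here is the true negative rate (the formula is authoritative; prose
descriptions of "specificity" sometimes describe precision instead). $CC$
is the Matthews-style correlation and equals the Pearson correlation of
the binary label and prediction indicators; it accounts for unequal class
sizes. When a marginal sum is zero $CC$ is undefined; the default is a
hard error, with an opt-in `degenerate = "zero"` mode that returns a
flagged 0 — silent zeros hide broken evaluations. All measures are
computed in double precision and only rounded for display.

## Synthetic corpora

The generator emulates the statistical skeleton of TSS-anchored promoter
corpora so that every downstream stage is testable without downloads:
promoter windows are i.i.d. background draws (default uniform over
A/C/G/T) with one or more PWM motifs sampled and overwritten at fixed
TSS-relative offsets; non-promoter windows are motif-free background.
Everything is deterministic given the corpus seed.

Built-in fixture motifs (consensus-weighted PWMs, *not* biological
claims): a TATA-box (`TATAAAAG`, 8 nt at −30), an initiator-like element
(`CAGT`, 4 nt at −1), and bacterial −10 (`TATAAT`) and −35 (`TTGACA`)
hexamers. The default consensus weight is 0.85 per position — enough
degeneracy that motif instances vary, as real elements do. The
acceptance-style end-to-end checks use the consensus-only (strength 1)
TATA variant, which makes the corpus separable by construction: a
positional string-match oracle achieves accuracy 1.0, so any shortfall in
the trained network is attributable to the learner, not the data.

Positional jitter is uniform over integers in $[-j, +j]$ — the simplest
positional-variability model, sufficient to test how profile dips widen.
An optional "coding-like" negative mode draws a 3-periodic base
composition that mimics the codon structure of coding sequence, giving a
harder, compositionally structured negative class. What the generator
deliberately does *not* model: dinucleotide and higher-order background
structure, CpG islands, isochores, or negatives drawn from real genomic
context (opposite-strand coding fragments, post-first-exon fragments).
Tests passing on these corpora therefore demonstrate correctness of the
machinery and learnability of positional signals — not expected accuracy
on real promoter corpora.

## Random-substitution profiling

To locate positionally conserved elements, a window of length $L$
(default 6) slides across the promoter set with stride 1. At each start
$x_1$ (the window covers $x_1..x_2$, $x_2 = x_1 + L - 1$), the window in
every promoter is replaced by a freshly drawn random sequence (uniform
over A/C/G/T by default, independently per record and replicate), the set
is re-classified with the fixed model, and sensitivity is averaged over
replicates (default 10, with a standard error per point). Dips below the
unsubstituted baseline mark sequence the classifier depends on;
`profile_minima()` merges consecutive window starts whose sensitivity
falls to or below $(1-\mathrm{drop})\times$ baseline and reports the
union of covered positions as TSS-relative intervals, since elements —
not window starts — are the objects of interest. Windows are indexed by
their 1-based start; output headers record the convention.

Profiles are computed on true promoters and report sensitivity; the
number of random draws averaged per window and the substitution
composition are package choices (the source procedure specifies
neither). For single-convolutional-layer models the implementation
reuses the base forward pass and recomputes only the activation columns
the substituted window overlaps; this is an exact optimization (the
full and incremental paths produce identical profiles for identical
seeds, which the test suite asserts) and makes profiling a 251-nt,
100-promoter, 10-replicate run a matter of seconds.

Per-position information content accompanies the profiles:
$IC_j = 2 + \sum_b p_{jb} \log_2 p_{jb}$ bits from the observed base
frequencies at column $j$ (N excluded from counts; $0 \log 0 = 0$), the
height scale of a sequence logo — 2 bits for an invariant column, 0 for
uniform. The Schneider-style small-sample correction
$e(n) = 3/(2 \ln(2) n)$ is available but off by default; at the corpus
sizes used here it is negligible.

## Problem sizes and numerical choices

The canonical end-to-end configuration used by the test suite and the
acceptance script: 1000 promoters + 1000 negatives in 251-nt windows,
consensus-only TATA at −30, split 70/10/20, one conv layer of 32
length-11 filters pooled by 8, dense 128, batch 16, at most 25 epochs
with patience 6. On one CPU a training run takes well under a minute and
the window-6, 10-replicate profile of 100 test promoters about fifteen
seconds. Across five seeds this configuration reaches held-out
sensitivity and specificity of 0.95 or better, while the same pipeline on
label-shuffled data stays at chance (accuracy 0.40–0.60 on 400 test
examples) — both asserted by the suite, not quoted from anywhere.

Degenerate inputs are errors, not warnings: empty promoter sets,
windows longer than the sequence, zero-baseline profiles, unlabeled
records in splits, classes with fewer than 10 members, zero CC marginals.
Score ties classify as non-promoter. Pooling drops trailing positions
that do not fill a window. Model files are single self-describing
archives with a format-version field; loads of truncated or foreign
files fail with explicit errors, and save/load round trips are bit-exact.

The two-element demonstration (mirroring the two-dip pattern reported
for plant non-TATA promoters) plants a TATA-box at −30 and an
initiator-like element at −1 in every promoter, and mixes the negative
class from background plus single-motif windows. That mixture makes each
element individually insufficient, so an accurate classifier must use
both and the profile necessarily dips twice; with pure background
negatives either motif alone separates the classes and a well-trained
network may legitimately ignore the other.

## Known limitations

* The engine is CPU-only, dense-algebra R; it is sized for desk-scale
  corpora (thousands of windows), not genome scans.
* Two independent sigmoid outputs trained on sum-normalized
  cross-entropy are faithful to the described architecture but are not a
  calibrated posterior; scores order sequences, they are not
  probabilities.
* Training determinism is exact for a fixed BLAS; across different BLAS
  builds, bit-level differences in accumulation order can change trained
  weights, so cross-machine comparisons should use the statistical
  assertions the suite uses, not bit equality.
* The synthetic negatives are far easier than real non-promoter
  sequence; accuracy on these corpora says nothing quantitative about
  EPD- or RegulonDB-scale performance.
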