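# promcnn

Convolutional neural network recognition of promoter sequences, with
random-substitution localization of the promoter elements a trained
network relies on.

## What it is for

Promoters are the DNA regions around transcription start sites (TSS)
that direct transcription initiation. Their computational recognition is
hard because the underlying signals are short, degenerate, positionally
constrained motifs — a TATA-box ~30 bp upstream of the TSS in a subset of
eukaryotic promoters, the bacterial −10/−35 hexamers, initiator elements
straddling the TSS — present in varying combinations. `promcnn` is for
researchers who want a sequence-only classifier of fixed-length,
TSS-anchored windows (81 nt spanning −60..+20 for bacteria, 251 nt
spanning −200..+50 for eukaryotes) and a principled way to ask *which
positions* a trained classifier depends on.

The core model is a convolutional network: one-hot encoded sequence
(A = (1,0,0,0), T = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1)) feeds one or
more valid (unpadded, stride-1) convolutional layers with ReLU and
non-overlapping max-pooling, described by `n_filters, filter_length,
pool_size` triplets (`"200, 21, 4"`; `/` separates layers), then a dense
ReLU layer (128 neurons) and a two-neuron sigmoid output (promoter,
non-promoter). Training uses minibatch Adam (batch 16) on categorical
cross-entropy, with a 70/10/20 stratified train/validation/test split and
validation-based epoch selection to limit over-fitting. Evaluation
reports sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP),
accuracy AC, and the Matthews-style correlation coefficient

    CC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

For element discovery, the *random-substitution profile* slides a short
window (default 6 nt) across the promoter set, replaces it with random
bases (averaged over replicates), re-classifies, and plots the surviving
sensitivity per window position: dips localize positionally conserved
elements, and `profile_minima()` turns them into TSS-relative intervals.
Per-position information content (sequence-logo heights, in bits)
complements the profile.

A synthetic corpus generator plants position-weight-matrix motifs at
fixed TSS-relative offsets on an i.i.d. background, so the entire
pipeline is testable end-to-end without any external downloads.

## Worked example

```r
library(promcnn)

# 1000 promoters carrying a consensus TATA-box at TSS-relative -30,
# 1000 background negatives, 251-nt windows with the TSS at position 201
corpus <- generate_corpus(corpus_spec(
  1000, 1000, window_length = 251, tss_index = 201,
  motifs = list(motif_tata(strength = 1)), seed = 1))

split <- split_dataset(corpus, seed = 1)
fit <- train(parse_architecture("32, 11, 8", 251), split,
             train_config(batch_size = 16, max_epochs = 25,
                          patience = 6, seed = 1))
evaluate(fit$model, split$test)
#> confusion counts: TP=200 FP=1 TN=199 FN=0
#> Sn = 1.00  Sp = 0.99  AC = 1.00  CC = 1.00

# where does the model look? substitute a sliding 6-nt window with
# random sequence and watch the sensitivity
proms <- split$test[split$test$label == "promoter", ][1:100, ]
prof <- substitution_profile(fit$model, proms, window_length = 6,
                             replicates = 10, seed = 7)
profile_minima(prof, drop_fraction = 0.5)
#>   start end tss_start tss_end min_sensitivity
#> 1   167 181       -34     -20           0.004
```

The single reported interval, TSS-relative −34..−20, covers exactly the
planted TATA element (−30..−23) plus the window-width smearing expected
from a 6-nt substitution window: destroying any part of the motif
abolishes promoter calls (sensitivity drops to ~0), while substituting
anywhere else leaves sensitivity at the 1.0 baseline.

The same workflow is available from the shell via the installed
launcher: `exec/promcnn simulate | train | predict | profile | evaluate`
(run any subcommand with `--help`).

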