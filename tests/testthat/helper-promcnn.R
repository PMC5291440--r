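# Shared fixtures, built in code at test time.

random_dna <- function(n, len, seed = NULL) {
  promcnn:::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = ""), character(1))
  })
}

# Small separable corpus: degenerate (consensus-only) TATA PWM at -30 in
# a 251-nt window, uniform background negatives.
tiny_separable_corpus <- function(n_per_class = 150, seed = 5,
                                  strength = 1) {
  generate_corpus(corpus_spec(
    n_per_class, n_per_class, window_length = 251, tss_index = 201,
    motifs = list(motif_tata(strength = strength)), seed = seed))
}

# Exact rule-based classifier: promoter iff `consensus` occupies 1-based
# positions start..(start + nchar - 1).
positional_match_classifier <- function(consensus, start) {
  force(consensus); force(start)
  function(sequences) {
    substr(sequences, start, start + nchar(consensus) - 1L) == consensus
  }
}

# Brute-force sliding dot product W x + b for a single one-hot matrix and
# a (L*4) x 1 filter; the independent convolution oracle.
brute_conv <- function(X, W, b, L) {
  n <- nrow(X)
  vapply(seq_len(n - L + 1L), function(i) {
    acc <- 0
    for (d in 1:4)
      for (l in 1:L)
        acc <- acc + W[(d - 1L) * L + l, 1L] * X[i + l - 1L, d]
    acc + b
  }, numeric(1))
}

# The canonical study corpus: 1000 promoters with the consensus-only
# TATA-box at TSS-relative -30 (jitter 0) in 251-nt windows, 1000
# background negatives; one-layer 32 x 11 model, 70/10/20 split, batch 16.
canonical_corpus <- function(seed)
  generate_corpus(corpus_spec(1000, 1000, window_length = 251,
                              tss_index = 201,
                              motifs = list(motif_tata(strength = 1)),
                              seed = seed))

.fit_cache <- new.env(parent = emptyenv())

canonical_fit <- function(seed) {
  key <- as.character(seed)
  if (is.null(.fit_cache[[key]])) {
    split <- split_dataset(canonical_corpus(seed), seed = seed)
    fit <- train(parse_architecture("32, 11, 8", 251), split,
                 train_config(batch_size = 16, max_epochs = 25,
                              patience = 6, seed = seed))
    .fit_cache[[key]] <- list(split = split, fit = fit)
  }
  .fit_cache[[key]]
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
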