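# Synthetic promoter corpora: PWM motifs planted at TSS-relative offsets
# on an i.i.d. background, and motif-free negatives.

#' Define a positional motif model
#'
#' A motif is a position weight matrix (PWM) plus a fixed TSS-relative
#' offset of its first position, with optional uniform positional jitter.
#' Offsets use the package's TSS-relative convention (TSS = 0): a TATA-box
#' at offset -30 inside a 251-nt window with `tss_index` 201 starts at
#' 1-based position 171.
#'
#' @param name motif name (free text).
#' @param pwm numeric matrix, width x 4, columns in A,T,G,C order, each row
#'   a probability vector.
#' @param offset TSS-relative coordinate of the motif's first position.
#' @param offset_jitter nonnegative integer; the planted start is shifted by
#'   a uniform integer in `[-offset_jitter, offset_jitter]` per record.
#' @return an object of class `promcnn_motif`.
#' @examples
#' motif_model("TATA-box", consensus_pwm("TATAAAAG"), offset = -30)
#' @export
motif_model <- function(name, pwm, offset, offset_jitter = 0L) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L)
    stop_config("PWM for motif '%s' must have 4 columns (A,T,G,C)", name)
  if (any(pwm < 0))
    stop_config("PWM for motif '%s' has negative entries", name)
  if (any(abs(rowSums(pwm) - 1) > 1e-9))
    stop_config("PWM row %d of motif '%s' sums to %.12f, not 1",
                which(abs(rowSums(pwm) - 1) > 1e-9)[1L], name,
                rowSums(pwm)[which(abs(rowSums(pwm) - 1) > 1e-9)[1L]])
  offset_jitter <- as.integer(offset_jitter)
  if (offset_jitter < 0L)
    stop_config("offset_jitter must be >= 0, got %d", offset_jitter)
  colnames(pwm) <- DNA_BASES
  structure(list(name = name, pwm = pwm, offset = as.integer(offset),
                 offset_jitter = offset_jitter),
            class = "promcnn_motif")
}

#' Build a consensus-dominated PWM
#'
#' Each position puts probability `strength` on the consensus base and
#' splits the remainder evenly over the other three.
#'
#' @param consensus consensus string over A/C/G/T.
#' @param strength probability mass on the consensus base (default 0.85).
#' @return a width x 4 PWM matrix (columns A,T,G,C).
#' @export
consensus_pwm <- function(consensus, strength = 0.85) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx))
    stop_config("consensus '%s' contains a base outside A/C/G/T", consensus)
  pwm <- matrix((1 - strength) / 3, nrow = length(chars), ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
  pwm[cbind(seq_along(idx), idx)] <- strength
  pwm
}

#' Built-in motif fixtures
#'
#' Consensus-weighted PWMs for classic positional promoter elements, meant
#' as test fixtures for the synthetic generator, not as claims about
#' biology: a TATA-box (8 nt at -30), an initiator-like element (4 nt
#' straddling the TSS at -1), and the bacterial -10 and -35 hexamers.
#'
#' @param strength consensus probability passed to [consensus_pwm()].
#' @param offset_jitter positional jitter passed to [motif_model()].
#' @return a `promcnn_motif`.
#' @name builtin_motifs
NULL

#' @rdname builtin_motifs
#' @export
motif_tata <- function(strength = 0.85, offset_jitter = 0L)
  motif_model("TATA-box", consensus_pwm("TATAAAAG", strength),
              offset = -30L, offset_jitter = offset_jitter)

#' @rdname builtin_motifs
#' @export
motif_inr <- function(strength = 0.85, offset_jitter = 0L)
  motif_model("Inr-like", consensus_pwm("CAGT", strength),
              offset = -1L, offset_jitter = offset_jitter)

#' @rdname builtin_motifs
#' @export
motif_minus10 <- function(strength = 0.85, offset_jitter = 0L)
  motif_model("-10 box", consensus_pwm("TATAAT", strength),
              offset = -10L, offset_jitter = offset_jitter)

#' @rdname builtin_motifs
#' @export
motif_minus35 <- function(strength = 0.85, offset_jitter = 0L)
  motif_model("-35 box", consensus_pwm("TTGACA", strength),
              offset = -35L, offset_jitter = offset_jitter)

builtin_motif <- function(name, ...) {
  switch(name,
         tata = motif_tata(...), inr = motif_inr(...),
         minus10 = motif_minus10(...), minus35 = motif_minus35(...),
         stop_config("unknown built-in motif '%s' (tata/inr/minus10/minus35)",
                     name))
}

#' Specify a synthetic corpus
#'
#' @param n_promoters,n_nonpromoters record counts per class.
#' @param window_length window length in nt (81 for the bacterial
#'   convention -60..+20, 251 for the eukaryotic -200..+50).
#' @param tss_index 1-based TSS position within the window (61 or 201 for
#'   the conventions above).
#' @param motifs list of `promcnn_motif` planted in promoters only.
#' @param background length-4 probability vector over A,T,G,C for the
#'   i.i.d. background.
#' @param negative_mode `"background"` for i.i.d. background negatives, or
#'   `"coding-like"` for a 3-periodic base composition that mimics the
#'   codon structure of coding sequence.
#' @param seed integer seed controlling every draw.
#' @return an object of class `promcnn_corpus_spec`.
#' @export
corpus_spec <- function(n_promoters, n_nonpromoters,
                        window_length = 251L, tss_index = 201L,
                        motifs = list(motif_tata()),
                        background = rep(0.25, 4),
                        negative_mode = c("background", "coding-like"),
                        seed = 1L) {
  negative_mode <- match.arg(negative_mode)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop_config("background must be 4 nonnegative probabilities summing to 1")
  window_length <- as.integer(window_length)
  tss_index <- as.integer(tss_index)
  if (tss_index < 1L || tss_index > window_length)
    stop_config("tss_index %d outside window of length %d",
                tss_index, window_length)
  for (m in motifs) {
    if (!inherits(m, "promcnn_motif"))
      stop_config("motifs must be promcnn_motif objects")
    w <- nrow(m$pwm)
    lo <- tss_index + m$offset - m$offset_jitter
    hi <- tss_index + m$offset + m$offset_jitter + w - 1L
    if (lo < 1L || hi > window_length)
      stop_config(paste0("motif '%s' (offset %d, jitter %d, width %d) spans ",
                         "positions %d..%d, outside window 1..%d"),
                  m$name, m$offset, m$offset_jitter, w, lo, hi, window_length)
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 n_nonpromoters = as.integer(n_nonpromoters),
                 window_length = window_length, tss_index = tss_index,
                 motifs = motifs, background = as.numeric(background),
                 negative_mode = negative_mode, seed = as.integer(seed)),
            class = "promcnn_corpus_spec")
}

#' Sample one realization of a motif
#'
#' Each position is drawn independently from its PWM row.
#'
#' @param motif a `promcnn_motif`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a string of the motif's width.
#' @export
sample_motif <- function(motif, seed = NULL) {
  with_seed(seed, {
    paste0(vapply(seq_len(nrow(motif$pwm)), function(i)
      sample(DNA_BASES, 1L, prob = motif$pwm[i, ]), character(1)),
      collapse = "")
  })
}

# Character matrix (n x len) of i.i.d. background sequence.
background_chars <- function(n, len, probs) {
  matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = probs),
         nrow = n, ncol = len)
}

# 3-periodic composition loosely shaped like coding sequence: G/A-rich
# first codon position, even second, pyrimidine-leaning third.
coding_like_chars <- function(n, len) {
  comp <- list(c(A = 0.32, T = 0.14, G = 0.34, C = 0.20),
               c(A = 0.30, T = 0.27, G = 0.19, C = 0.24),
               c(A = 0.17, T = 0.28, G = 0.22, C = 0.33))
  m <- matrix("", nrow = n, ncol = len)
  for (phase in 1:3) {
    cols <- seq(phase, len, by = 3L)
    m[, cols] <- sample(DNA_BASES, n * length(cols), replace = TRUE,
                        prob = comp[[phase]])
  }
  m
}

#' Generate a labeled synthetic corpus
#'
#' Promoter records are background draws with every motif's sampled
#' realization overwritten at its (jittered) TSS-relative offset;
#' non-promoter records are motif-free background (or coding-like, see
#' [corpus_spec()]). Byte-identical output for identical specs.
#'
#' @param spec a `promcnn_corpus_spec`.
#' @return a labeled record `data.frame` with `n_promoters` promoter rows
#'   followed by `n_nonpromoters` nonpromoter rows.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "promcnn_corpus_spec"))
  with_seed(spec$seed, {
    len <- spec$window_length
    np <- spec$n_promoters
    nn <- spec$n_nonpromoters
    prom <- if (np > 0L) {
      m <- background_chars(np, len, spec$background)
      for (mot in spec$motifs) {
        w <- nrow(mot$pwm)
        shifts <- if (mot$offset_jitter > 0L)
          sample(seq(-mot$offset_jitter, mot$offset_jitter), np,
                 replace = TRUE)
        else rep(0L, np)
        starts <- spec$tss_index + mot$offset + shifts
        # draw all positions for all records from the PWM at once
        draws <- vapply(seq_len(w), function(i)
          sample(DNA_BASES, np, replace = TRUE, prob = mot$pwm[i, ]),
          character(np))
        draws <- matrix(draws, nrow = np)
        for (i in seq_len(w))
          m[cbind(seq_len(np), starts + i - 1L)] <- draws[, i]
      }
      m
    } else matrix("", 0L, len)
    neg <- if (nn > 0L) {
      if (spec$negative_mode == "coding-like") coding_like_chars(nn, len)
      else background_chars(nn, len, spec$background)
    } else matrix("", 0L, len)
    seqs <- c(apply(prom, 1L, paste0, collapse = ""),
              apply(neg, 1L, paste0, collapse = ""))
    ids <- c(sprintf("prom_%05d", seq_len(np)),
             sprintf("nonprom_%05d", seq_len(nn)))
    labels <- c(rep("promoter", np), rep("nonpromoter", nn))
    sequence_records(ids, seqs, labels, spec$tss_index)
  })
}

#' Write a corpus as two FASTA files plus a label manifest
#'
#' @param records labeled record `data.frame`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_corpus <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(promoters = file.path(dir, "promoters.fa"),
             nonpromoters = file.path(dir, "nonpromoters.fa"),
             labels = file.path(dir, "labels.tsv"))
  write_fasta(records[records$label == "promoter", , drop = FALSE],
              paths[["promoters"]])
  write_fasta(records[records$label == "nonpromoter", , drop = FALSE],
              paths[["nonpromoters"]])
  write_label_manifest(records, paths[["labels"]])
  invisible(paths)
}

#' Read or write a PWM as tab-delimited text
#'
#' Rows are motif positions; the four columns are headed A, T, G, C.
#'
#' @param path file path.
#' @return for `read_pwm`, a width x 4 PWM matrix.
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop_data("PWM file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!identical(toupper(names(df)), DNA_BASES))
    stop_data("PWM file '%s' must have columns A, T, G, C (got %s)",
              path, paste(names(df), collapse = ","))
  m <- as.matrix(df)
  colnames(m) <- DNA_BASES
  m
}

#' @rdname read_pwm
#' @param pwm a width x 4 PWM matrix (columns A,T,G,C).
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(pwm)
  names(df) <- DNA_BASES
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motifs from MEME minimal motif format
#'
#' Parses the `letter-probability matrix` blocks of a MEME minimal-format
#' file (alphabet ACGT). MEME orders columns A, C, G, T; they are reordered
#' to this package's A, T, G, C convention.
#'
#' @param path MEME minimal-format file.
#' @param offset,offset_jitter planting coordinates to attach to every
#'   parsed motif (MEME files carry none).
#' @return a list of `promcnn_motif`.
#' @export
read_meme <- function(path, offset = 0L, offset_jitter = 0L) {
  if (!file.exists(path)) stop_data("MEME file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L)
    stop_data("no MOTIF block found in '%s'", path)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[starts[k]])
    hdr <- grep("letter-probability matrix", lines[seq(starts[k],
                length(lines))], fixed = TRUE)[1L]
    if (is.na(hdr))
      stop_data("motif '%s' in '%s' has no letter-probability matrix",
                name, path)
    hdr <- starts[k] + hdr - 1L
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1",
                                         lines[hdr])))
    if (is.na(w)) stop_data("cannot parse motif width for '%s'", name)
    rows <- lines[(hdr + 1L):(hdr + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(lengths(vals) != 4L) || anyNA(unlist(vals)))
      stop_data("malformed probability row in motif '%s'", name)
    acgt <- do.call(rbind, vals)
    pwm <- acgt[, c(1L, 4L, 3L, 2L), drop = FALSE]   # A,C,G,T -> A,T,G,C
    # renormalize tiny rounding drift typical of MEME files
    pwm <- pwm / rowSums(pwm)
    out[[k]] <- motif_model(name, pwm, offset, offset_jitter)
  }
  out
}
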