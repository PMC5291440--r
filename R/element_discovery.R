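# Random-substitution profiling of a trained classifier, plus
# sequence-logo information content.

# Normalize a model or a plain function into a predictor over a character
# matrix of sequences (n x len): returns logical is-promoter calls.
# Functions receive a character vector of sequences — this lets exact
# rule-based oracle classifiers stand in for a trained network.
as_predictor <- function(model) {
  if (inherits(model, "promcnn_model")) {
    function(char_mat) {
      arr <- encode_set(collapse_rows(char_mat))
      scores <- forward_scores(model, arr)
      scores[, 1L] > scores[, 2L]
    }
  } else if (is.function(model)) {
    function(char_mat) {
      res <- model(collapse_rows(char_mat))
      as.logical(res)
    }
  } else {
    stop_config("model must be a promcnn_model or a classifier function")
  }
}

collapse_rows <- function(char_mat) {
  apply(char_mat, 1L, paste0, collapse = "")
}

#' Random-substitution sensitivity profile
#'
#' Slides a window of `window_length` nt across the promoter set with
#' stride 1. At each window start, the window of every promoter is
#' replaced by a freshly drawn random sequence (independently per record
#' and per replicate), the whole set is re-classified, and the
#' sensitivity (fraction still called promoter) is averaged over
#' replicates. Dips in the profile localize positionally conserved
#' elements the classifier relies on — the TATA-box, bacterial -10/-35
#' boxes and similar fixed-position motifs.
#'
#' @param model a trained `promcnn_model`, or a classifier function taking
#'   a character vector of sequences and returning logical promoter calls
#'   (useful for exact rule-based oracles).
#' @param promoters record `data.frame` of true promoter windows, all of
#'   the model's input length.
#' @param window_length substitution window in nt (default 6).
#' @param replicates independent random substitutions averaged per window
#'   (default 10).
#' @param seed integer seed for the random replacement bases.
#' @param base_probs substitution base composition over A,T,G,C; default
#'   uniform.
#' @param tss_index 1-based TSS position used for TSS-relative
#'   coordinates; defaults to the records' `tss_index`.
#' @param method `"auto"` (default) uses incremental recomputation for
#'   single-conv-layer models — a substituted window only perturbs the
#'   activation columns it overlaps, so the rest of the base forward pass
#'   is reused — and the full forward pass otherwise. `"incremental"` and
#'   `"full"` force a path; both give the same profile.
#' @return an object of class `promcnn_profile`: window starts (1-based
#'   and TSS-relative), mean sensitivity and its standard error per
#'   window, the unsubstituted baseline sensitivity, and the run
#'   parameters.
#' @export
substitution_profile <- function(model, promoters, window_length = 6L,
                                 replicates = 10L, seed = 1L,
                                 base_probs = rep(0.25, 4),
                                 tss_index = NULL,
                                 method = c("auto", "incremental",
                                            "full")) {
  method <- match.arg(method)
  if (nrow(promoters) == 0L)
    stop_data("substitution_profile needs a non-empty promoter set")
  len <- unique(nchar(promoters$sequence))
  if (length(len) != 1L)
    stop_data("promoter sequences have unequal lengths")
  window_length <- as.integer(window_length)
  if (window_length < 1L || window_length > len)
    stop_data("window_length %d outside 1..%d", window_length, len)
  if (is.null(tss_index)) {
    tss_index <- unique(promoters$tss_index)
    tss_index <- tss_index[!is.na(tss_index)]
    if (length(tss_index) != 1L) tss_index <- NA_integer_
  }
  n <- nrow(promoters)
  starts <- seq_len(len - window_length + 1L)
  nrep <- as.integer(replicates)
  rep_rows <- rep(seq_len(n), nrep)
  sens_mean <- numeric(length(starts))
  sens_se <- numeric(length(starts))
  if (inherits(model, "promcnn_model")) {
    # substitute directly in one-hot space, no string churn
    if (model$spec$input_length != len)
      stop_data("promoters are %d nt; model expects %d", len,
                model$spec$input_length)
    if (method == "incremental" && length(model$conv) != 1L)
      stop_config("incremental profiling needs a single-conv-layer model")
    incremental <- method == "incremental" ||
      (method == "auto" && length(model$conv) == 1L)
    X0 <- encode_set(promoters$sequence)
    base_calls <- {
      sc <- forward_scores(model, X0)
      sc[, 1L] > sc[, 2L]
    }
    baseline <- mean(base_calls)
    ns <- n * nrep
    w <- window_length
    if (incremental) {
      res <- profile_incremental(model, X0, starts, w, n, nrep, rep_rows,
                                 base_probs, seed)
      sens_mean <- res$mean
      sens_se <- res$se
    } else {
      Xrep <- X0[, , rep_rows, drop = FALSE]
      with_seed(seed, {
        for (k in seq_along(starts)) {
          s <- starts[k]
          Xw <- Xrep
          Xw[s:(s + w - 1L), , ] <- 0
          draws <- sample.int(4L, ns * w, replace = TRUE,
                              prob = base_probs)
          Xw[cbind(rep(s:(s + w - 1L), times = ns), draws,
                   rep(seq_len(ns), each = w))] <- 1
          sc <- forward_scores(model, Xw)
          per_rep <- colMeans(matrix(sc[, 1L] > sc[, 2L], nrow = n,
                                     ncol = nrep))
          sens_mean[k] <- mean(per_rep)
          sens_se[k] <- if (nrep > 1L) sd(per_rep) / sqrt(nrep)
                        else NA_real_
        }
      })
    }
  } else {
    predict_fun <- as_predictor(model)
    chars <- matrix(unlist(strsplit(promoters$sequence, "", fixed = TRUE),
                           use.names = FALSE), nrow = len)
    chars <- t(chars)                                 # n x len
    baseline <- mean(predict_fun(chars))
    with_seed(seed, {
      for (k in seq_along(starts)) {
        s <- starts[k]
        sub <- chars[rep_rows, , drop = FALSE]
        sub[, s:(s + window_length - 1L)] <-
          sample(DNA_BASES, n * nrep * window_length, replace = TRUE,
                 prob = base_probs)
        calls <- predict_fun(sub)
        per_rep <- colMeans(matrix(calls, nrow = n, ncol = nrep))
        sens_mean[k] <- mean(per_rep)
        sens_se[k] <- if (nrep > 1L) sd(per_rep) / sqrt(nrep) else NA_real_
      }
    })
  }
  structure(list(window_length = window_length,
                 window_starts = starts,
                 tss_relative_starts = if (is.na(tss_index))
                   rep(NA_integer_, length(starts))
                 else tss_relative(starts, tss_index),
                 sensitivity = sens_mean, se = sens_se,
                 baseline_sensitivity = baseline,
                 replicates = nrep, seed = as.integer(seed),
                 n_promoters = n, tss_index = tss_index),
            class = "promcnn_profile")
}

# Incremental substitution profiling for single-conv-layer models.
#
# Substituting window [s, s+w-1] only changes conv activation columns
# a1..a2 with a1 = max(1, s-L+1), a2 = min(out_len, s+w-1); everything
# else in the base forward pass is reused. The random draws consume the
# RNG in exactly the same order as the full path, so both paths give the
# same profile for the same seed.
profile_incremental <- function(model, X0, starts, w, n, nrep, rep_rows,
                                base_probs, seed) {
  spec <- model$spec
  len <- spec$input_length
  Lf <- spec$conv_layers[[1L]]$filter_length
  p <- max(spec$conv_layers[[1L]]$pool_size, 1L)
  nF <- spec$conv_layers[[1L]]$n_filters
  out_len <- len - Lf + 1L
  out_p <- out_len %/% p
  ns <- n * nrep
  W <- model$conv[[1L]]$W
  b <- model$conv[[1L]]$b
  W1 <- model$dense$W
  W2 <- model$output$W
  b2 <- model$output$b

  # base forward pass, caching the pre-pool activation map
  Xflat <- X0
  dim(Xflat) <- c(len * 4L, n)
  cf <- conv_forward(Xflat, W, b, len, 4L, Lf, spec$conv_layers[[1L]]$pool_size,
                     n, keep = TRUE)
  A0 <- array(cf$Amap, dim = c(out_len, n, nF))   # post-ReLU, pre-pool
  Xf0 <- t(cf$Xout)                               # n x features
  Hpre0 <- Xf0 %*% W1
  Hpre0 <- Hpre0 + rep(model$dense$b, each = n)

  sens_mean <- numeric(length(starts))
  sens_se <- numeric(length(starts))
  score_calls <- function(Hpre) {
    H <- Hpre
    H[H < 0] <- 0
    Z <- H %*% W2
    Z <- Z + rep(b2, each = nrow(Z))
    Z[, 1L] > Z[, 2L]        # sigmoid is monotone; compare pre-activations
  }
  with_seed(seed, {
    for (k in seq_along(starts)) {
      s <- starts[k]
      a1 <- max(1L, s - Lf + 1L)
      a2 <- min(out_len, s + w - 1L)
      apos <- a1:a2
      slab <- a1:(a2 + Lf - 1L)
      slab_len <- length(slab)
      # modified one-hot slab for every record x replicate
      S <- X0[slab, , rep_rows, drop = FALSE]
      wr <- (s:(s + w - 1L)) - a1 + 1L
      S[wr, , ] <- 0
      draws <- sample.int(4L, ns * w, replace = TRUE, prob = base_probs)
      S[cbind(rep(wr, times = ns), draws, rep(seq_len(ns), each = w))] <- 1
      dim(S) <- c(slab_len * 4L, ns)
      aff <- conv_forward(S, W, b, slab_len, 4L, Lf, 0L, ns, keep = TRUE)
      Aaff <- array(aff$Amap, dim = c(length(apos), ns, nF))
      # affected pooled groups (positions past out_p * p are dropped by
      # pooling and change nothing)
      g_set <- unique((apos - 1L) %/% p) + 1L
      g_set <- g_set[g_set <= out_p]
      if (length(g_set) == 0L) {
        calls <- score_calls(Hpre0[rep_rows, , drop = FALSE])
      } else {
        ng <- length(g_set)
        D <- array(0, dim = c(ns, ng, nF))
        for (gi in seq_len(ng)) {
          g <- g_set[gi]
          gp <- ((g - 1L) * p + 1L):(g * p)
          G <- A0[gp, rep_rows, , drop = FALSE]     # p x ns x nF
          inside <- which(gp %in% apos)
          G[inside, , ] <- Aaff[match(gp[inside], apos), , , drop = FALSE]
          best <- G[1L, , ]
          if (p > 1L) for (i in 2:p) best <- pmax(best, G[i, , ])
          base_best <- A0[gp[1L], rep_rows, ]
          if (p > 1L) for (i in 2:p)
            base_best <- pmax(base_best, A0[gp[i], rep_rows, ])
          D[, gi, ] <- best - base_best
        }
        dim(D) <- c(ns, ng * nF)
        rows_idx <- as.vector(outer(g_set, (seq_len(nF) - 1L) * out_p,
                                    `+`))
        Hpre <- Hpre0[rep_rows, , drop = FALSE] +
          D %*% W1[rows_idx, , drop = FALSE]
        calls <- score_calls(Hpre)
      }
      per_rep <- colMeans(matrix(calls, nrow = n, ncol = nrep))
      sens_mean[k] <- mean(per_rep)
      sens_se[k] <- if (nrep > 1L) sd(per_rep) / sqrt(nrep) else NA_real_
    }
  })
  list(mean = sens_mean, se = sens_se)
}

#' @export
print.promcnn_profile <- function(x, ...) {
  cat(sprintf(paste0("substitution profile: %d windows of %d nt, ",
                     "%d promoters x %d replicates, baseline Sn %.3f, ",
                     "min Sn %.3f at start %d\n"),
              length(x$window_starts), x$window_length, x$n_promoters,
              x$replicates, x$baseline_sensitivity,
              min(x$sensitivity),
              x$window_starts[which.min(x$sensitivity)]))
  invisible(x)
}

#' @export
as.data.frame.promcnn_profile <- function(x, ...) {
  data.frame(window_start = x$window_starts,
             tss_relative_start = x$tss_relative_starts,
             sensitivity = x$sensitivity, se = x$se,
             replicates = x$replicates)
}

#' Write a profile as delimited text
#'
#' Single commented header line records the conventions (windows indexed
#' by their 1-based start; TSS-relative coordinate of position p is
#' p - tss_index).
#'
#' @param profile a `promcnn_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(paste0("# promcnn substitution profile | window=%d ",
                            "(indexed by 1-based start) | replicates=%d | ",
                            "seed=%d | baseline_sensitivity=%.6f | ",
                            "tss_index=%s | columns: window_start ",
                            "tss_relative_start mean_sensitivity se ",
                            "replicates"),
                     profile$window_length, profile$replicates,
                     profile$seed, profile$baseline_sensitivity,
                     ifelse(is.na(profile$tss_index), "NA",
                            profile$tss_index)),
             con)
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locate profile minima as element intervals
#'
#' Windows whose mean sensitivity falls to or below
#' `(1 - drop_fraction) * baseline` are implicated; maximal runs of
#' consecutive implicated window starts are merged, and each run is
#' reported as the union of the sequence positions its windows cover,
#' in both 1-based and TSS-relative coordinates.
#'
#' @param profile a `promcnn_profile`.
#' @param drop_fraction fraction of the baseline sensitivity that must be
#'   lost for a window to be implicated (default 0.5).
#' @return a `data.frame` with columns `start`, `end` (1-based),
#'   `tss_start`, `tss_end` (TSS-relative), `min_sensitivity`; zero rows
#'   when no window drops.
#' @export
profile_minima <- function(profile, drop_fraction = 0.5) {
  stopifnot(inherits(profile, "promcnn_profile"))
  if (profile$baseline_sensitivity == 0)
    stop_data("profile baseline sensitivity is 0; minima are undefined")
  thr <- (1 - drop_fraction) * profile$baseline_sensitivity
  hit <- profile$sensitivity <= thr
  if (!any(hit))
    return(data.frame(start = integer(), end = integer(),
                      tss_start = integer(), tss_end = integer(),
                      min_sensitivity = numeric()))
  r <- rle(hit)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(i) {
    w <- profile$window_starts[starts_at[i]:ends_at[i]]
    lo <- min(w)
    hi <- max(w) + profile$window_length - 1L
    data.frame(start = lo, end = hi,
               tss_start = if (is.na(profile$tss_index)) NA_integer_
                           else tss_relative(lo, profile$tss_index),
               tss_end = if (is.na(profile$tss_index)) NA_integer_
                         else tss_relative(hi, profile$tss_index),
               min_sensitivity =
                 min(profile$sensitivity[starts_at[i]:ends_at[i]]))
  })
  do.call(rbind, out)
}

#' Per-position information content (sequence-logo heights)
#'
#' For each alignment column, IC = 2 + sum_b p_b log2 p_b bits over the
#' observed base frequencies (0 log 0 = 0); N bases are excluded from the
#' column counts. An invariant column scores 2 bits, a uniform column 0.
#'
#' @param x record `data.frame` or character vector of equal-length
#'   sequences.
#' @param correction apply the Schneider-style small-sample correction
#'   e(n) = 3 / (2 ln(2) n) per column (clamped at 0)? Default `FALSE`;
#'   negligible at the corpus sizes the package targets.
#' @param tss_index optional TSS position for TSS-relative coordinates;
#'   defaults to the records' `tss_index` when `x` is a record set.
#' @return an object of class `promcnn_information_profile`: a list with
#'   `position`, `tss_relative`, `ic` (bits), `frequencies` (positions x
#'   4 matrix) and `n_sequences`.
#' @export
information_profile <- function(x, correction = FALSE, tss_index = NULL) {
  if (is.data.frame(x)) {
    if (is.null(tss_index)) {
      ti <- unique(x$tss_index)
      ti <- ti[!is.na(ti)]
      tss_index <- if (length(ti) == 1L) ti else NA_integer_
    }
    x <- x$sequence
  }
  if (length(x) == 0L) stop_data("information_profile needs sequences")
  if (is.null(tss_index)) tss_index <- NA_integer_
  len <- unique(nchar(x))
  if (length(len) != 1L)
    stop_data("sequences must be aligned (equal length)")
  chars <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                  nrow = len)                         # len x n
  freq <- matrix(0, nrow = len, ncol = 4L,
                 dimnames = list(NULL, DNA_BASES))
  counts_n <- numeric(len)
  for (b in seq_along(DNA_BASES))
    freq[, b] <- rowSums(chars == DNA_BASES[b])
  counts_n <- rowSums(freq)                           # N excluded
  if (any(counts_n == 0))
    stop_data("column %d contains only N bases", which(counts_n == 0)[1L])
  p <- freq / counts_n
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  ic <- 2 + rowSums(plogp)
  if (correction) ic <- pmax(ic - 3 / (2 * log(2) * counts_n), 0)
  structure(list(position = seq_len(len),
                 tss_relative = if (is.na(tss_index))
                   rep(NA_integer_, len) else
                   tss_relative(seq_len(len), tss_index),
                 ic = ic, frequencies = p,
                 n_sequences = length(x), correction = correction),
            class = "promcnn_information_profile")
}

#' @export
as.data.frame.promcnn_information_profile <- function(x, ...) {
  data.frame(position = x$position, tss_relative = x$tss_relative,
             x$frequencies, ic = x$ic)
}

#' Write an information profile as delimited text
#'
#' Per-position base frequencies plus IC in bits; consumable by standard
#' logo-drawing tools.
#'
#' @param profile a `promcnn_information_profile`.
#' @param path output path.
#' @export
write_information_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(paste0("# promcnn information profile | n=%d | ",
                            "correction=%s | columns: position ",
                            "tss_relative A T G C ic_bits"),
                     profile$n_sequences, profile$correction), con)
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
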