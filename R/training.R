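# Dataset splitting, Adam training with validation-based epoch selection,
# and evaluation.

#' Stratified train/validation/test split
#'
#' Splits a labeled record set 70/10/20 (train/validation/test) by
#' default, stratified so each part preserves the class ratio within
#' rounding, deterministic given the seed.
#'
#' @param records labeled record `data.frame` (no `NA` labels).
#' @param seed integer seed.
#' @param fractions named numeric vector summing to 1, fractions of the
#'   full set: `c(train = 0.70, validation = 0.10, test = 0.20)`.
#' @return an object of class `promcnn_split`: list with elements
#'   `train`, `validation`, `test`, plus `seed` and `fractions`.
#' @export
split_dataset <- function(records, seed = 1L,
                          fractions = c(train = 0.70, validation = 0.10,
                                        test = 0.20)) {
  if (anyNA(records$label))
    stop_data("record '%s' is unlabeled; every record needs a label",
              records$id[is.na(records$label)][1L])
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_config("split fractions must sum to 1")
  classes <- unique(records$label)
  for (cl in classes) {
    n_cl <- sum(records$label == cl)
    if (n_cl < 10L)
      stop_data(paste0("class '%s' has only %d records; need >= 10 ",
                       "(use a smaller split or more data)"), cl, n_cl)
  }
  with_seed(seed, {
    part <- character(nrow(records))
    for (cl in classes) {
      idx <- which(records$label == cl)
      idx <- sample(idx)
      n <- length(idx)
      n_test <- round(fractions[["test"]] * n)
      n_val <- round(fractions[["validation"]] * n)
      n_test <- max(n_test, 1L)
      n_val <- max(n_val, 1L)
      part[idx[seq_len(n_test)]] <- "test"
      part[idx[n_test + seq_len(n_val)]] <- "validation"
      part[idx[(n_test + n_val + 1L):n]] <- "train"
    }
    structure(list(train = records[part == "train", , drop = FALSE],
                   validation = records[part == "validation", , drop = FALSE],
                   test = records[part == "test", , drop = FALSE],
                   seed = as.integer(seed), fractions = fractions),
              class = "promcnn_split")
  })
}

#' @export
print.promcnn_split <- function(x, ...) {
  cat(sprintf("split: %d train / %d validation / %d test (seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size minibatch size (default 16).
#' @param max_epochs upper bound on training epochs.
#' @param learning_rate,beta1,beta2,epsilon Adam step-size parameters
#'   (standard defaults 1e-3, 0.9, 0.999, 1e-8).
#' @param patience stop after this many epochs without a new best
#'   validation accuracy.
#' @param seed integer seed driving initialization, shuffling and batch
#'   order.
#' @param clip_norm clip each minibatch gradient to this global L2 norm
#'   before the Adam step (`Inf` disables). The sum-normalized sigmoid
#'   output head has flat absorbing regions where both output neurons
#'   saturate; clipping prevents early overshoot into them.
#' @param class_weights optional named vector
#'   `c(promoter = , nonpromoter = )` of loss weights; `NULL` (default)
#'   trains unweighted.
#' @return an object of class `promcnn_train_config`.
#' @export
train_config <- function(batch_size = 16L, max_epochs = 30L,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, patience = 8L, seed = 1L,
                         clip_norm = 1, class_weights = NULL) {
  if (batch_size < 1L) stop_config("batch_size must be >= 1")
  if (max_epochs < 1L) stop_config("max_epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 patience = as.integer(patience), seed = as.integer(seed),
                 clip_norm = clip_norm, class_weights = class_weights),
            class = "promcnn_train_config")
}

# Global L2-norm gradient clipping across every parameter block.
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- sum(vapply(grads$conv, function(g) sum(g$W^2) + sum(g$b^2),
                   numeric(1))) +
    sum(grads$dense$W^2) + sum(grads$dense$b^2) +
    sum(grads$output$W^2) + sum(grads$output$b^2)
  nrm <- sqrt(sq)
  if (nrm <= max_norm) return(grads)
  sc <- max_norm / nrm
  grads$conv <- lapply(grads$conv, function(g)
    list(W = g$W * sc, b = g$b * sc))
  grads$dense <- list(W = grads$dense$W * sc, b = grads$dense$b * sc)
  grads$output <- list(W = grads$output$W * sc, b = grads$output$b * sc)
  grads
}

one_hot_targets <- function(labels) {
  t_pos <- as.numeric(labels == "promoter")
  cbind(t_pos, 1 - t_pos)
}

batch_accuracy <- function(scores, labels) {
  mean((scores[, 1L] > scores[, 2L]) == (labels == "promoter"))
}

#' Train a model
#'
#' Minibatch Adam on categorical cross-entropy. Each epoch the model is
#' scored on the validation part; the returned parameters are those of
#' the epoch with the highest validation accuracy (earliest on ties), not
#' necessarily the last epoch — this is how the number of learning epochs
#' is limited to avoid over-fitting. Training stops early after
#' `patience` epochs without improvement. Fully deterministic given the
#' config seed on a fixed BLAS.
#'
#' @param spec a `promcnn_model_spec` (or an already built
#'   `promcnn_model` to continue from its initialization).
#' @param split a `promcnn_split` with labeled train and validation parts.
#' @param config a `promcnn_train_config`.
#' @return a list with `model` (a trained `promcnn_model`, parameters
#'   from the selected epoch, `selected_epoch` set) and `history` (a
#'   `data.frame` with per-epoch `train_loss`, `train_accuracy`,
#'   `validation_accuracy`).
#' @export
train <- function(spec, split, config = train_config()) {
  stopifnot(inherits(split, "promcnn_split"),
            inherits(config, "promcnn_train_config"))
  model <- if (inherits(spec, "promcnn_model")) spec
           else build_model(spec, seed = config$seed)
  input_length <- model$spec$input_length
  if (nrow(split$validation) == 0L)
    stop_data("validation set is empty; epoch selection needs one")
  if (nrow(split$train) == 0L) stop_data("training set is empty")
  Xtr <- as_flat_batch(split$train, input_length)
  Ttr <- one_hot_targets(split$train$label)
  Xval <- as_flat_batch(split$validation, input_length)
  lab_val <- split$validation$label
  wts <- NULL
  if (!is.null(config$class_weights))
    wts <- unname(config$class_weights[split$train$label])
  n <- ncol(Xtr)
  state <- adam_init(model)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_accuracy = numeric(),
                     validation_accuracy = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL)
  with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        bi <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xtr[, bi, drop = FALSE]
        Tb <- Ttr[bi, , drop = FALSE]
        fw <- nn_forward(model, Xb, keep = TRUE)
        lg <- nn_loss_grad(fw$scores, Tb,
                           weights = if (is.null(wts)) NULL else wts[bi])
        grads <- nn_backward(model, fw, lg$dZ)
        grads <- clip_gradients(grads, config$clip_norm)
        upd <- adam_update(model, grads, state, config$learning_rate,
                           config$beta1, config$beta2, config$epsilon)
        model <- upd$model
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        ep_correct <- ep_correct +
          sum((fw$scores[, 1L] > fw$scores[, 2L]) == (Tb[, 1L] == 1))
      }
      val_scores <- forward_scores(model, Xval_array(Xval))
      val_acc <- batch_accuracy(val_scores, lab_val)
      hist[epoch, ] <- list(epoch, ep_loss / n, ep_correct / n, val_acc)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch,
                     params = model[c("conv", "dense", "output")])
      }
      if (epoch - best$epoch >= config$patience) break
    }
  })
  model[c("conv", "dense", "output")] <- best$params
  model$selected_epoch <- best$epoch
  model$train_config <- config
  list(model = model, history = hist)
}

# forward_scores expects records/arrays, not flat matrices; rewrap.
Xval_array <- function(Xflat) {
  len <- nrow(Xflat) / 4L
  array(Xflat, dim = c(len, 4L, ncol(Xflat)))
}

#' Evaluate a model on labeled records
#'
#' Scores every record, calls classes with [classify()], tallies against
#' the labels and reports Sn, Sp, AC and CC. Pure: repeated calls give
#' identical reports.
#'
#' @param model a `promcnn_model`.
#' @param records labeled record `data.frame`.
#' @return a `promcnn_report` (see [metrics_report()]); the per-record
#'   predictions are attached as attribute `predictions`.
#' @export
evaluate <- function(model, records) {
  if (anyNA(records$label))
    stop_data("evaluate needs labeled records")
  scores <- forward_scores(model, records)
  calls <- classify(scores)
  counts <- tally(records$label, calls$class)
  rep <- metrics_report(counts)
  attr(rep, "predictions") <- cbind(records[, c("id", "label")], calls)
  rep
}
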