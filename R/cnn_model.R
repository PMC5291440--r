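# Model construction, application and serialization.

MODEL_FORMAT_VERSION <- "1.0"

#' Build an untrained model from a spec
#'
#' Weights use seeded He-normal initialization (sd = sqrt(2/fan_in)) for
#' the ReLU conv and dense layers; the sigmoid output layer starts at
#' exactly zero (see Details in the methods vignette) and biases start at
#' zero. The scheme is recorded in the model metadata.
#'
#' @param spec a `promcnn_model_spec`.
#' @param seed integer seed; identical seeds give identical parameters.
#' @return an object of class `promcnn_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "promcnn_model_spec"))
  layer_lengths(spec)   # re-validate; errors name the offending layer
  with_seed(seed, {
    depth <- 4L
    conv <- lapply(spec$conv_layers, function(ly) {
      fan_in <- ly$filter_length * depth
      W <- matrix(rnorm(fan_in * ly$n_filters, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = ly$n_filters)
      depth <<- ly$n_filters
      list(W = W, b = rep(0, ly$n_filters))
    })
    ll <- layer_lengths(spec)
    n_feat <- ll$after_pool[nrow(ll)] * depth
    dense <- list(W = matrix(rnorm(n_feat * spec$dense_units,
                                   sd = sqrt(2 / n_feat)),
                             nrow = n_feat, ncol = spec$dense_units),
                  b = rep(0, spec$dense_units))
    # The output layer starts at zero so both sigmoid neurons begin at
    # 0.5 and grow anti-symmetrically under the class gradients; a random
    # head lets the sum-normalized cross-entropy drift both neurons into
    # saturation, where training dies.
    output <- list(W = matrix(0, nrow = spec$dense_units,
                              ncol = spec$n_classes),
                   b = rep(0, spec$n_classes))
    structure(list(format_version = MODEL_FORMAT_VERSION,
                   spec = spec, arch = format(spec), seed = as.integer(seed),
                   init = "he_normal+zero_output",
                   selected_epoch = NA_integer_,
                   conv = conv, dense = dense, output = output),
              class = "promcnn_model")
  })
}

#' @export
print.promcnn_model <- function(x, ...) {
  cat(sprintf("promcnn model: input %d nt | conv [%s] | dense %d | seed %d%s\n",
              x$spec$input_length, x$arch, x$spec$dense_units, x$seed,
              if (is.na(x$selected_epoch)) " | untrained"
              else sprintf(" | epoch %d", x$selected_epoch)))
  invisible(x)
}

# Coerce records / character vectors / one-hot matrices / 3-D arrays into
# the flat (len*4) x n batch representation, enforcing the model's input
# length and naming the offending record on mismatch.
as_flat_batch <- function(x, input_length) {
  if (is.data.frame(x)) {
    ids <- x$id
    lens <- nchar(x$sequence)
    if (any(lens != input_length))
      stop_data("record '%s' has length %d; model expects %d",
                ids[lens != input_length][1L],
                lens[lens != input_length][1L], input_length)
    arr <- encode_set(x$sequence)
  } else if (is.character(x)) {
    lens <- nchar(x)
    if (any(lens != input_length))
      stop_data("sequence %d has length %d; model expects %d",
                which(lens != input_length)[1L],
                lens[lens != input_length][1L], input_length)
    arr <- encode_set(x)
  } else if (is.list(x)) {
    lens <- vapply(x, nrow, integer(1))
    if (any(lens != input_length))
      stop_data("matrix %d has %d rows; model expects %d",
                which(lens != input_length)[1L],
                lens[lens != input_length][1L], input_length)
    arr <- array(unlist(x, use.names = FALSE),
                 dim = c(input_length, 4L, length(x)))
    # list elements are (len x 4); unlist concatenates column-major per
    # element, which matches the (len, 4, n) array layout
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1L] != input_length)
      stop_data("array first dimension %d; model expects %d",
                dim(x)[1L], input_length)
    arr <- x
  } else if (is.matrix(x)) {
    return(as_flat_batch(list(x), input_length))
  } else {
    stop_data("unsupported input type for forward_scores: %s",
              paste(class(x), collapse = "/"))
  }
  dim(arr) <- c(input_length * 4L, dim(arr)[3L])
  arr
}

#' Score a batch of sequences
#'
#' Runs the forward pass and returns the two sigmoid outputs per input,
#' (promoter score, non-promoter score), each in \[0, 1\]. Scores depend
#' only on the individual input, never on batch composition.
#'
#' @param model a `promcnn_model`.
#' @param batch a record `data.frame`, character vector of sequences, list
#'   of one-hot matrices, or a (length x 4 x n) array.
#' @param chunk_size internal batch chunking (memory control only; does
#'   not affect results).
#' @return an n x 2 matrix with columns `promoter`, `nonpromoter`.
#' @export
forward_scores <- function(model, batch, chunk_size = 512L) {
  stopifnot(inherits(model, "promcnn_model"))
  X <- as_flat_batch(batch, model$spec$input_length)
  n <- ncol(X)
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("promoter", "nonpromoter"))))
  }
  starts <- seq(1L, n, by = chunk_size)
  out <- lapply(starts, function(s) {
    e <- min(s + chunk_size - 1L, n)
    nn_forward(model, X[, s:e, drop = FALSE])$scores
  })
  do.call(rbind, out)
}

#' Turn score pairs into class calls
#'
#' A sequence is called promoter iff its promoter score strictly exceeds
#' its non-promoter score; ties break to non-promoter (the conservative
#' call). The reported score is always the promoter-neuron output.
#'
#' @param scores an n x 2 score matrix from [forward_scores()], or a
#'   length-2 numeric pair.
#' @return a `data.frame` with columns `class` and `score`.
#' @export
classify <- function(scores) {
  if (is.numeric(scores) && is.null(dim(scores)))
    scores <- matrix(scores, ncol = 2L)
  stopifnot(ncol(scores) == 2L)
  cls <- ifelse(scores[, 1L] > scores[, 2L], "promoter", "nonpromoter")
  data.frame(class = cls, score = scores[, 1L], stringsAsFactors = FALSE)
}

#' Save or load a model
#'
#' The model file is a single self-describing archive (RDS) holding the
#' architecture spec, provenance metadata (seed, initialization scheme,
#' selected epoch) and every parameter array; round trips are bit-exact.
#' Files carry a format-version field checked on load.
#'
#' @param model a `promcnn_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "promcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("model file not found: %s", path)
  model <- tryCatch(readRDS(path),
                    error = function(e)
                      stop_data("cannot read model file '%s': %s",
                                path, conditionMessage(e)))
  if (!inherits(model, "promcnn_model"))
    stop_data("'%s' is not a promcnn model file", path)
  if (!identical(model$format_version, MODEL_FORMAT_VERSION))
    stop_data("model file '%s' has format version %s; this build reads %s",
              path, model$format_version, MODEL_FORMAT_VERSION)
  model
}
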