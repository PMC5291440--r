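# Declarative model architectures: "F, L, P" triplets, '/'-separated layers.

#' Specify a convolutional layer
#'
#' @param n_filters number of filters (>= 1).
#' @param filter_length filter length in nt (>= 1).
#' @param pool_size max-pooling window; 0 means no pooling after this layer.
#'   Pooling windows are non-overlapping (stride = pool size) and trailing
#'   positions that do not fill a window are dropped.
#' @return an object of class `promcnn_conv_layer`.
#' @export
conv_layer <- function(n_filters, filter_length, pool_size = 0L) {
  n_filters <- as.integer(n_filters)
  filter_length <- as.integer(filter_length)
  pool_size <- as.integer(pool_size)
  if (is.na(n_filters) || n_filters < 1L)
    stop_config("n_filters must be >= 1, got %s", n_filters)
  if (is.na(filter_length) || filter_length < 1L)
    stop_config("filter_length must be >= 1, got %s", filter_length)
  if (is.na(pool_size) || pool_size < 0L)
    stop_config("pool_size must be >= 0, got %s", pool_size)
  structure(list(n_filters = n_filters, filter_length = filter_length,
                 pool_size = pool_size), class = "promcnn_conv_layer")
}

#' Specify a full model architecture
#'
#' Convolutions are "valid" (no padding) with stride 1, so each layer maps
#' a length-`n` input to `n - L + 1` activation positions; a pool of size
#' `p > 0` then keeps `floor((n - L + 1)/p)` positions. The final
#' activation map is flattened into a dense ReLU layer and a two-neuron
#' sigmoid output (promoter, non-promoter).
#'
#' @param input_length window length in nt the model accepts.
#' @param conv_layers list of [conv_layer()] objects, applied in order.
#' @param dense_units width of the fully connected ReLU layer (default 128).
#' @return an object of class `promcnn_model_spec`.
#' @export
model_spec <- function(input_length, conv_layers, dense_units = 128L) {
  input_length <- as.integer(input_length)
  if (is.na(input_length) || input_length < 1L)
    stop_config("input_length must be >= 1")
  if (inherits(conv_layers, "promcnn_conv_layer"))
    conv_layers <- list(conv_layers)
  if (length(conv_layers) == 0L)
    stop_config("at least one convolutional layer is required")
  dense_units <- as.integer(dense_units)
  if (is.na(dense_units) || dense_units < 1L)
    stop_config("dense_units must be >= 1")
  spec <- structure(list(input_length = input_length,
                         conv_layers = conv_layers,
                         dense_units = dense_units,
                         n_classes = 2L, stride = 1L),
                    class = "promcnn_model_spec")
  layer_lengths(spec)  # validates length arithmetic, errors name the layer
  spec
}

#' Activation-map lengths after each layer
#'
#' @param spec a `promcnn_model_spec`.
#' @return a `data.frame` with one row per conv layer: `layer`,
#'   `after_conv` (length of the valid-convolution activation map) and
#'   `after_pool` (length after max-pooling; equals `after_conv` when
#'   `pool_size` is 0).
#' @export
layer_lengths <- function(spec) {
  stopifnot(inherits(spec, "promcnn_model_spec"))
  len <- spec$input_length
  rows <- lapply(seq_along(spec$conv_layers), function(i) {
    ly <- spec$conv_layers[[i]]
    if (ly$filter_length > len)
      stop_config("layer %d: filter length %d exceeds its input length %d",
                  i, ly$filter_length, len)
    after_conv <- len - ly$filter_length + 1L
    after_pool <- if (ly$pool_size > 0L)
      after_conv %/% ly$pool_size else after_conv
    if (after_pool < 1L)
      stop_config("layer %d: pool size %d empties the %d-length map",
                  i, ly$pool_size, after_conv)
    len <<- after_pool
    data.frame(layer = i, after_conv = after_conv, after_pool = after_pool)
  })
  do.call(rbind, rows)
}

#' Trainable-parameter counts
#'
#' Each conv filter holds `filter_length x depth` weights plus one bias,
#' where depth is 4 at the input and the previous layer's filter count
#' deeper in.
#'
#' @param spec a `promcnn_model_spec`.
#' @return a list with per-conv-layer counts (`conv`), `dense`, `output`
#'   and `total`.
#' @export
parameter_counts <- function(spec) {
  stopifnot(inherits(spec, "promcnn_model_spec"))
  ll <- layer_lengths(spec)
  depth <- 4L
  conv <- integer(length(spec$conv_layers))
  for (i in seq_along(spec$conv_layers)) {
    ly <- spec$conv_layers[[i]]
    conv[i] <- ly$n_filters * (ly$filter_length * depth) + ly$n_filters
    depth <- ly$n_filters
  }
  n_feat <- ll$after_pool[nrow(ll)] * depth
  dense <- n_feat * spec$dense_units + spec$dense_units
  output <- spec$dense_units * spec$n_classes + spec$n_classes
  list(conv = conv, dense = dense, output = output,
       total = sum(conv) + dense + output)
}

#' Parse an architecture string
#'
#' Architectures are written as comma-separated triplets
#' `n_filters, filter_length, pool_size`, with `/` separating successive
#' layers — e.g. `"200, 21, 4"` for one layer of 200 length-21 filters
#' pooled by 4, or `"100,7, 0 / 150, 21, 12"` for two layers with no
#' pooling after the first.
#'
#' @param text architecture string.
#' @param input_length window length the model accepts.
#' @param dense_units dense-layer width (default 128).
#' @return a `promcnn_model_spec`.
#' @examples
#' parse_architecture("200, 21, 4", input_length = 251)
#' @export
parse_architecture <- function(text, input_length, dense_units = 128L) {
  layers_txt <- strsplit(text, "/", fixed = TRUE)[[1L]]
  if (length(layers_txt) == 0L || all(trimws(layers_txt) == ""))
    stop_config("empty architecture string")
  layers <- lapply(seq_along(layers_txt), function(i) {
    toks <- trimws(strsplit(layers_txt[i], ",", fixed = TRUE)[[1L]])
    if (length(toks) != 3L)
      stop_config("layer %d: expected 3 comma-separated values, got %d (%s)",
                  i, length(toks), layers_txt[i])
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop_config("layer %d, token %d: '%s' is not an integer",
                  i, j, toks[j])
    }
    conv_layer(vals[1L], vals[2L], vals[3L])
  })
  model_spec(input_length, layers, dense_units)
}

#' @export
format.promcnn_model_spec <- function(x, ...) {
  paste(vapply(x$conv_layers, function(ly)
    sprintf("%d, %d, %d", ly$n_filters, ly$filter_length, ly$pool_size),
    character(1)), collapse = " / ")
}

#' @export
print.promcnn_model_spec <- function(x, ...) {
  cat(sprintf("CNN spec: input %d nt | conv [%s] | dense %d | 2 sigmoid\n",
              x$input_length, format(x), x$dense_units))
  invisible(x)
}
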