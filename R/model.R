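#' Convolutional classifier architecture specification
#'
#' Describes the VGG-style network used for binder/non-binder
#' classification: `length(block_filters)` convolution blocks, each with
#' `convs_per_block` 3x3 same-padded convolution layers (ReLU) followed by
#' 2x2 max pooling and dropout, then dense ReLU layers and a single
#' sigmoid output unit.  The defaults reproduce the published
#' architecture: three blocks of two convolutions with 32, 64 and 128
#' filters on a 34 x 9 x 18 input.
#'
#' @param input_shape Integer vector `c(W, H, C)`; default `c(34, 9, 18)`.
#' @param block_filters Filters per convolution block (default
#'   `c(32, 64, 128)`).
#' @param convs_per_block Convolution layers per block (default 2).
#' @param kernel Convolution kernel size; only `c(3, 3)` is supported.
#' @param pool Pooling window; only `c(2, 2)` (stride 2, floor) supported.
#' @param dropout_rate Dropout fraction applied after each block
#'   (default 0.25).
#' @param dense_sizes Dense ReLU layer widths (default `c(256, 128)`).
#' @param output_activation `"sigmoid"` (default) or `"identity"` (linear
#'   output, useful for testing attribution on toy models).
#' @return An `ila_model_spec` object.
#' @export
model_spec <- function(input_shape = c(34L, 9L, 18L),
                       block_filters = c(32L, 64L, 128L),
                       convs_per_block = 2L,
                       kernel = c(3L, 3L),
                       pool = c(2L, 2L),
                       dropout_rate = 0.25,
                       dense_sizes = c(256L, 128L),
                       output_activation = c("sigmoid", "identity")) {
  output_activation <- match.arg(output_activation)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L),
            length(block_filters) >= 1L, all(block_filters >= 1L),
            convs_per_block >= 1L,
            dropout_rate >= 0, dropout_rate < 1,
            length(dense_sizes) >= 1L, all(dense_sizes >= 1L))
  if (!identical(as.integer(kernel), c(3L, 3L)))
    stop("only 3x3 convolution kernels are supported", call. = FALSE)
  if (!identical(as.integer(pool), c(2L, 2L)))
    stop("only 2x2 max pooling is supported", call. = FALSE)
  structure(list(input_shape = as.integer(input_shape),
                 block_filters = as.integer(block_filters),
                 convs_per_block = as.integer(convs_per_block),
                 kernel = c(3L, 3L), pool = c(2L, 2L),
                 dropout_rate = dropout_rate,
                 dense_sizes = as.integer(dense_sizes),
                 output_activation = output_activation),
            class = "ila_model_spec")
}

#' Build an untrained network from a specification
#'
#' Instantiates the layer stack with Glorot-uniform initial weights drawn
#' from R's RNG; passing `seed` makes two builds bit-identical.  Building
#' fails if any pooling stage would shrink a spatial dimension below 1.
#'
#' @param spec An `ila_model_spec`.
#' @param seed Optional integer seed for the weight initialization.
#' @return An `ila_net` with elements `spec`, `input_shape`, `layers`, and
#'   `param_count`.
#' @export
#' @examples
#' net <- build_model(model_spec(), seed = 1)
#' net$param_count
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ila_model_spec"))
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  w <- spec$input_shape[1L]; h <- spec$input_shape[2L]
  cin <- spec$input_shape[3L]
  layers <- list()
  for (bi in seq_along(spec$block_filters)) {
    f <- spec$block_filters[bi]
    for (ci in seq_len(spec$convs_per_block)) {
      layers[[length(layers) + 1L]] <- list(
        type = "conv", W = w, H = h, Cin = cin, F = f,
        K = glorot_matrix(9L * cin, f, 9L * cin, 9L * f),
        b = numeric(f))
      layers[[length(layers) + 1L]] <- list(type = "relu")
      cin <- f
    }
    if (w %/% 2L < 1L || h %/% 2L < 1L)
      stop(sprintf(
        "input too small: pooling in block %d would reduce %dx%d below 1x1",
        bi, w, h), call. = FALSE)
    layers[[length(layers) + 1L]] <- list(type = "pool", W = w, H = h,
                                          C = cin)
    w <- w %/% 2L; h <- h %/% 2L
    layers[[length(layers) + 1L]] <- list(type = "dropout",
                                          rate = spec$dropout_rate)
  }
  nin <- w * h * cin
  for (d in spec$dense_sizes) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", Win = nin, Wout = d,
      Wt = glorot_matrix(nin, d, nin, d), b = numeric(d))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    nin <- d
  }
  layers[[length(layers) + 1L]] <- list(
    type = "dense", Win = nin, Wout = 1L,
    Wt = glorot_matrix(nin, 1L, nin, 1L), b = numeric(1L))
  layers[[length(layers) + 1L]] <- list(type = spec$output_activation)
  net <- structure(list(spec = spec, input_shape = spec$input_shape,
                        layers = layers),
                   class = "ila_net")
  net$param_count <- net_param_count(net)
  net
}

#' Predict binding probabilities with a network
#'
#' Runs the network in inference mode (dropout off; deterministic).  Input
#' may be a single `ila_array`, a list of them, or a pre-stacked matrix
#' from [ila_stack()].
#'
#' @param object An `ila_net`.
#' @param newdata Input ILAs (see Details).
#' @param batch_size Chunk size for the forward pass.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]` (raw scores for
#'   identity-output models), order-preserving.
#' @export
predict.ila_net <- function(object, newdata, batch_size = 512L, ...) {
  X <- as_ila_matrix(newdata)
  net_predict_matrix(object, X, batch_size = batch_size)
}

as_ila_matrix <- function(newdata) {
  if (is.matrix(newdata)) return(newdata)
  if (inherits(newdata, "ila_array")) return(ila_stack(list(newdata)))
  if (is.list(newdata)) return(ila_stack(newdata))
  stop("newdata must be an ila_array, a list of them, or an ila_stack matrix",
       call. = FALSE)
}

#' @export
print.ila_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Convolutional binder/non-binder classifier (untrained handle)\n"))
  cat(sprintf("  input %s; blocks: %s filters x%d convs; dense: %s; %s output\n",
              paste(s$input_shape, collapse = "x"),
              paste(s$block_filters, collapse = "/"), s$convs_per_block,
              paste(s$dense_sizes, collapse = "/"), s$output_activation))
  cat(sprintf("  parameters: %s\n", format(x$param_count, big.mark = ",")))
  invisible(x)
}
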