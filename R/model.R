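#' Model architecture configuration
#'
#' Describes the convolutional classifier: a stack of
#' `num_conv_layers` blocks, each `conv(kernel_length, filters_per_layer)
#' -> ReLU -> average pool(pool_length)`, followed by global average
#' pooling over the positional axis and a single logistic output unit.
#' The defaults are the published architecture: four layers of 128 filters
#' of length 15 with pooling of length 5 over 4-channel one-hot input.
#'
#' Convolutions are 'same'-padded with stride 1 and pooling windows are
#' non-overlapping with a final partial window averaged over its true
#' size, so the same weights apply to any input length at or above
#' `min_input_length` without padding or rebuilding.
#'
#' @param num_conv_layers number of conv/ReLU/pool blocks.
#' @param filters_per_layer filters in every convolutional layer.
#' @param kernel_length odd filter length in bases.
#' @param pool_length average-pooling window in positions.
#' @param input_channels one-hot channels; 4 for DNA.
#' @param output_units output dimension; must be 1 (host probability).
#' @param min_input_length shortest read length (bp) the model accepts.
#' @return A `model_config` list.
#' @export
model_config <- function(num_conv_layers = 4L, filters_per_layer = 128L,
                         kernel_length = 15L, pool_length = 5L,
                         input_channels = 4L, output_units = 1L,
                         min_input_length = 50L) {
  cfg <- list(num_conv_layers = as.integer(num_conv_layers),
              filters_per_layer = as.integer(filters_per_layer),
              kernel_length = as.integer(kernel_length),
              pool_length = as.integer(pool_length),
              input_channels = as.integer(input_channels),
              output_units = as.integer(output_units),
              min_input_length = as.integer(min_input_length))
  if (any(vapply(cfg, function(x) x < 1L, logical(1))))
    stop("all model_config fields must be positive")
  if (cfg$kernel_length %% 2L == 0L)
    stop("kernel_length must be odd")
  if (cfg$output_units != 1L)
    stop("only a single logistic output unit is supported")
  structure(cfg, class = "model_config")
}

#' Build a randomly initialized classifier
#'
#' Weights are drawn reproducibly from `seed`: He-scaled normals for the
#' convolutional filters (sd = sqrt(2 / fan_in), suited to ReLU) and
#' sd = sqrt(1 / filters) for the output unit; all biases start at zero.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling initialization.
#' @return A `host_cnn` model object.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  k <- config$kernel_length
  nf <- config$filters_per_layer
  conv <- vector("list", config$num_conv_layers)
  c_in <- config$input_channels
  for (i in seq_len(config$num_conv_layers)) {
    fan_in <- c_in * k
    conv[[i]] <- list(
      W = matrix(rnorm(nf * fan_in, sd = sqrt(2 / fan_in)), nf, fan_in),
      b = numeric(nf))
    c_in <- nf
  }
  structure(list(config = config,
                 weights = list(conv = conv,
                                fc_w = rnorm(nf, sd = sqrt(1 / nf)),
                                fc_b = 0),
                 version = 1L),
            class = "host_cnn")
}

# Engine-facing views of the weight lists.
.engine_args <- function(model) {
  w <- model$weights
  list(W = lapply(w$conv, `[[`, "W"),
       b = lapply(w$conv, `[[`, "b"),
       fw = w$fc_w, fb = w$fc_b,
       k = model$config$kernel_length, pool = model$config$pool_length)
}

# Coerce a batch to the engine layout 4 x (L*N); returns list(X, L, N).
# Accepts a character vector of equal-length sequences or an N x L x 4
# array as produced by one_hot_encode() rows stacked along dim 1.
.engine_batch <- function(model, x) {
  if (is.character(x)) {
    L <- unique(nchar(x))
    if (length(L) != 1L)
      stop("all sequences in a batch must share one length; got lengths {",
           paste(sort(L), collapse = ", "), "}")
    list(X = encode_seqs_cpp(x, L), L = L, N = length(x))
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 4L) {
    n <- dim(x)[1]; L <- dim(x)[2]
    list(X = matrix(aperm(x, c(3L, 2L, 1L)), nrow = 4L), L = L, N = n)
  } else if (is.matrix(x) && ncol(x) == 4L) {
    list(X = t(x), L = nrow(x), N = 1L)
  } else {
    stop("batch must be a character vector, an L x 4 matrix, ",
         "or an N x L x 4 array")
  }
}

.check_length <- function(model, L) {
  if (L < model$config$min_input_length)
    stop("input length ", L, " is below the minimum supported length ",
         model$config$min_input_length)
}

#' Score a batch of reads
#'
#' Runs the network on `batch` and returns one host probability per read.
#' The batch must be length-homogeneous (that is what the binning module
#' guarantees); any length at or above the model's minimum is accepted
#' with the same weights.
#'
#' @param model a `host_cnn`.
#' @param batch character vector of equal-length sequences, an `L x 4`
#'   one-hot matrix (single read), or an `N x L x 4` array.
#' @param type `"probability"` (default) or `"logit"`.
#' @return Numeric vector of length N.
#' @export
model_forward <- function(model, batch, type = c("probability", "logit")) {
  stopifnot(inherits(model, "host_cnn"))
  type <- match.arg(type)
  eb <- .engine_batch(model, batch)
  .check_length(model, eb$L)
  ea <- .engine_args(model)
  z <- as.numeric(cnn_forward_cpp(ea$W, ea$b, ea$fw, ea$fb, ea$k, ea$pool,
                                  eb$X, eb$L))
  if (type == "logit") z else plogis(z)
}

#' Count trainable scalars in a model
#' @param model a `host_cnn`.
#' @return Integer: weights plus biases across all layers.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "host_cnn"))
  w <- model$weights
  n <- sum(vapply(w$conv, function(l) length(l$W) + length(l$b), numeric(1)))
  as.integer(n + length(w$fc_w) + 1L)
}

#' Serialized storage footprint in GB
#'
#' Parameter count times bytes per scalar, reported to 3 decimal places.
#' At 32-bit precision the default architecture occupies 0.003 GB.
#'
#' @param model a `host_cnn`.
#' @param precision bytes per scalar (4 = 32-bit floats).
#' @return Numeric GB, rounded to 3 decimals.
#' @export
serialized_size_gb <- function(model, precision = 4) {
  round(count_parameters(model) * precision / 1e9, 3)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file container holding the weights, the
#' [model_config()], and a format version; loading a checkpoint restores a
#' model whose outputs are bit-identical to the saved one.
#'
#' @param model a `host_cnn`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "host_cnn"))
  # uncompressed: weight arrays are incompressible and the file size then
  # tracks the parameter count at 8 bytes per scalar
  saveRDS(list(container = "hostsieve_checkpoint", version = model$version,
               config = unclass(model$config), weights = model$weights),
          path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot load model checkpoint '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$container, "hostsieve_checkpoint"))
    stop("'", path, "' is not a hostsieve model checkpoint")
  if (!identical(obj$version, 1L))
    stop("unsupported checkpoint version: ", obj$version)
  cfg <- do.call(model_config, obj$config)
  nf <- cfg$filters_per_layer
  ok <- length(obj$weights$conv) == cfg$num_conv_layers &&
    length(obj$weights$fc_w) == nf
  if (!ok) stop("checkpoint weight shapes do not match its config")
  structure(list(config = cfg, weights = obj$weights, version = 1L),
            class = "host_cnn")
}

#' @export
print.host_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<host_cnn> ", cfg$num_conv_layers, " conv layers x ",
      cfg$filters_per_layer, " filters (kernel ", cfg$kernel_length,
      ", pool ", cfg$pool_length, "), GAP -> 1 logistic unit; ",
      count_parameters(x), " parameters\n", sep = "")
  invisible(x)
}
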