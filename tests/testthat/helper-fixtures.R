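# Shared fixtures and independent oracles.  Expensive artifacts (trained
# models) are built lazily and cached for the whole test run.

.hs_cache <- new.env(parent = emptyenv())

tiny_config <- function(num_conv_layers = 2L, filters_per_layer = 8L,
                        kernel_length = 5L, pool_length = 3L,
                        min_input_length = 10L) {
  model_config(num_conv_layers = num_conv_layers,
               filters_per_layer = filters_per_layer,
               kernel_length = kernel_length, pool_length = pool_length,
               min_input_length = min_input_length)
}

tiny_model <- function(seed = 42L, config = tiny_config()) {
  build_model(config, seed = seed)
}

zero_weights <- function(model) {
  for (i in seq_along(model$weights$conv)) {
    model$weights$conv[[i]]$W[] <- 0
    model$weights$conv[[i]]$b[] <- 0
  }
  model$weights$fc_w[] <- 0
  model$weights$fc_b <- 0
  model
}

# Independent forward oracle: plain-R convolution ('same' padding, stride
# 1), ReLU, ceiling average pooling, global average pooling, linear unit.
oracle_logit <- function(model, bases) {
  cfg <- model$config
  k <- cfg$kernel_length
  p <- cfg$pool_length
  pad <- k %/% 2
  A <- t(one_hot_encode(bases, nchar(bases)))
  for (i in seq_len(cfg$num_conv_layers)) {
    W <- model$weights$conv[[i]]$W
    b <- model$weights$conv[[i]]$b
    C <- nrow(A); L <- ncol(A); nf <- nrow(W)
    Z <- matrix(0, nf, L)
    for (t in seq_len(L)) {
      for (kk in seq_len(k)) {
        src <- t + kk - 1L - pad
        if (src >= 1 && src <= L)
          Z[, t] <- Z[, t] +
            W[, ((kk - 1L) * C + 1L):(kk * C), drop = FALSE] %*% A[, src]
      }
      Z[, t] <- Z[, t] + b
    }
    A <- pmax(Z, 0)
    Lp <- ceiling(L / p)
    P <- matrix(0, nf, Lp)
    for (j in seq_len(Lp))
      P[, j] <- rowMeans(A[, ((j - 1L) * p + 1L):min(L, j * p),
                           drop = FALSE])
    A <- P
  }
  sum(model$weights$fc_w * rowMeans(A)) + model$weights$fc_b
}

# A small trained model on strongly separable synthetic reads, for the
# pipeline / calibration / attribution tests that need a learner that has
# actually learned something.  Cached across test files.
trained_tiny <- function() {
  if (!is.null(.hs_cache$tiny_fit)) return(.hs_cache$tiny_fit)
  spec <- read_set_spec(n_reads = 500, host_fraction = 0.5,
                        min_length = 200, max_length = 200, seed = 11)
  rs <- generate_read_set(spec)
  ds <- labeled_dataset(rs$bases, rs$label)
  fit <- train_model(tiny_model(seed = 7),
                     ds[1:350, ], ds[351:425, ],
                     training_config(max_epochs = 6L, patience = 30L,
                                     batch_size = 50L, seed = 7L))
  .hs_cache$tiny_fit <- list(fit = fit, data = ds,
                             idx = list(train = 1:350, val = 351:425,
                                        test = 426:500))
  .hs_cache$tiny_fit
}

# The full acceptance artifact: the default architecture trained on the
# 2,000-read stated world (length 1,000, CG-suppressed host profile), split
# 1400/300/300 train/val/held-out, with CNN and naive-CG evaluations.
acceptance_fit <- function(seed = 1L) {
  if (!is.null(.hs_cache$accept)) return(.hs_cache$accept)
  spec <- read_set_spec(n_reads = 2000, host_fraction = 0.5,
                        min_length = 1000, max_length = 1000, seed = seed)
  rs <- generate_read_set(spec)
  ds <- labeled_dataset(rs$bases, rs$label)
  idx <- list(train = 1:1400, val = 1401:1700, test = 1701:2000)
  fit <- train_model(build_model(model_config(), seed = seed),
                     ds[idx$train, ], ds[idx$val, ],
                     training_config(max_epochs = 8L, patience = 30L,
                                     batch_size = 64L, seed = seed))
  tab <- calibrate_thresholds(fit$model, ds[idx$val, ],
                              calibration_lengths = 1000)
  probs <- model_forward(fit$model, ds$bases[idx$test])
  pred <- classify_probability(probs, select_threshold(1000, tab))
  cnn <- confusion_metrics(pred, ds$label[idx$test])
  cg_thr <- calibrate_cg_threshold(ds$bases[idx$val], ds$label[idx$val])
  naive <- confusion_metrics(naive_cg_classifier(ds$bases[idx$test], cg_thr),
                             ds$label[idx$test])
  .hs_cache$accept <- list(model = fit$model, history = fit$history,
                           data = ds, idx = idx, thresholds = tab,
                           cnn = cnn, naive = naive)
  .hs_cache$accept
}

# Write a read data.frame to a temporary FASTA/FASTQ file.
tmp_seq_file <- function(reads, format = "fastq") {
  path <- tempfile(fileext = paste0(".", format))
  write_sequences(reads, path, format)
  path
}
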