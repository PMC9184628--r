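test_that("make_length_variants crops per target length it can support", {
  set.seed(2)
  long_read <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                     collapse = "")
  ds <- labeled_dataset(c(long_read, strrep("ACGTG", 100)), c(1L, 0L))
  v <- make_length_variants(ds, c(100, 1000, 10000), seed = 4)
  expect_equal(sort(v$length[v$source == 1]), c(100L, 1000L, 10000L))
  expect_equal(v$length[v$source == 2], 100L)  # 500 bp read: only 100
  expect_true(all(nchar(v$bases) == v$length))
  expect_true(all(v$label == ds$label[v$source]))
  # crops are substrings of their source
  for (i in seq_len(nrow(v)))
    expect_true(grepl(v$bases[i], ds$bases[v$source[i]], fixed = TRUE))
  expect_identical(make_length_variants(ds, c(100, 1000, 10000), seed = 4),
                   v)
  expect_false(identical(
    make_length_variants(ds, c(100, 1000, 10000), seed = 5)$bases, v$bases))
})

test_that("model_loss has the analytic value in closed-form cases", {
  m0 <- zero_weights(tiny_model())
  set.seed(6)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  y <- c(1L, 0L, 1L, 0L)
  # zero weights: p = 0.5 so BCE = ln 2; L2 and gradient penalty vanish
  expect_equal(model_loss(m0, seqs, y), log(2), tolerance = 1e-12)
  # with both lambdas 0 the loss is plain mean BCE of the probabilities
  m <- tiny_model(seed = 31)
  cfg0 <- training_config(l2_lambda = 0, input_grad_lambda = 0)
  p <- model_forward(m, seqs)
  expect_equal(model_loss(m, seqs, y, cfg0),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  # hand-set small model, 2-read batch; includes the double-backprop
  # input-gradient penalty term
  cfg <- model_config(num_conv_layers = 2L, filters_per_layer = 3L,
                      kernel_length = 3L, pool_length = 2L,
                      min_input_length = 5L)
  m <- build_model(cfg, seed = 55)
  seqs <- c("ACGTACGTACGTAC", "TTGGCCAATTGGCC")
  y <- c(1, 0)
  lgp <- 0.3
  X <- hostsieve:::encode_seqs_cpp(seqs, 14L)
  ea <- hostsieve:::.engine_args(m)
  g <- hostsieve:::cnn_grad_cpp(ea$W, ea$b, ea$fw, ea$fb, ea$k, ea$pool,
                                X, 14L, y, TRUE, TRUE)
  lossfun <- function(W, b, fw, fb) {
    gg <- hostsieve:::cnn_grad_cpp(W, b, fw, fb, ea$k, ea$pool, X, 14L, y,
                                   FALSE, TRUE)
    gg$bce + lgp * gg$grad_penalty
  }
  eps <- 1e-6
  fd <- function(mutate) {
    args <- list(W = ea$W, b = ea$b, fw = ea$fw, fb = ea$fb)
    up <- mutate(args, eps); dn <- mutate(args, -eps)
    (do.call(lossfun, up) - do.call(lossfun, dn)) / (2 * eps)
  }
  set.seed(56)
  for (layer in 1:2) {
    for (j in sample(length(ea$W[[layer]]), 4)) {
      ana <- g$gW[[layer]][j] + lgp * g$gpW[[layer]][j]
      num <- fd(function(a, e) { a$W[[layer]][j] <- a$W[[layer]][j] + e; a })
      expect_equal(ana, num, tolerance = 1e-5)
    }
    jb <- sample(length(ea$b[[layer]]), 1)
    num <- fd(function(a, e) { a$b[[layer]][jb] <- a$b[[layer]][jb] + e; a })
    expect_equal(g$gb[[layer]][jb], num, tolerance = 1e-5)
  }
  for (j in sample(length(ea$fw), 3)) {
    num <- fd(function(a, e) { a$fw[j] <- a$fw[j] + e; a })
    expect_equal(g$gfw[j] + lgp * g$gpfw[j], num, tolerance = 1e-5)
  }
  num <- fd(function(a, e) { a$fb <- a$fb + e; a })
  expect_equal(g$gfb, num, tolerance = 1e-5)
})

test_that("loss is non-decreasing in both regularization coefficients", {
  m <- tiny_model(seed = 61)
  set.seed(62)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  y <- rep(c(1L, 0L), 3)
  for (lam in list(c(0, 1e-4, 1e-2), c(0, 1e-3, 1e-1))) {
    l2s <- vapply(lam, function(l)
      model_loss(m, seqs, y, training_config(l2_lambda = l,
                                             input_grad_lambda = 1e-4)),
      numeric(1))
    expect_true(!is.unsorted(l2s))
    gps <- vapply(lam, function(l)
      model_loss(m, seqs, y, training_config(l2_lambda = 1e-5,
                                             input_grad_lambda = l)),
      numeric(1))
    expect_true(!is.unsorted(gps))
  }
})

test_that("training learns, checkpoints the best epoch, and is seeded", {
  tf <- trained_tiny()
  h <- tf$fit$history
  expect_gte(nrow(h), 1)
  # learning signal on separable synthetic data
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # returned weights come from the best validation epoch
  val_best <- min(h$val_loss)
  ds <- tf$data
  cfg <- training_config(max_epochs = 2L, patience = 30L, batch_size = 50L,
                         seed = 7L)
  # determinism: identical (data, config, seed) -> identical history/weights
  r1 <- train_model(tiny_model(seed = 7), ds[1:100, ], ds[426:500, ], cfg)
  r2 <- train_model(tiny_model(seed = 7), ds[1:100, ], ds[426:500, ], cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$weights, r2$model$weights)
  expect_error(train_model(tiny_model(), ds[ds$label == 1, ][1:10, ],
                           ds[426:500, ], cfg), "both classes")
})

test_that("patience 0 stops at the first epoch without improvement", {
  tf <- trained_tiny()
  ds <- tf$data
  # learning rate so small that the validation loss cannot improve
  cfg <- training_config(learning_rate = 1e-20, patience = 0L,
                         max_epochs = 10L, batch_size = 50L, seed = 3L,
                         input_grad_lambda = 0)
  r <- train_model(tiny_model(seed = 9), ds[1:100, ], ds[426:500, ], cfg)
  expect_identical(nrow(r$history), 2L)
  expect_equal(min(r$history$val_loss), r$history$val_loss[1])
})
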