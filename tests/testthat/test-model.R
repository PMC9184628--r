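test_that("forward matches the plain-R arithmetic oracle", {
  set.seed(5)
  cfgs <- list(
    model_config(num_conv_layers = 1L, filters_per_layer = 1L,
                 kernel_length = 3L, pool_length = 2L,
                 min_input_length = 5L),
    tiny_config(),
    model_config(num_conv_layers = 3L, filters_per_layer = 6L,
                 kernel_length = 7L, pool_length = 5L,
                 min_input_length = 20L))
  for (cfg in cfgs) {
    m <- build_model(cfg, seed = 101)
    for (L in c(20L, 37L, 64L)) {
      if (L < cfg$min_input_length) next
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      expect_equal(model_forward(m, s, type = "logit"), oracle_logit(m, s),
                   tolerance = 1e-10)
      expect_equal(model_forward(m, s), plogis(oracle_logit(m, s)),
                   tolerance = 1e-10)
    }
  }
})

test_that("zero-weight model outputs 0.5 for every read", {
  m <- zero_weights(tiny_model())
  set.seed(8)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE),
          collapse = ""), character(1))
  expect_equal(model_forward(m, seqs), rep(0.5, 5))
})

test_that("batching does not couple reads and any supported length works", {
  m <- tiny_model()
  set.seed(9)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = ""),
    character(1))
  batch <- model_forward(m, seqs)
  single <- vapply(seqs, function(s) model_forward(m, s), numeric(1),
                   USE.NAMES = FALSE)
  expect_equal(batch, single)
  expect_true(all(batch >= 0 & batch <= 1))
  # identical reads give identical probabilities
  expect_equal(model_forward(m, c(seqs[1], seqs[1]))[1],
               model_forward(m, c(seqs[1], seqs[1]))[2])
  # one set of default-architecture weights serves every binned length
  full <- build_model(model_config(), seed = 3)
  for (L in c(50L, 100L, 1000L, 6000L)) {
    s <- strrep("ACGT", ceiling(L / 4))
    p <- model_forward(full, substr(s, 1, L))
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(model_forward(full, "ACGTACGT"), "minimum supported length")
  expect_error(model_forward(m, c("ACGT", "ACGTA")), "share one length")
  # encoded inputs (N x L x 4 array, or L x 4 matrix for one read) give
  # the same probabilities as the sequences themselves
  arr <- array(0, c(2, 45, 4))
  arr[1, , ] <- one_hot_encode(seqs[1], 45)
  arr[2, , ] <- one_hot_encode(seqs[2], 45)
  expect_equal(model_forward(m, arr), batch[1:2])
  expect_equal(model_forward(m, one_hot_encode(seqs[1], 45)), batch[1])
})

test_that("count_parameters matches the closed form", {
  closed_form <- function(cfg) {
    tot <- cfg$input_channels * cfg$kernel_length * cfg$filters_per_layer +
      cfg$filters_per_layer
    if (cfg$num_conv_layers > 1)
      tot <- tot + (cfg$num_conv_layers - 1) *
        (cfg$filters_per_layer * cfg$kernel_length * cfg$filters_per_layer +
         cfg$filters_per_layer)
    as.integer(tot + cfg$filters_per_layer + 1)
  }
  full <- build_model(model_config(), seed = 1)
  expect_identical(count_parameters(full), 745601L)
  expect_identical(count_parameters(full), closed_form(model_config()))
  toy_cfg <- model_config(num_conv_layers = 1L, filters_per_layer = 1L,
                          kernel_length = 3L, pool_length = 2L,
                          min_input_length = 5L)
  toy <- build_model(toy_cfg, seed = 1)
  expect_identical(count_parameters(toy), 15L)
  expect_identical(count_parameters(toy), closed_form(toy_cfg))
  dbl <- build_model(model_config(filters_per_layer = 256L), seed = 1)
  expect_gt(count_parameters(dbl), 2 * count_parameters(full))
})

test_that("serialized size is parameters x precision, to 3 decimals", {
  full <- build_model(model_config(), seed = 1)
  expect_equal(serialized_size_gb(full), 0.003)
  expect_equal(serialized_size_gb(full, precision = 8),
               round(2 * count_parameters(full) * 4 / 1e9, 3))
  toy <- build_model(model_config(num_conv_layers = 1L,
                                  filters_per_layer = 1L,
                                  kernel_length = 3L, pool_length = 2L,
                                  min_input_length = 5L), seed = 1)
  expect_equal(serialized_size_gb(toy), 0)
})

test_that("checkpoints round-trip bit-identically and reject junk", {
  m <- tiny_model(seed = 13)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(14)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
             collapse = "")
  expect_identical(model_forward(m, s), model_forward(m2, s))
  expect_identical(count_parameters(m), count_parameters(m2))
  # truncated file
  raw <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- tempfile()
  writeBin(raw[1:100], trunc_path)
  expect_error(load_model(trunc_path), "cannot load")
  # wrong container
  other <- tempfile()
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not a hostsieve")
})

test_that("build_model is reproducible from its seed", {
  a <- build_model(tiny_config(), seed = 77)
  b <- build_model(tiny_config(), seed = 77)
  expect_identical(a$weights, b$weights)
  c <- build_model(tiny_config(), seed = 78)
  expect_false(identical(a$weights, c$weights))
})
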