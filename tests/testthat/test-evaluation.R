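test_that("confusion_metrics counts the four cells correctly", {
  r <- confusion_metrics(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1.0)
  expect_equal(r$accuracy, 0.75)
  perfect <- confusion_metrics(c(1L, 0L), c(1L, 0L))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  # randomized case vs an independent four-cell tally
  set.seed(31)
  for (rep in 1:5) {
    truth <- sample(c(0L, 1L), 20, replace = TRUE)
    pred <- sample(c(0L, 1L), 20, replace = TRUE)
    if (length(unique(truth)) < 2) next
    cells <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in 1:20) {
      if (truth[i] == 1) {
        if (pred[i] == 1) cells["tp"] <- cells["tp"] + 1
        else cells["fn"] <- cells["fn"] + 1
      } else {
        if (pred[i] == 1) cells["fp"] <- cells["fp"] + 1
        else cells["tn"] <- cells["tn"] + 1
      }
    }
    got <- confusion_metrics(pred, truth)
    expect_equal(got$tp, unname(cells["tp"]))
    expect_equal(got$sensitivity,
                 unname(cells["tp"] / (cells["tp"] + cells["fn"])))
    expect_equal(got$specificity,
                 unname(cells["tn"] / (cells["tn"] + cells["fp"])))
    expect_equal(got$accuracy, unname((cells["tp"] + cells["tn"]) / 20))
    # permutation invariance
    o <- sample(20)
    expect_equal(confusion_metrics(pred[o], truth[o]), got)
  }
  expect_warning(one <- confusion_metrics(c(1L, 1L), c(1L, 1L)),
                 "specificity undefined")
  expect_true(is.na(one$specificity))
  expect_equal(one$sensitivity, 1)
})

test_that("cg_fraction counts overlapping dimers over length - 1", {
  expect_equal(cg_fraction("CGCG"), 2 / 3)
  expect_equal(cg_fraction("AAAA"), 0)
  expect_equal(cg_fraction("ACGT"), 1 / 3)
  expect_equal(cg_fraction(c("cgcg", "ACGT")), c(2 / 3, 1 / 3))
  expect_error(cg_fraction("A"), "shorter than 2")
  # monotone under appending CG blocks
  s <- "ATATATAT"
  vals <- vapply(0:5, function(i)
    cg_fraction(paste0(s, strrep("CG", i))), numeric(1))
  expect_true(!is.unsorted(vals))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("naive_cg_classifier follows CG suppression", {
  expect_identical(naive_cg_classifier("AAAAAA", 0.02), 1L)
  expect_identical(naive_cg_classifier("CGCGCG", 0.02), 0L)
  # threshold 0: every read is called microbe
  expect_identical(naive_cg_classifier(c("AAAA", "CGCG"), 0),
                   c(0L, 0L))
})

test_that("calibrate_cg_threshold maximizes Youden's J", {
  bases <- c("AAAAAAAA", "ATATATAT", "CGCGCGCG", "ACGCGCGT")
  labels <- c(1L, 1L, 0L, 0L)
  thr <- calibrate_cg_threshold(bases, labels)
  pred <- naive_cg_classifier(bases, thr)
  expect_identical(pred, labels)  # separable -> perfect recovery
})

test_that("stratify_by_cg partitions into the five strata", {
  # 2-mers: fractions 0.03 and exactly 0.01 by construction
  s3 <- paste0(strrep("CG", 3), strrep("AT", 97))   # 3 CG in 199 dimers
  expect_true(abs(cg_fraction(s3) - 0.015) < 0.001)
  expect_equal(as.character(stratify_by_cg(s3)), "[1,2)")
  s_exact <- paste0("CG", strrep("A", 99))          # 1 CG / 100 dimers = 1%
  expect_equal(cg_fraction(s_exact), 0.01)
  expect_equal(as.character(stratify_by_cg(s_exact)), "[1,2)")  # left-closed
  s0 <- strrep("AT", 100)
  expect_equal(as.character(stratify_by_cg(s0)), "[0,1)")
  s_hi <- strrep("CG", 100)
  expect_equal(as.character(stratify_by_cg(s_hi)), "[10,100]")
  set.seed(41)
  reads <- generate_read_set(read_set_spec(300, min_length = 200,
                                           max_length = 500, seed = 41))
  strata <- stratify_by_cg(reads$bases)
  expect_equal(sum(table(strata)), 300)
  expect_false(anyNA(strata))
})

test_that("kmer_uniqueness is the host-exclusive fraction of distinct k-mers", {
  expect_equal(kmer_uniqueness(strrep("A", 20), strrep("C", 20), 3), 1)
  expect_equal(kmer_uniqueness(c("ACGTT", "GGGCA"), c("ACGTT", "GGGCA"), 3),
               0)
  # hand-enumerated toy: host 3-mers {ACG, CGT, GTA, TTT},
  # microbe {ACG, CGT, GTT}; exclusive = {GTA, TTT} -> 0.5
  expect_equal(kmer_uniqueness(c("ACGTA", "TTTTT"), "ACGTT", 3), 0.5)
  # superset monotonicity: adding microbe reads never raises uniqueness
  set.seed(51)
  host <- sample_sequence(host_profile(), rep(100, 10))
  mic1 <- sample_sequence(microbe_profile(), rep(100, 5))
  mic2 <- c(mic1, sample_sequence(microbe_profile(), rep(100, 5)))
  for (k in c(11, 13, 15, 17))
    expect_lte(kmer_uniqueness(host, mic2, k),
               kmer_uniqueness(host, mic1, k))
  expect_error(kmer_uniqueness("ACGT", "ACGT", 11), "shorter than k")
})

test_that("metric reports serialize as TSV", {
  r <- confusion_metrics(c(1L, 0L, 1L), c(1L, 0L, 0L))
  path <- tempfile()
  write_metric_report(r, path)
  back <- read.delim(path)
  expect_equal(back$accuracy, r$accuracy)
  expect_equal(back$tp, r$tp)
})
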