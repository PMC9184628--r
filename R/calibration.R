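#' Length-dependent threshold table
#'
#' Maps calibration lengths to decision probabilities. A read is labelled
#' host when its probability strictly exceeds the threshold of the
#' nearest calibration length. The default ships 0.5 at every length
#' until [calibrate_thresholds()] is run.
#'
#' @param lengths strictly increasing calibration lengths (bp).
#' @param thresholds probabilities in \[0, 1\]; recycled to
#'   `length(lengths)`.
#' @return A `threshold_table` data.frame with columns `length`,
#'   `threshold`.
#' @export
threshold_table <- function(lengths = c(100, 150, 200, 300, 500, 1000,
                                        5000, 10000),
                            thresholds = 0.5) {
  if (!length(lengths)) stop("threshold table must be non-empty")
  if (is.unsorted(lengths, strictly = TRUE))
    stop("calibration lengths must be strictly increasing")
  thresholds <- rep_len(thresholds, length(lengths))
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  structure(data.frame(length = as.integer(lengths),
                       threshold = as.numeric(thresholds)),
            class = c("threshold_table", "data.frame"))
}

#' Read / write a threshold table
#'
#' TSV with header columns `length` and `threshold`.
#' @param path file path.
#' @param table a `threshold_table`.
#' @export
read_threshold_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  threshold_table(df$length, df$threshold)
}

#' @rdname read_threshold_table
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the threshold for a read length
#'
#' Returns the entry whose calibration length is closest to `length`;
#' ties break toward the smaller calibration length.
#'
#' @param length integer vector of read lengths (bp).
#' @param table a [threshold_table()].
#' @return Numeric vector of thresholds.
#' @export
select_threshold <- function(length, table = threshold_table()) {
  stopifnot(inherits(table, "threshold_table"), nrow(table) >= 1)
  idx <- vapply(length, function(l) which.min(abs(table$length - l)),
                integer(1))
  table$threshold[idx]
}

#' Threshold a host probability into a label
#'
#' Label 1 (host) iff `probability > threshold`, strictly; a probability
#' exactly at the threshold is labelled microbe.
#'
#' @param probability numeric vector in \[0, 1\].
#' @param threshold numeric vector in \[0, 1\] (recycled).
#' @return Integer vector of labels in \{0, 1\}.
#' @export
classify_probability <- function(probability, threshold) {
  stopifnot(all(probability >= 0 & probability <= 1),
            all(threshold >= 0 & threshold <= 1))
  as.integer(probability > threshold)
}

#' Youden-optimal decision threshold
#'
#' Scans all observed scores plus \{0, 1\} as candidate thresholds for the
#' rule "positive iff score > t" and returns the smallest candidate
#' maximizing Youden's J = sensitivity + specificity - 1. Deterministic
#' and invariant to the order of the observations.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels integer truth labels in \{0, 1\} (1 = positive), both
#'   classes present.
#' @return Scalar threshold; its achieved J is in attribute `"J"`.
#' @export
youden_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            length(unique(labels)) == 2L)
  grid <- sort(unique(c(0, scores, 1)))
  j <- vapply(grid, function(t)
    mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1,
    numeric(1))
  structure(grid[which(j == max(j))[1]], J = max(j))
}

#' Calibrate length-dependent thresholds on validation data
#'
#' For each calibration length, the validation reads at least that long
#' are cropped (prefix) to the length, scored by the model, and the
#' threshold maximizing Youden's J (sensitivity + specificity - 1) over a
#' grid of all observed probabilities plus \{0, 1\} is chosen; the
#' smallest optimal grid value is returned, making the procedure
#' deterministic and invariant to read order.
#'
#' @param model a `host_cnn`.
#' @param validation data.frame with `bases` and `label` (1 = host).
#' @param calibration_lengths lengths (bp) to calibrate; defaults to the
#'   standard eight.
#' @param batch_size reads scored per forward call.
#' @return A [threshold_table()].
#' @export
calibrate_thresholds <- function(model, validation,
                                 calibration_lengths = c(100, 150, 200, 300,
                                                         500, 1000, 5000,
                                                         10000),
                                 batch_size = 256L) {
  stopifnot(inherits(model, "host_cnn"),
            all(c("bases", "label") %in% names(validation)))
  lens <- nchar(validation$bases)
  thr <- vapply(calibration_lengths, function(len) {
    keep <- which(lens >= len)
    lab <- validation$label[keep]
    if (length(unique(lab)) < 2L)
      stop("calibration error at length ", len,
           ": validation slice does not contain both classes")
    crops <- substr(validation$bases[keep], 1L, len)
    probs <- unlist(lapply(split(seq_along(crops),
                                 (seq_along(crops) - 1L) %/% batch_size),
                           function(i) model_forward(model, crops[i])))
    best <- youden_threshold(probs, lab)
    if (attr(best, "J") <= 0)
      warning("no discriminative threshold at length ", len,
              " (best Youden J = ", signif(attr(best, "J"), 3), ")")
    as.numeric(best)
  }, numeric(1))
  threshold_table(calibration_lengths, thr)
}
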