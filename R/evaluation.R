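#' Confusion metrics with host as the positive class
#'
#' Sensitivity is the fraction of true host reads labelled host,
#' specificity the fraction of true microbe reads labelled microbe.
#' When the truth contains a single class, the undefined metric is `NA`
#' with a warning.
#'
#' @param predictions,truth aligned integer labels in \{0, 1\}.
#' @return A `metric_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
confusion_metrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth),
            all(predictions %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  tp <- sum(predictions == 1L & truth == 1L)
  fn <- sum(predictions == 0L & truth == 1L)
  tn <- sum(predictions == 0L & truth == 0L)
  fp <- sum(predictions == 1L & truth == 0L)
  sens <- if (tp + fn == 0) {
    warning("no host reads in truth; sensitivity undefined"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no microbe reads in truth; specificity undefined"); NA_real_
  } else tn / (tn + fp)
  structure(list(accuracy = (tp + tn) / length(truth), sensitivity = sens,
                 specificity = spec, tp = tp, fp = fp, tn = tn, fn = fn,
                 n = length(truth)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  sensitivity %s  specificity %s  (TP %d FP %d TN %d FN %d, n = %d)\n",
    x$accuracy, format(x$sensitivity, digits = 4),
    format(x$specificity, digits = 4), x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Write a metric report as TSV
#' @param report a `metric_report` (or named list of them, one row each).
#' @param path output file.
#' @export
write_metric_report <- function(report, path) {
  if (inherits(report, "metric_report")) report <- list(overall = report)
  df <- do.call(rbind, lapply(report, function(r)
    as.data.frame(unclass(r))))
  df <- cbind(stratum = names(report), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlapping CG dimer fraction
#'
#' Count of overlapping `"CG"` dimers divided by `length - 1`;
#' case-insensitive. Undefined (error) for sequences shorter than 2.
#'
#' @param bases character vector of sequences.
#' @return Numeric vector in \[0, 1\].
#' @export
cg_fraction <- function(bases) {
  n <- nchar(bases)
  if (any(n < 2))
    stop("cg_fraction is undefined for sequences shorter than 2 bases")
  vapply(toupper(bases), function(s) {
    r <- charToRaw(s)
    ln <- length(r)
    sum(r[-ln] == charToRaw("C") & r[-1] == charToRaw("G")) / (ln - 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Naive CG-content classifier
#'
#' Labels a read microbe (0) iff its CG dimer fraction is at least
#' `cg_threshold`, else host (1) - the direction implied by CG
#' suppression in vertebrates. This is the baseline the learned
#' classifier must beat.
#'
#' @param bases character vector of sequences (length >= 2).
#' @param cg_threshold decision boundary on [cg_fraction()].
#' @return Integer labels in \{0, 1\}.
#' @export
naive_cg_classifier <- function(bases, cg_threshold) {
  ifelse(cg_fraction(bases) >= cg_threshold, 0L, 1L)
}

#' Calibrate the naive CG threshold by Youden's J
#'
#' Scans all observed CG fractions plus \{0, 1\} and returns the smallest
#' threshold maximizing sensitivity + specificity - 1, mirroring the
#' probability-threshold calibration of the learned model.
#'
#' @param bases character vector of sequences.
#' @param labels integer truth labels (1 = host).
#' @return Scalar threshold.
#' @export
calibrate_cg_threshold <- function(bases, labels) {
  stopifnot(length(bases) == length(labels),
            length(unique(labels)) == 2L)
  cg <- cg_fraction(bases)
  grid <- sort(unique(c(0, cg, 1)))
  j <- vapply(grid, function(t)
    mean(cg[labels == 1] < t) + mean(cg[labels == 0] >= t) - 1, numeric(1))
  grid[which(j == max(j))[1]]
}

#' Stratify reads by CG percentage
#'
#' Bins the CG dimer percentage into the five left-closed/right-open
#' strata \[0,1), \[1,2), \[2,4), \[4,10), \[10,100\].
#'
#' @param bases character vector of sequences.
#' @return Factor with the five stratum labels.
#' @export
stratify_by_cg <- function(bases) {
  cut(100 * cg_fraction(bases), breaks = c(0, 1, 2, 4, 10, 100),
      labels = c("[0,1)", "[1,2)", "[2,4)", "[4,10)", "[10,100]"),
      right = FALSE, include.lowest = TRUE)
}

.kmer_set <- function(bases, k) {
  keep <- nchar(bases) >= k
  unique(unlist(lapply(bases[keep], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  })))
}

#' Fraction of host k-mers absent from the microbe set
#'
#' Distinct k-mers are taken as written (single strand, no canonical
#' collapsing); the statistic is `|host k-mers not in microbe set| /
#' |host k-mers|`, the host-exclusive fraction.
#'
#' @param host_bases,microbe_bases character vectors of sequences.
#' @param k k-mer length (11, 13, 15 or 17 in typical use).
#' @return Scalar in \[0, 1\].
#' @export
kmer_uniqueness <- function(host_bases, microbe_bases, k) {
  stopifnot(length(host_bases) >= 1, length(microbe_bases) >= 1, k >= 1)
  hk <- .kmer_set(host_bases, k)
  if (!length(hk))
    stop("kmer_uniqueness undefined: all host reads shorter than k = ", k)
  mk <- .kmer_set(microbe_bases, k)
  mean(!(hk %in% mk))
}
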