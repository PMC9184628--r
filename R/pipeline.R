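#' End-to-end host depletion
#'
#' Reads the input, rejects reads shorter than `inc1`, schedules
#' memory-bounded passes of length bins, scores each bin in fixed-size
#' batches (reads truncated to the bin boundary), maps probabilities to
#' labels through the length-dependent thresholds (selected by each
#' read's original length), and writes `mlprobs.txt` (id, label, length,
#' in input order), `mlpaths.fasta|fastq` (the microbial reads at full
#' original length), and `run.log` to `output_dir`. Output files are
#' written to temporaries and renamed, so an interrupted run leaves no
#' truncated outputs.
#'
#' @param input FASTA/FASTQ file of single-end reads.
#' @param format `"fastq"` or `"fasta"`.
#' @param output_dir output folder (created if needed).
#' @param model a `host_cnn` or path to a checkpoint.
#' @param thresholds a [threshold_table()] or path to one.
#' @param config a [binning_config()].
#' @param seed echoed in the log; inference itself is deterministic.
#' @param threads accepted for interface compatibility; computation is
#'   single-threaded and results never depend on it.
#' @return Invisibly, a list with `records` (id, probability, label,
#'   length), `n_host`, `n_microbe`, `n_rejected`, `n_passes`, `files`.
#' @export
run_host_depletion <- function(input, format = c("fastq", "fasta"),
                               output_dir, model,
                               thresholds = threshold_table(),
                               config = binning_config(), seed = 1L,
                               threads = 1L) {
  format <- match.arg(format)
  t0 <- Sys.time()
  if (is.character(model)) model <- load_model(model)
  if (is.character(thresholds)) thresholds <- read_threshold_table(thresholds)
  stopifnot(inherits(model, "host_cnn"),
            inherits(thresholds, "threshold_table"),
            inherits(config, "binning_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  reads <- read_sequences(input, format)
  passes <- withCallingHandlers(
    plan_passes(reads, config),
    warning = function(w) invokeRestart("muffleWarning"))
  rejected <- attr(passes, "rejected_ids")

  prob <- setNames(rep(NA_real_, nrow(reads)), reads$id)
  for (pass in passes) {
    for (bin in pass) {
      tl <- bin$truncation_length
      for (batch_ids in plan_batches(bin, config)) {
        seqs <- reads$bases[match(batch_ids, reads$id)]
        X <- encode_seqs_cpp(seqs, tl)
        ea <- .engine_args(model)
        prob[batch_ids] <- plogis(as.numeric(
          cnn_forward_cpp(ea$W, ea$b, ea$fw, ea$fb, ea$k, ea$pool, X, tl)))
      }
    }
  }

  accepted <- reads[!(reads$id %in% rejected), , drop = FALSE]
  p <- unname(prob[accepted$id])
  thr <- select_threshold(accepted$length, thresholds)
  records <- data.frame(id = accepted$id, probability = p,
                        label = classify_probability(p, thr),
                        length = accepted$length, stringsAsFactors = FALSE)

  probs_path <- file.path(output_dir, "mlprobs.txt")
  paths_path <- file.path(output_dir, paste0("mlpaths.", format))
  tmp1 <- paste0(probs_path, ".tmp")
  tmp2 <- paste0(paths_path, ".tmp")
  write_predictions(records, tmp1)
  write_microbial_reads(reads, records, format, tmp2)
  file.rename(tmp1, probs_path)
  file.rename(tmp2, paths_path)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  n_host <- sum(records$label == 1L)
  n_microbe <- sum(records$label == 0L)
  log_lines <- c(
    sprintf("hostsieve run | seed=%d threads=%d", seed, threads),
    sprintf("input=%s format=%s", input, format),
    sprintf("reads=%d accepted=%d rejected_short=%d", nrow(reads),
            nrow(records), length(rejected)),
    if (length(rejected))
      sprintf("rejected (length < %d bp): %s", config$inc1,
              paste(rejected, collapse = ",")),
    sprintf("passes=%d", length(passes)),
    sprintf("host=%d microbe=%d", n_host, n_microbe),
    sprintf("elapsed_sec=%.2f", elapsed))
  writeLines(log_lines, file.path(output_dir, "run.log"))

  invisible(list(records = records, n_host = n_host, n_microbe = n_microbe,
                 n_rejected = length(rejected), n_passes = length(passes),
                 files = c(mlprobs = probs_path, mlpaths = paths_path,
                           log = file.path(output_dir, "run.log"))))
}
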