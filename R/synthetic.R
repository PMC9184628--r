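#' Dinucleotide composition profile
#'
#' A first-order Markov chain over A/C/G/T: the first base is drawn from
#' `initial_distribution` and each subsequent base from the transition
#' row of its predecessor. This is enough structure to realize the CG
#' (CpG) suppression that separates vertebrate from microbial sequence.
#'
#' @param transition_matrix 4x4 row-stochastic matrix, rows/cols in
#'   A, C, G, T order.
#' @param initial_distribution length-4 probability vector.
#' @param name label for the profile.
#' @return A `composition_profile`.
#' @export
composition_profile <- function(transition_matrix,
                                initial_distribution = rep(0.25, 4),
                                name = "profile") {
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(4, 4)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition_matrix must be 4x4, non-negative, rows summing to 1")
  if (length(initial_distribution) != 4 || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9)
    stop("initial_distribution must be a length-4 probability vector")
  dimnames(tm) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  structure(list(transition_matrix = tm,
                 initial_distribution = as.numeric(initial_distribution),
                 name = name),
            class = "composition_profile")
}

#' Default host (CG-suppressed) and microbe profiles
#'
#' The host profile is uniform except that the C -> G transition is cut
#' to `cg_transition` (default 0.01) with the freed mass spread over the
#' rest of the C row, reproducing vertebrate CG suppression; the microbe
#' profile is uniform 0.25 everywhere.
#'
#' @param cg_transition probability of G following C in host sequence.
#' @return A [composition_profile()].
#' @export
host_profile <- function(cg_transition = 0.01) {
  tm <- matrix(0.25, 4, 4)
  tm[2, ] <- (1 - cg_transition) / 3
  tm[2, 3] <- cg_transition
  composition_profile(tm, name = "host (CG-suppressed)")
}

#' @rdname host_profile
#' @export
microbe_profile <- function() {
  composition_profile(matrix(0.25, 4, 4), name = "microbe (uniform)")
}

#' Sample sequences from a composition profile
#'
#' @param profile a [composition_profile()].
#' @param length integer vector of sequence lengths (one sequence each).
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return Character vector of sequences.
#' @export
sample_sequence <- function(profile, length, seed = NULL) {
  stopifnot(inherits(profile, "composition_profile"), all(length >= 1))
  if (!is.null(seed)) set.seed(seed)
  as.character(markov_seqs_cpp(as.integer(length),
                               profile$transition_matrix,
                               profile$initial_distribution))
}

#' Apply Nanopore-like noise to sequences
#'
#' Independent per-position edits: each original base is deleted with
#' probability `del_rate`, otherwise substituted (by a uniformly chosen
#' different base) with probability `sub_rate`; independently, a uniform
#' random base is inserted after each original position with probability
#' `ins_rate`. The expected length change is
#' `length * (ins_rate - del_rate)`.
#'
#' @param bases character vector of sequences.
#' @param sub_rate,ins_rate,del_rate per-base rates in \[0, 1\].
#' @param seed optional seed.
#' @return Character vector of noised sequences.
#' @export
apply_noise <- function(bases, sub_rate = 0, ins_rate = 0, del_rate = 0,
                        seed = NULL) {
  stopifnot(all(c(sub_rate, ins_rate, del_rate) >= 0),
            all(c(sub_rate, ins_rate, del_rate) <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(bases)
  alph <- c("A", "C", "G", "T")
  vapply(bases, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    del <- runif(n) < del_rate
    sub <- !del & (runif(n) < sub_rate)
    if (any(sub)) {
      cur <- match(ch[sub], alph)
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      new_idx <- ifelse(is.na(cur), sample.int(4L, sum(sub), replace = TRUE),
                        (cur - 1L + shift) %% 4L + 1L)
      ch[sub] <- alph[new_idx]
    }
    ins <- runif(n) < ins_rate
    insch <- rep(NA_character_, n)
    if (any(ins)) insch[ins] <- sample(alph, sum(ins), replace = TRUE)
    ch[del] <- NA_character_
    out <- c(rbind(ch, insch))
    paste(out[!is.na(out)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Specification of a synthetic read set
#'
#' Lengths follow a log-normal (long-tailed, Nanopore-like) distribution
#' clipped to `[min_length, max_length]`; the default median of 4000 bp
#' mirrors typical long-read sets.
#'
#' @param n_reads number of reads.
#' @param host_fraction fraction of reads labelled host (e.g. 0.01, 0.25,
#'   0.5, 0.75, 0.99).
#' @param length_meanlog,length_sdlog log-normal parameters of the length
#'   distribution.
#' @param min_length,max_length clip bounds (bp); `min_length >= 50`.
#' @param sub_rate,ins_rate,del_rate noise rates for [apply_noise()].
#' @param seed integer seed governing every random choice.
#' @return A `read_set_spec`.
#' @export
read_set_spec <- function(n_reads, host_fraction = 0.5,
                          length_meanlog = log(4000), length_sdlog = 1,
                          min_length = 100, max_length = 30000,
                          sub_rate = 0, ins_rate = 0, del_rate = 0,
                          seed = 1L) {
  stopifnot(n_reads >= 1, host_fraction >= 0, host_fraction <= 1,
            min_length >= 50, max_length >= min_length,
            all(c(sub_rate, ins_rate, del_rate) >= 0),
            all(c(sub_rate, ins_rate, del_rate) <= 1))
  structure(list(n_reads = as.integer(n_reads),
                 host_fraction = host_fraction,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = as.integer(seed)),
            class = "read_set_spec")
}

#' Generate a labeled synthetic read set
#'
#' Draws exactly `round(n_reads * host_fraction)` host reads from
#' `host` and the remainder from `microbe`, applies noise if configured,
#' shuffles the reads, and (optionally) writes a FASTQ/FASTA file plus a
#' truth TSV (`id`, `label`). Quality strings are constant `'I'`;
#' classification never reads them. Byte-identical outputs follow from
#' identical (spec, profiles).
#'
#' @param spec a [read_set_spec()].
#' @param host,microbe [composition_profile()]s.
#' @param dir output directory; `NULL` skips file output.
#' @param format `"fastq"` or `"fasta"`.
#' @param prefix file name stem for `<prefix>.<format>` and
#'   `<prefix>_truth.tsv`.
#' @return data.frame with `id`, `bases`, `quality`, `label`, `length`;
#'   file paths in the `"files"` attribute when written.
#' @export
generate_read_set <- function(spec, host = host_profile(),
                              microbe = microbe_profile(), dir = NULL,
                              format = c("fastq", "fasta"),
                              prefix = "synthetic") {
  stopifnot(inherits(spec, "read_set_spec"))
  format <- match.arg(format)
  set.seed(spec$seed)
  n <- spec$n_reads
  n_host <- round(n * spec$host_fraction)
  lens <- pmin(pmax(round(rlnorm(n, spec$length_meanlog, spec$length_sdlog)),
                    spec$min_length), spec$max_length)
  label <- rep(c(1L, 0L), c(n_host, n - n_host))
  bases <- character(n)
  if (n_host > 0)
    bases[seq_len(n_host)] <- sample_sequence(host, lens[seq_len(n_host)])
  if (n_host < n)
    bases[(n_host + 1):n] <- sample_sequence(microbe, lens[(n_host + 1):n])
  if (spec$sub_rate > 0 || spec$ins_rate > 0 || spec$del_rate > 0)
    bases <- apply_noise(bases, spec$sub_rate, spec$ins_rate, spec$del_rate)
  perm <- sample(n)
  bases <- bases[perm]
  label <- label[perm]
  reads <- data.frame(id = sprintf("read_%06d", seq_len(n)), bases = bases,
                      quality = strrep("I", nchar(bases)),
                      label = label, length = nchar(bases),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    seq_path <- file.path(dir, paste0(prefix, ".", format))
    truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
    write_sequences(reads, seq_path, format)
    write.table(reads[, c("id", "label")], truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    attr(reads, "files") <- c(sequences = seq_path, truth = truth_path)
  }
  reads
}
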