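#' Read single-end sequences from FASTA or FASTQ
#'
#' Parses the file with Biostrings and returns one row per record with the
#' identifier taken up to the first whitespace. FASTQ quality strings are
#' kept (and must match the sequence length); FASTA records get `NA`
#' quality. Lowercase (soft-masked) bases and IUPAC ambiguity codes are
#' accepted.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return A data.frame with columns `id`, `bases`, `quality`, `length`.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "fasta") {
    xs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) .reraise_parse(path, format, e))
    qual <- rep(NA_character_, length(xs))
  } else {
    # qualities are extracted inside the tryCatch: on structurally broken
    # records the Biostrings parser returns corrupt quality strings
    # rather than failing
    parsed <- tryCatch({
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      q <- as.character(S4Vectors::mcols(x)$qualities)
      bad <- which(nchar(q) != Biostrings::width(x))
      if (length(bad))
        stop("quality length ", nchar(q)[bad[1]],
             " != sequence length ", Biostrings::width(x)[bad[1]])
      list(x = x, q = q)
    }, error = function(e) .reraise_parse(path, format, e))
    xs <- parsed$x
    qual <- parsed$q
  }
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids))
    stop("duplicated read id in '", path, "': ",
         ids[anyDuplicated(ids)][1])
  data.frame(id = ids, bases = as.character(xs), quality = qual,
             length = Biostrings::width(xs), stringsAsFactors = FALSE)
}

# On a Biostrings parse failure, scan the file to name the offending
# record index before re-raising.
.reraise_parse <- function(path, format, e) {
  idx <- tryCatch(.locate_malformed(path, format), error = function(e2) NA)
  stop("parse error in ", format, " record ",
       if (is.na(idx)) "(unknown index)" else idx, " of '", path, "': ",
       conditionMessage(e), call. = FALSE)
}

.locate_malformed <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "fastq") {
    nrec <- ceiling(length(lines) / 4)
    for (r in seq_len(nrec)) {
      blk <- lines[(4 * r - 3):min(length(lines), 4 * r)]
      if (length(blk) < 4 || !startsWith(blk[1], "@") ||
          !startsWith(blk[3], "+") || nchar(blk[2]) != nchar(blk[4]))
        return(r)
    }
  } else {
    if (length(lines) && !startsWith(lines[1], ">")) return(1L)
  }
  NA_integer_
}

#' Write sequences to FASTA or FASTQ
#'
#' @param reads data.frame with `id`, `bases` and (for FASTQ) `quality`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fastq") {
    if (any(is.na(reads$quality)))
      stop("FASTQ output requires quality strings for every read")
    if (any(nchar(reads$quality) != nchar(reads$bases)))
      stop("quality strings must match sequence lengths")
    # written directly: the Biostrings FASTQ writer uses a fixed line
    # buffer and cannot emit Nanopore-length (> ~20 kb) records
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$bases, "+",
                               reads$quality)), con)
  } else {
    xs <- Biostrings::DNAStringSet(reads$bases)
    names(xs) <- reads$id
    Biostrings::writeXStringSet(xs, path, format = "fasta")
  }
  invisible(path)
}

#' One-hot encode a sequence at a fixed length
#'
#' A/C/G/T map to the unit vectors `[1,0,0,0]`, `[0,1,0,0]`, `[0,0,1,0]`,
#' `[0,0,0,1]`; ambiguity codes (N, R, Y, ...) become all-zero rows so
#' they contribute nothing to any convolution; matching is
#' case-insensitive. Bases beyond `target_length` are discarded
#' (truncation); the binning module guarantees `target_length` never
#' exceeds a read's length in the pipeline.
#'
#' @param bases a single sequence string.
#' @param target_length number of leading bases to encode.
#' @return A `target_length x 4` matrix with columns A, C, G, T.
#' @export
one_hot_encode <- function(bases, target_length) {
  stopifnot(is.character(bases), length(bases) == 1L, target_length >= 1)
  if (target_length > nchar(bases))
    stop("target_length ", target_length, " exceeds sequence length ",
         nchar(bases))
  ch <- strsplit(toupper(substr(bases, 1L, target_length)), "",
                 fixed = TRUE)[[1]]
  m <- matrix(0, target_length, 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(ch, c("A", "C", "G", "T"))
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1
  m
}

#' Write the prediction table (mlprobs)
#'
#' Tab-separated, headerless, one row per record with columns id, label
#' (1 = host, 0 = microbe) and original read length, preserving input
#' order.
#'
#' @param records data.frame with `id`, `label`, `length`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  stopifnot(all(c("id", "label", "length") %in% names(records)))
  stopifnot(all(records$label %in% c(0L, 1L)))
  write.table(records[, c("id", "label", "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the microbial fraction (mlpaths)
#'
#' Emits exactly the reads whose label is 0, at full original length
#' (truncation is internal to classification only, so downstream
#' metagenomic classifiers see complete reads), in the same format as the
#' input.
#'
#' @param reads data.frame from [read_sequences()].
#' @param records data.frame with `id` and `label` covering a subset of
#'   `reads$id`.
#' @param format `"fasta"` or `"fastq"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_microbial_reads <- function(reads, records, format = c("fasta", "fastq"),
                                  path) {
  format <- match.arg(format)
  miss <- setdiff(records$id, reads$id)
  if (length(miss))
    stop("record id(s) not present among reads: ",
         paste(utils::head(miss, 3), collapse = ", "))
  keep <- reads$id %in% records$id[records$label == 0L]
  write_sequences(reads[keep, , drop = FALSE], path, format)
}
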