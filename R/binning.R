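#' Inference-time binning configuration
#'
#' Reads are grouped by length into truncation bins: increments of `inc1`
#' up to `seq_cutoff`, increments of `inc2` above it, and a hard cap of
#' `max_len` beyond which reads are truncated. `lim` bounds the total
#' truncated bases staged per classification pass and `batch_max_len`
#' bounds the bases per forward batch (so a bin of truncation length L is
#' scored in batches of `floor(batch_max_len / L)` reads).
#'
#' @param seq_cutoff length (bp) at which the bin increment switches.
#' @param inc1 bin increment below `seq_cutoff`; reads shorter than
#'   `inc1` are rejected.
#' @param inc2 bin increment above `seq_cutoff`.
#' @param max_len truncation cap (bp).
#' @param lim total truncated bp admitted per pass.
#' @param batch_max_len total bp per forward batch.
#' @return A `binning_config` list.
#' @export
binning_config <- function(seq_cutoff = 5000, inc1 = 50, inc2 = 1000,
                           max_len = 6000, lim = 1200000000,
                           batch_max_len = 900000) {
  cfg <- list(seq_cutoff = seq_cutoff, inc1 = inc1, inc2 = inc2,
              max_len = max_len, lim = lim, batch_max_len = batch_max_len)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stop("all binning_config fields must be positive scalars")
  if (cfg$inc1 > cfg$inc2) stop("inc1 must not exceed inc2")
  if (cfg$seq_cutoff > cfg$max_len) stop("seq_cutoff must not exceed max_len")
  if (cfg$seq_cutoff %% cfg$inc1 != 0) stop("inc1 must divide seq_cutoff")
  structure(cfg, class = "binning_config")
}

#' Read / write a binning configuration file
#'
#' Plain two-column key/value TSV carrying the six [binning_config()]
#' fields.
#'
#' @param path file path.
#' @param config a `binning_config`.
#' @return `read_binning_config` returns a `binning_config`.
#' @export
read_binning_config <- function(path) {
  kv <- read.table(path, sep = "\t", col.names = c("key", "value"),
                   stringsAsFactors = FALSE)
  do.call(binning_config, as.list(setNames(kv$value, kv$key)))
}

#' @rdname read_binning_config
#' @export
write_binning_config <- function(config, path) {
  stopifnot(inherits(config, "binning_config"))
  write.table(data.frame(key = names(config), value = unlist(config)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Map a read length to its truncation length
#'
#' Lengths floor to the nearest `inc1` multiple up to `seq_cutoff`, to the
#' nearest `inc2` multiple between `seq_cutoff` and `max_len`, and cap at
#' `max_len`. The bin's truncation length is its lower boundary, so it
#' never exceeds any member's length. Lengths below `inc1` return `NA`
#' (reject-read signal).
#'
#' @param length integer vector of read lengths (bp).
#' @param config a [binning_config()].
#' @return Integer vector of truncation lengths (`NA` = rejected).
#' @export
assign_bin <- function(length, config = binning_config()) {
  stopifnot(inherits(config, "binning_config"))
  out <- ifelse(length > config$max_len, config$max_len,
         ifelse(length > config$seq_cutoff,
                (length %/% config$inc2) * config$inc2,
                (length %/% config$inc1) * config$inc1))
  out[length < config$inc1] <- NA
  as.integer(out)
}

#' Group reads into length bins
#'
#' Every accepted read lands in exactly one bin keyed by
#' [assign_bin()] of its length; within-bin order follows input order.
#' Rejected reads (shorter than `inc1`) are dropped with a warning and
#' recorded in the `"rejected_ids"` attribute.
#'
#' @param reads data.frame with `id` and `length` (e.g. from
#'   [read_sequences()]).
#' @param config a [binning_config()].
#' @return List of bins, ascending in truncation length; each bin is a
#'   list with `truncation_length` and `member_ids`.
#' @export
build_bins <- function(reads, config = binning_config()) {
  tl <- assign_bin(reads$length, config)
  rejected <- reads$id[is.na(tl)]
  if (length(rejected))
    warning(length(rejected), " read(s) shorter than inc1 = ", config$inc1,
            " bp were rejected")
  keep <- !is.na(tl)
  groups <- split(reads$id[keep], tl[keep])
  lv <- as.integer(names(groups))
  o <- order(lv)
  bins <- lapply(o, function(i)
    list(truncation_length = lv[i], member_ids = groups[[i]]))
  attr(bins, "rejected_ids") <- rejected
  bins
}

#' Split one bin into fixed-size batches
#'
#' Batch size is `N = floor(batch_max_len / truncation_length)`; batches
#' cover the members in order and all but the last hold exactly `N` ids.
#'
#' @param bin a bin from [build_bins()].
#' @param config a [binning_config()].
#' @return List of character vectors of member ids.
#' @export
plan_batches <- function(bin, config = binning_config()) {
  tl <- bin$truncation_length
  if (tl > config$batch_max_len)
    stop("truncation length ", tl, " exceeds batch_max_len ",
         config$batch_max_len)
  n <- config$batch_max_len %/% tl
  ids <- bin$member_ids
  if (!length(ids)) return(list())
  unname(split(ids, (seq_along(ids) - 1L) %/% n))
}

#' Schedule memory-bounded classification passes
#'
#' Greedy by ascending truncation length: bins are admitted to the
#' current pass while the pass's total truncated bases stay within `lim`;
#' a bin too large for the remaining budget is split across consecutive
#' passes, and later passes otherwise contain only strictly longer bins.
#' This mirrors the streaming scheme of classifying what fits in memory
#' and then returning to the input for the larger sequences.
#'
#' @param reads data.frame with `id` and `length`.
#' @param config a [binning_config()].
#' @return List of passes; each pass is a list of bins as in
#'   [build_bins()]. Rejected ids are kept in the `"rejected_ids"`
#'   attribute.
#' @export
plan_passes <- function(reads, config = binning_config()) {
  bins <- build_bins(reads, config)
  passes <- list()
  cur <- list()
  cur_bp <- 0
  for (bin in bins) {
    ids <- bin$member_ids
    tl <- bin$truncation_length
    while (length(ids)) {
      fit <- (config$lim - cur_bp) %/% tl
      if (fit < 1) {
        if (!length(cur)) {  # single read larger than lim: best effort
          warning("truncation length ", tl, " exceeds lim = ", config$lim,
                  "; scheduling one read per pass")
          fit <- 1
        } else {
          passes <- c(passes, list(cur))
          cur <- list()
          cur_bp <- 0
          next
        }
      }
      take <- min(fit, length(ids))
      cur <- c(cur, list(list(truncation_length = tl,
                              member_ids = ids[seq_len(take)])))
      cur_bp <- cur_bp + take * tl
      ids <- ids[-seq_len(take)]
    }
  }
  if (length(cur)) passes <- c(passes, list(cur))
  attr(passes, "rejected_ids") <- attr(bins, "rejected_ids")
  passes
}
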