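#' Reference-based per-nucleotide attribution
#'
#' DeepLift-style rescale-rule contribution scores of the pre-squashing
#' logit (positive pushes toward host) against `n_references` references,
#' each a seeded random permutation of the input's own positions (so base
#' composition is preserved), averaged over references. Channel scores
#' are summed per position, and the per-position scores are aggregated
#' into sliding k-mer windows where k is the model's first-layer kernel
#' length (15 by default).
#'
#' Attribution targets the logit rather than the probability because the
#' completeness identity - per-position scores summing to
#' `logit(input) - mean(logit(reference))` - is exact on the logit scale.
#'
#' @param model a `host_cnn`.
#' @param bases a single sequence within the model's supported lengths.
#' @param n_references number of permuted references to average over.
#' @param seed integer seed for the permutations.
#' @param id optional read identifier carried into reports.
#' @return An `attribution_result`: `per_position` (length-L numeric),
#'   `kmer_scores` (named by 1-based window start; window i sums
#'   positions i..i+k-1), `k`, `bases`, `id`, `input_logit`,
#'   `reference_logits`.
#' @export
attribute_read <- function(model, bases, n_references = 20L, seed = 1L,
                           id = NULL) {
  stopifnot(inherits(model, "host_cnn"), is.character(bases),
            length(bases) == 1L, n_references >= 1)
  L <- nchar(bases)
  .check_length(model, L)
  x <- encode_seqs_cpp(bases, L)
  set.seed(seed)
  refs <- do.call(cbind, lapply(seq_len(n_references), function(r)
    x[, sample.int(L), drop = FALSE]))
  ea <- .engine_args(model)
  dl <- deeplift_cpp(ea$W, ea$b, ea$fw, ea$fb, ea$k, ea$pool, x, refs, L)
  pp <- as.numeric(colSums(dl$scores))
  k <- model$config$kernel_length
  ks <- if (L >= k) {
    starts <- seq_len(L - k + 1L)
    setNames(vapply(starts, function(i) sum(pp[i:(i + k - 1L)]),
                    numeric(1)), starts)
  } else numeric(0)
  structure(list(per_position = pp, kmer_scores = ks, k = k, bases = bases,
                 id = if (is.null(id)) NA_character_ else id,
                 input_logit = dl$input_logit,
                 reference_logits = as.numeric(dl$ref_logits)),
            class = "attribution_result")
}

#' Rank k-mers by mean attribution
#'
#' Pools every k-mer window across the given results, groups windows by
#' their base sequence, ranks the groups by mean score, and returns the
#' `m` most host-pushing and `m` most microbe-pushing k-mers with their
#' mean scores, instance counts, and mean per-position score profiles.
#'
#' @param results an `attribution_result` or list of them.
#' @param m how many k-mers per direction.
#' @return A `kmer_ranking` list: data.frames `top` and `bottom`
#'   (columns `kmer`, `mean_score`, `n`), and named lists
#'   `top_profiles`, `bottom_profiles` of length-k numeric vectors.
#' @export
top_kmers <- function(results, m = 5L) {
  if (inherits(results, "attribution_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  tabs <- lapply(results, function(r) {
    if (!length(r$kmer_scores)) return(NULL)
    starts <- as.integer(names(r$kmer_scores))
    data.frame(kmer = substring(r$bases, starts, starts + r$k - 1L),
               score = as.numeric(r$kmer_scores), start = starts,
               read = seq_along(starts) * 0L, stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, tabs)
  if (is.null(pool) || !nrow(pool)) stop("no k-mer windows to rank")
  profs <- do.call(rbind, lapply(results, function(r) {
    if (!length(r$kmer_scores)) return(NULL)
    starts <- as.integer(names(r$kmer_scores))
    t(vapply(starts, function(i) r$per_position[i:(i + r$k - 1L)],
             numeric(results[[1]]$k)))
  }))
  agg <- aggregate(score ~ kmer, pool, mean)
  cnt <- as.data.frame(table(pool$kmer), stringsAsFactors = FALSE)
  names(cnt) <- c("kmer", "n")
  agg <- merge(agg, cnt, by = "kmer")
  names(agg)[names(agg) == "score"] <- "mean_score"
  if (nrow(agg) < m)
    warning("only ", nrow(agg), " distinct k-mers available (m = ", m, ")")
  mm <- min(m, nrow(agg))
  o <- order(agg$mean_score, agg$kmer, decreasing = TRUE)
  top <- agg[o[seq_len(mm)], , drop = FALSE]
  o2 <- order(agg$mean_score, agg$kmer)
  bottom <- agg[o2[seq_len(mm)], , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  mean_profile <- function(km) colMeans(profs[pool$kmer == km, , drop = FALSE])
  structure(list(top = top, bottom = bottom,
                 top_profiles = setNames(lapply(top$kmer, mean_profile),
                                         top$kmer),
                 bottom_profiles = setNames(lapply(bottom$kmer, mean_profile),
                                            bottom$kmer)),
            class = "kmer_ranking")
}

#' Write an attribution report
#'
#' One row per k-mer window: read id, 1-based window start, k-mer
#' sequence, summed score.
#'
#' @param results an `attribution_result` or list of them.
#' @param path output TSV.
#' @export
write_attribution_report <- function(results, path) {
  if (inherits(results, "attribution_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    starts <- as.integer(names(r$kmer_scores))
    data.frame(id = r$id, start = starts,
               kmer = substring(r$bases, starts, starts + r$k - 1L),
               score = as.numeric(r$kmer_scores), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-position score track (BED-like)
#'
#' 0-based half-open coordinates: columns id, start, end, score, one row
#' per position.
#'
#' @param result an `attribution_result`.
#' @param path output file.
#' @export
write_position_track <- function(result, path) {
  stopifnot(inherits(result, "attribution_result"))
  L <- length(result$per_position)
  write.table(data.frame(id = result$id, start = 0:(L - 1), end = 1:L,
                         score = result$per_position),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
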