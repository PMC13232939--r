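# Naive parallel k-mer counting and a whole-file sequence scan, both built
# on the map-reduce record-processing interface, plus the normalized
# time/storage composite score used to compare formats.

# all length-k windows of one sequence (possibly empty)
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

merge_counts <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  nm <- union(names(a), names(b))
  out <- setNames(numeric(length(nm)), nm)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Count k-mers in a BINSEQ file
#'
#' Slides a window of size `k` over the decoded sequence of every record
#' (both mates for paired files) and tallies each literal window. Each
#' worker accumulates windows in local state; at every batch boundary the
#' local tally is folded into the worker's running count table and cleared,
#' and per-worker tables are summed at the end. No reverse-complement
#' canonicalization is applied; windows containing `N` (four-bit sources)
#' are counted as literal strings.
#'
#' @param source a `.bq`/`.vbq` path or open handle.
#' @param k window size (>= 1).
#' @param n_workers,batch_size see [process_parallel()].
#' @return A tibble with columns `kmer` and `count`, sorted by `kmer`;
#'   total count equals `sum(max(0, L - k + 1))` over all sequences.
#' @export
count_kmers <- function(source, k, n_workers = 1, batch_size = 4096) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) argument_error("k must be a positive integer")
  proc <- record_processor(
    init_state = function() list(),
    init_result = function() numeric(0),
    map = function(state, record) {
      state[[length(state) + 1L]] <- seq_kmers(record$primary, k)
      if (!is.null(record$extended))
        state[[length(state) + 1L]] <- seq_kmers(record$extended, k)
      state
    },
    reduce = function(result, state) {
      if (!length(state)) return(result)
      tab <- table(unlist(state, use.names = FALSE))
      merge_counts(result, setNames(as.numeric(tab), names(tab)))
    },
    combine = merge_counts
  )
  counts <- process_parallel(source, proc, n_workers, batch_size)
  counts <- counts[order(names(counts))]
  tibble::tibble(kmer = names(counts), count = as.numeric(counts))
}

#' Scan all sequences of a BINSEQ file
#'
#' The baseline sequence-access workload: decode every record and total
#' the records and bases seen.
#'
#' @param source a `.bq`/`.vbq` path or open handle.
#' @param n_workers parallel workers.
#' @return A list with `records` and `bases`.
#' @export
scan_sequences <- function(source, n_workers = 1) {
  proc <- record_processor(
    init_state = function() c(records = 0, bases = 0),
    init_result = function() c(records = 0, bases = 0),
    map = function(state, record) {
      state["records"] <- state["records"] + 1
      state["bases"] <- state["bases"] + nchar(record$primary) +
        (if (is.null(record$extended)) 0 else nchar(record$extended))
      state
    },
    reduce = `+`,
    combine = `+`
  )
  res <- process_parallel(source, proc, n_workers)
  list(records = unname(res["records"]), bases = unname(res["bases"]))
}

#' Normalized time/storage composite score
#'
#' Min-max normalizes read times and file sizes across formats and
#' averages them: `m_i = (t_norm_i + s_norm_i) / 2`, so 0 is best on both
#' axes and 1 worst on both. Requires at least two entries and
#' non-degenerate ranges on both metrics.
#'
#' @param times elapsed times (seconds), one per format.
#' @param sizes file sizes (bytes or MB), one per format.
#' @return A tibble with `time`, `size`, `time_norm`, `size_norm`,
#'   `score`, all scores in `[0, 1]`.
#' @examples
#' composite_score(c(1, 2, 3), c(30, 20, 10))$score # 0.5 0.5 0.5
#' @export
composite_score <- function(times, sizes) {
  if (length(times) < 2 || length(times) != length(sizes))
    argument_error("need >= 2 paired (time, size) entries")
  rt <- range(times)
  rs <- range(sizes)
  if (diff(rt) == 0 || diff(rs) == 0)
    binseq_error("degenerate range: max equals min in times or sizes",
                 "binseq_normalization_error")
  t_norm <- (times - rt[1]) / diff(rt)
  s_norm <- (sizes - rs[1]) / diff(rs)
  tibble::tibble(time = times, size = sizes, time_norm = t_norm,
                 size_norm = s_norm, score = (t_norm + s_norm) / 2)
}
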