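# Hook-based map-reduce over BQ/VBQ sources.
#
# The contract mirrors classic map-reduce: a per-record map hook folds each
# record into worker-local state, and a per-batch reduce hook merges that
# local state into the worker's running result every `batch_size` records
# (and once more at drain when records are pending). Results must not
# depend on the order in which workers see records: with commutative,
# associative aggregation the merged result is identical for any worker
# count and scheduling. BQ sources are partitioned into contiguous record
# ranges (cheap because of closed-form record offsets); VBQ sources are
# partitioned by whole blocks, the format's parallel unit.

#' Define a record processor
#'
#' @param map `function(state, record) -> state`: folds one record into
#'   worker-local state. `record` is a list with `primary` and, when
#'   present in the file, `extended`, `qual_primary`, `qual_extended`,
#'   `header_primary`, `header_extended`, `flag`.
#' @param reduce `function(result, state) -> result`: merges local state
#'   into the worker's result at each batch boundary; called at least once
#'   after a worker's final record whenever records are pending.
#' @param combine `function(result, result) -> result`: merges results of
#'   two workers; required when `n_workers > 1`. Must be commutative and
#'   associative for scheduling-independent answers.
#' @param init_state zero-argument function creating fresh local state
#'   (default `NULL` state).
#' @param init_result zero-argument function creating the initial result.
#' @return A `record_processor` object for [process_parallel()].
#' @export
record_processor <- function(map, reduce, combine = NULL,
                             init_state = function() NULL,
                             init_result = function() NULL) {
  stopifnot(is.function(map), is.function(reduce),
            is.null(combine) || is.function(combine),
            is.function(init_state), is.function(init_result))
  structure(list(map = map, reduce = reduce, combine = combine,
                 init_state = init_state, init_result = init_result),
            class = "record_processor")
}

#' Open a BINSEQ source by sniffing its magic number
#'
#' @param path a `.bq` or `.vbq` file.
#' @return A `bq_file` or `vbq_file` handle.
#' @export
binseq_open <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4)
  close(con)
  if (identical(magic, BQ_MAGIC)) bq_open(path)
  else if (identical(magic, VBQ_MAGIC)) vbq_open(path)
  else format_error(sprintf("%s is neither a BQ nor a VBQ file", path))
}

binseq_records <- function(x) {
  if (inherits(x, "bq_file")) x$header$n_records else x$n_records
}

# split 1..n into at most k contiguous runs of near-equal size
split_ranges <- function(n, k) {
  if (n == 0) return(list())
  k <- max(1L, min(k, n))
  bounds <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(j) c(lo = bounds[j], hi = bounds[j + 1]))
}

# tibble chunk -> list of per-record lists
rows_as_records <- function(chunk) {
  cols <- as.list(chunk)
  nms <- names(cols)
  lapply(seq_len(nrow(chunk)), function(j) {
    r <- lapply(cols, `[[`, j)
    names(r) <- nms
    r
  })
}

# run map over a chunk of records, reducing every batch_size records
fold_chunk <- function(recs, proc, ctx) {
  for (r in recs) {
    ctx$state <- proc$map(ctx$state, r)
    ctx$pending <- ctx$pending + 1L
    if (ctx$pending == ctx$batch_size) {
      ctx$result <- proc$reduce(ctx$result, ctx$state)
      ctx$state <- proc$init_state()
      ctx$pending <- 0L
    }
  }
}

worker_bq <- function(path, part, proc, batch_size) {
  f <- bq_open(path)
  on.exit(close(f))
  ctx <- new.env(parent = emptyenv())
  ctx$result <- proc$init_result(); ctx$state <- proc$init_state()
  ctx$pending <- 0L; ctx$batch_size <- batch_size
  at <- part["lo"]
  while (at < part["hi"]) {
    take <- min(part["hi"] - at, max(batch_size, 4096))
    fold_chunk(rows_as_records(bq_read(f, first = at, n = take)), proc, ctx)
    at <- at + take
  }
  if (ctx$pending > 0L) ctx$result <- proc$reduce(ctx$result, ctx$state)
  ctx$result
}

worker_vbq <- function(path, block_rows, proc, batch_size) {
  f <- vbq_open(path)
  on.exit(close(f))
  ctx <- new.env(parent = emptyenv())
  ctx$result <- proc$init_result(); ctx$state <- proc$init_state()
  ctx$pending <- 0L; ctx$batch_size <- batch_size
  for (j in block_rows)
    fold_chunk(rows_as_records(read_block(f, f$index[j, , drop = FALSE])),
               proc, ctx)
  if (ctx$pending > 0L) ctx$result <- proc$reduce(ctx$result, ctx$state)
  ctx$result
}

#' Process a BINSEQ file with map-reduce hooks
#'
#' Every record of the source is passed to the processor's map hook exactly
#' once; the reduce hook fires every `batch_size` records per worker and at
#' drain. With `n_workers = 1` the computation is a plain serial loop; with
#' more workers, disjoint partitions covering all records are processed
#' concurrently (forked processes) and per-worker results are merged with
#' the processor's `combine`.
#'
#' @param source a `.bq`/`.vbq` path or an open handle.
#' @param processor a [record_processor()].
#' @param n_workers number of parallel workers (>= 1).
#' @param batch_size records per reduce batch (>= 1); default 4096.
#' @return The merged result.
#' @export
process_parallel <- function(source, processor, n_workers = 1,
                             batch_size = 4096) {
  stopifnot(inherits(processor, "record_processor"))
  n_workers <- as.integer(n_workers)
  batch_size <- as.integer(batch_size)
  if (n_workers < 1) argument_error("n_workers must be >= 1")
  if (batch_size < 1) argument_error("batch_size must be >= 1")
  f <- if (inherits(source, c("bq_file", "vbq_file"))) source
       else binseq_open(source)
  if (!inherits(source, c("bq_file", "vbq_file"))) close(f)  # workers reopen
  path <- f$path

  if (inherits(f, "bq_file")) {
    parts <- split_ranges(f$header$n_records, n_workers)
    run <- function(p) worker_bq(path, p, processor, batch_size)
    label <- function(p) sprintf("records [%d, %d)", p["lo"], p["hi"])
  } else {
    parts <- split_ranges(nrow(f$index), n_workers)
    parts <- lapply(parts, function(p) seq.int(p["lo"] + 1L, p["hi"]))
    run <- function(p) worker_vbq(path, p, processor, batch_size)
    label <- function(p) sprintf("blocks %d-%d", min(p), max(p))
  }

  if (!length(parts)) return(processor$init_result())
  if (length(parts) > 1 && is.null(processor$combine))
    argument_error("processor needs a combine function for n_workers > 1")

  safely <- function(p) tryCatch(list(ok = run(p)),
                                 error = function(e) list(err = e))
  results <- if (n_workers == 1 || length(parts) == 1) {
    lapply(parts, safely)
  } else {
    parallel::mclapply(parts, safely, mc.cores = n_workers)
  }
  for (j in seq_along(results)) {
    r <- results[[j]]
    if (!is.list(r) || !is.null(r$err)) {
      msg <- if (is.list(r)) conditionMessage(r$err) else as.character(r)
      binseq_error(sprintf("worker failed on partition %d (%s): %s",
                           j, label(parts[[j]]), msg), "binseq_worker_error")
    }
  }
  out <- results[[1]]$ok
  for (j in seq_along(results)[-1])
    out <- processor$combine(out, results[[j]]$ok)
  out
}
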