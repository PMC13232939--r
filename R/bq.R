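# BQ container: 32-byte header followed by fixed-size records, giving O(1)
# random access by closed-form offset arithmetic.
#
# Header layout (little-endian, 32 bytes):
#   0-3   magic "BSQ\x01"
#   4     version (1)
#   5     encoding bits per base (2 or 4)
#   6     flag_enabled (0/1)
#   7     reserved (0)
#   8-11  slen  u32, primary sequence length in bases (>= 1)
#   12-15 xlen  u32, extended sequence length (0 = unpaired)
#   16-31 reserved, must be zero
#
# Each record is: [flag u64]? [primary words] [extended words]?, giving the
# record-size identity S = F + W*(ceil(N/B) + ceil(M/B)) with F in {0, 8}.

#' BQ file header
#'
#' Describes a BQ file: primary (and optional extended/mate) sequence
#' length, packing scheme, and whether each record carries a 64-bit flag
#' slot for implementation-defined metadata. Serialized headers are exactly
#' 32 bytes.
#'
#' @param slen primary sequence length in bases (>= 1).
#' @param xlen extended (second mate) length in bases; 0 means unpaired.
#' @param encoding bits per base, 2 or 4.
#' @param flag_enabled store a 64-bit flag word per record?
#' @return A `bq_header` object.
#' @examples
#' h <- bq_header(slen = 100)
#' record_size(h)        # 32 bytes: 8 * ceiling(100 / 32)
#' record_offset(10, h)  # 32 + 10 * 32
#' @export
bq_header <- function(slen, xlen = 0, encoding = 2, flag_enabled = FALSE) {
  slen <- as.numeric(slen)
  xlen <- as.numeric(xlen)
  if (length(slen) != 1 || is.na(slen) || slen < 1)
    argument_error("slen must be a single length >= 1")
  if (length(xlen) != 1 || is.na(xlen) || xlen < 0)
    argument_error("xlen must be >= 0")
  scheme <- encoding_scheme(encoding)
  structure(
    list(slen = slen, xlen = xlen, encoding = scheme$bits_per_base,
         flag_enabled = isTRUE(flag_enabled)),
    class = "bq_header"
  )
}

#' @export
print.bq_header <- function(x, ...) {
  cat(sprintf("<bq_header: slen=%d xlen=%d %d-bit flag=%s record=%dB>\n",
              x$slen, x$xlen, x$encoding,
              if (x$flag_enabled) "on" else "off", record_size(x)))
  invisible(x)
}

#' Fixed record size and record offsets
#'
#' `record_size()` evaluates the record-size identity
#' `S = F + W * (ceiling(N/B) + ceiling(M/B))` where `F` is the flag-field
#' size (0 or 8 bytes), `W = 8` the word size, `B` the bases per word, and
#' `N`, `M` the primary/extended lengths (the `M` term is absent for
#' unpaired files). `record_offset()` gives the byte position of zero-based
#' record `i`: `P_i = H + i * S` with `H = 32` the header size.
#'
#' @param header a [bq_header()].
#' @return Byte counts / byte offsets as numerics.
#' @export
record_size <- function(header) {
  stopifnot(inherits(header, "bq_header"))
  scheme <- encoding_scheme(header$encoding)
  f <- if (header$flag_enabled) 8 else 0
  words <- words_needed(header$slen, scheme) +
    if (header$xlen > 0) words_needed(header$xlen, scheme) else 0L
  f + scheme$word_size * words
}

#' @rdname record_size
#' @param i zero-based record index (vectorized).
#' @export
record_offset <- function(i, header) {
  if (any(i < 0)) argument_error("record index must be >= 0")
  HEADER_BYTES + i * record_size(header)
}

serialize_bq_header <- function(header) {
  r <- raw(HEADER_BYTES)
  r[1:4] <- BQ_MAGIC
  r[5] <- as.raw(FORMAT_VERSION)
  r[6] <- as.raw(header$encoding)
  r[7] <- as.raw(as.integer(header$flag_enabled))
  r[9:12] <- u32_raw(header$slen)
  r[13:16] <- u32_raw(header$xlen)
  r
}

parse_bq_header <- function(r) {
  if (length(r) != HEADER_BYTES || !identical(r[1:4], BQ_MAGIC))
    format_error("not a BQ file: bad magic")
  if (as.integer(r[5]) != FORMAT_VERSION)
    format_error(sprintf("unsupported BQ version %d", as.integer(r[5])))
  enc <- as.integer(r[6])
  if (!enc %in% c(2L, 4L))
    format_error(sprintf("invalid encoding field %d", enc))
  if (any(r[c(8, 17:32)] != as.raw(0)))
    format_error("reserved header bytes are not zero")
  bq_header(slen = raw_u32(r[9:12]), xlen = raw_u32(r[13:16]),
            encoding = enc, flag_enabled = as.integer(r[7]) == 1L)
}

#' Incremental BQ writer
#'
#' Opens a BQ file for writing and returns a writer handle whose
#' `$write(primary, extended, flags)` method appends record chunks and whose
#' `$close()` method finalizes the file (verifying the file-size identity
#' `size = 32 + n * S`). All primary sequences must have length `slen` and
#' all extended sequences length `xlen`; variable-length data belongs in
#' VBQ.
#'
#' @param path output file path.
#' @inheritParams bq_header
#' @return A `bq_writer` handle (environment) with `$write()`, `$close()`
#'   and `$records_written()`.
#' @export
bq_writer <- function(path, slen, xlen = 0, encoding = 2, flag_enabled = FALSE) {
  header <- bq_header(slen, xlen, encoding, flag_enabled)
  con <- file(path, "wb")
  writeBin(serialize_bq_header(header), con)
  n <- 0
  self <- new.env(parent = emptyenv())

  self$write <- function(primary, extended = NULL, flags = NULL) {
    primary <- as.character(primary)
    bad <- which(nchar(primary) != header$slen)
    if (length(bad))
      format_error(sprintf(
        "record %d: primary length %d does not match slen %d (use VBQ for variable-length records)",
        n + bad[1], nchar(primary[bad[1]]), header$slen))
    if (header$xlen == 0 && !is.null(extended))
      argument_error("unpaired file (xlen = 0) cannot take extended sequences")
    if (header$xlen > 0) {
      if (is.null(extended) || length(extended) != length(primary))
        pairing_error("paired file: extended sequences required for every record")
      extended <- as.character(extended)
      bad <- which(nchar(extended) != header$xlen)
      if (length(bad))
        format_error(sprintf(
          "record %d: extended length %d does not match xlen %d (use VBQ for variable-length records)",
          n + bad[1], nchar(extended[bad[1]]), header$xlen))
    }
    blob <- .cpp_pack_records(primary,
                              if (header$xlen > 0) extended else NULL,
                              if (header$flag_enabled) as.numeric(flags) else NULL,
                              as.integer(header$slen), as.integer(header$xlen),
                              header$encoding, header$flag_enabled)
    writeBin(blob, con)
    n <<- n + length(primary)
    invisible(self)
  }

  self$records_written <- function() n

  self$abort <- function() try(close(con), silent = TRUE)

  self$close <- function() {
    close(con)
    expect <- HEADER_BYTES + n * record_size(header)
    got <- file.size(path)
    if (!isTRUE(got == expect))
      format_error(sprintf(
        "file-size identity violated: %d bytes written, expected 32 + %d * %d = %d",
        got, n, record_size(header), expect))
    invisible(list(path = path, records = n, bytes = got))
  }

  class(self) <- "bq_writer"
  self
}

#' Write sequences to a BQ file
#'
#' One-shot writer around [bq_writer()]. If a `policy` is given, sequences
#' are passed through [sanitize()] first; records hit by the `skip` policy
#' (either mate, for paired data) are dropped and counted.
#'
#' @param primary character vector of primary sequences (equal lengths).
#' @param path output path.
#' @param extended optional mate sequences (equal lengths).
#' @param flags optional numeric per-record flag values (enables the flag
#'   field).
#' @param encoding bits per base, 2 or 4.
#' @param flag_enabled store the 64-bit flag slot (default: only when
#'   `flags` supplied).
#' @param policy optional [invalid_policy()] applied before packing.
#' @return Invisibly, a list with `path`, `written`, `skipped`, `bytes`.
#' @export
write_bq <- function(primary, path, extended = NULL, flags = NULL,
                     encoding = 2, flag_enabled = !is.null(flags),
                     policy = NULL) {
  skipped <- 0L
  if (!is.null(policy)) {
    scheme <- encoding_scheme(encoding)
    primary <- sanitize(primary, policy, scheme)
    if (!is.null(extended)) extended <- sanitize(extended, policy, scheme)
    drop <- is.na(primary) | (if (is.null(extended)) FALSE else is.na(extended))
    skipped <- sum(drop)
    primary <- primary[!drop]
    extended <- if (!is.null(extended)) extended[!drop]
    flags <- if (!is.null(flags)) flags[!drop]
  }
  if (!length(primary))
    argument_error("no records to write (all skipped or empty input)")
  w <- bq_writer(path, slen = nchar(primary[1]),
                 xlen = if (is.null(extended)) 0 else nchar(extended[1]),
                 encoding = encoding, flag_enabled = flag_enabled)
  w$write(primary, extended, flags)
  res <- w$close()
  invisible(list(path = path, written = res$records, skipped = skipped,
                 bytes = res$bytes))
}

#' Read a BQ header from disk
#'
#' Validates the magic number, version, and that the data section is an
#' exact multiple of the record size; returns the header together with the
#' record count implied by the fixed layout,
#' `n = (filesize - 32) / record_size`.
#'
#' @param path a BQ file.
#' @return A `bq_header` with an extra `n_records` field.
#' @export
read_bq_header <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- parse_bq_header(read_raw(con, HEADER_BYTES, "BQ header"))
  data_bytes <- file.size(path) - HEADER_BYTES
  s <- record_size(header)
  if (data_bytes < 0 || data_bytes %% s != 0)
    format_error(sprintf(
      "corrupt BQ file: %d data bytes is not a multiple of record size %d",
      data_bytes, s))
  header$n_records <- data_bytes / s
  header
}

#' Open a BQ file for record access
#'
#' Returns a lightweight handle keeping the connection open, for repeated
#' [bq_get_record()] / [bq_read()] calls.
#'
#' @param path a BQ file.
#' @return A `bq_file` handle. Close with [close()].
#' @export
bq_open <- function(path) {
  header <- read_bq_header(path)
  structure(
    list(path = path, con = file(path, "rb"), header = header),
    class = "bq_file"
  )
}

#' @export
close.bq_file <- function(con, ...) close(con$con)

#' @export
print.bq_file <- function(x, ...) {
  cat(sprintf("<bq_file: %s, %d records>\n", x$path, x$header$n_records))
  invisible(x)
}

as_bq_file <- function(x) {
  if (inherits(x, "bq_file")) x else bq_open(x)
}

#' Random access to a BQ record
#'
#' Seeks directly to `32 + i * record_size` and decodes one record; no
#' preceding records are touched, so access cost is independent of `i`.
#'
#' @param x a BQ path or [bq_open()] handle.
#' @param i zero-based record index.
#' @return A list with `primary`, `extended` (or `NULL`), `flag` (or
#'   `NULL`).
#' @export
bq_get_record <- function(x, i) {
  f <- as_bq_file(x)
  if (!inherits(x, "bq_file")) on.exit(close(f))
  h <- f$header
  if (length(i) != 1 || is.na(i) || i < 0 || i >= h$n_records)
    range_error(sprintf("record index %s out of range [0, %d)",
                        format(i), h$n_records))
  seek(f$con, record_offset(i, h), origin = "start")
  blob <- read_raw(f$con, record_size(h), "record")
  rec <- .cpp_unpack_records(blob, 1, as.integer(h$slen), as.integer(h$xlen),
                             h$encoding, h$flag_enabled)
  list(primary = rec$primary[1],
       extended = if (is.null(rec$extended)) NULL else rec$extended[1],
       flag = if (is.null(rec$flag)) NULL else rec$flag[1])
}

#' Read BQ records sequentially
#'
#' Decodes a contiguous run of records into a tibble. `first` / `n` allow
#' reading a slice without touching the rest of the file (used by the
#' parallel partitioning).
#'
#' @param x a BQ path or [bq_open()] handle.
#' @param first zero-based index of the first record (default 0).
#' @param n number of records (default: to end of file).
#' @return A tibble with column `primary` and, when present in the file,
#'   `extended` and `flag`.
#' @export
bq_read <- function(x, first = 0, n = Inf) {
  f <- as_bq_file(x)
  if (!inherits(x, "bq_file")) on.exit(close(f))
  h <- f$header
  if (first < 0 || first > h$n_records)
    range_error(sprintf("first=%s out of range", format(first)))
  n <- min(n, h$n_records - first)
  s <- record_size(h)
  seek(f$con, record_offset(first, h), origin = "start")
  chunk_recs <- max(1, min(n, floor(6.4e7 / s)))
  out <- list()
  remaining <- n
  while (remaining > 0) {
    take <- min(chunk_recs, remaining)
    blob <- read_raw(f$con, take * s, "records")
    out[[length(out) + 1L]] <-
      .cpp_unpack_records(blob, take, as.integer(h$slen), as.integer(h$xlen),
                          h$encoding, h$flag_enabled)
    remaining <- remaining - take
  }
  pull <- function(fld, empty) {
    v <- unlist(lapply(out, `[[`, fld), use.names = FALSE)
    if (is.null(v)) empty else v
  }
  cols <- list(primary = pull("primary", character(0)))
  if (h$xlen > 0) cols$extended <- pull("extended", character(0))
  if (h$flag_enabled) cols$flag <- pull("flag", numeric(0))
  tibble::as_tibble(cols)
}
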