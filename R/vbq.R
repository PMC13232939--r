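# VBQ container: variable-length records grouped into blocks of a fixed
# virtual (uncompressed) byte budget, each optionally ZSTD-compressed and
# preceded by a 32-byte block header, with a trailing compressed block
# index so blocks can be located and decompressed in parallel.
#
# File header (little-endian, 32 bytes):
#   0-3   magic "VBQ\x01"
#   4     version (1)
#   5     encoding bits per base (2 or 4)
#   6     feature bitfield: 1 quality, 2 compressed, 4 paired, 8 headers,
#         16 record flags
#   7     reserved
#   8-15  virtual_block_size u64 (payload byte budget per block)
#   16-31 reserved, zero
#
# Block header (32 bytes): magic "VBLK", stored_size u64 (bytes as written,
# i.e. post-compression), n_records u64, 12 reserved zero bytes.
#
# Index (after the last block): a 32-byte uncompressed index header
# (magic "VIDX", data_bytes u64 = bytes of the pre-index file region),
# then the ZSTD-compressed concatenation of 32-byte ranges
# (offset u64, stored_size u64, n_records u64, cum_records u64),
# then a 16-byte footer (index_bytes u64, magic "VEND").

FEATURE_BITS <- c(has_quality = 1L, compressed = 2L, paired = 4L,
                  has_headers = 8L, has_record_flags = 16L)
FOOTER_BYTES <- 16L
RANGE_BYTES <- 32L

vbq_features <- function(quality = FALSE, compressed = TRUE, paired = FALSE,
                         headers = FALSE, flags = FALSE) {
  list(has_quality = isTRUE(quality), compressed = isTRUE(compressed),
       paired = isTRUE(paired), has_headers = isTRUE(headers),
       has_record_flags = isTRUE(flags))
}

#' VBQ file header
#'
#' @param encoding bits per base, 2 or 4.
#' @param virtual_block_size uncompressed payload byte budget per block;
#'   every record must serialize to at most this many bytes.
#' @param quality,paired,headers,flags,compressed feature switches:
#'   store Phred+33 quality strings, mate sequences, sequence headers,
#'   64-bit per-record flags; compress block payloads with ZSTD.
#' @return A `vbq_header` object.
#' @export
vbq_header <- function(encoding = 2, virtual_block_size = 131072,
                       quality = FALSE, paired = FALSE, headers = FALSE,
                       flags = FALSE, compressed = TRUE) {
  scheme <- encoding_scheme(encoding)
  virtual_block_size <- as.numeric(virtual_block_size)
  if (length(virtual_block_size) != 1 || is.na(virtual_block_size) ||
      virtual_block_size < 64)
    argument_error("virtual_block_size must be a single value >= 64 bytes")
  structure(
    c(list(encoding = scheme$bits_per_base,
           virtual_block_size = virtual_block_size),
      vbq_features(quality, compressed, paired, headers, flags)),
    class = "vbq_header"
  )
}

#' @export
print.vbq_header <- function(x, ...) {
  on <- names(FEATURE_BITS)[vapply(names(FEATURE_BITS), function(f)
    isTRUE(x[[f]]), logical(1))]
  cat(sprintf("<vbq_header: %d-bit, block=%dB, features=[%s]>\n",
              x$encoding, x$virtual_block_size, paste(on, collapse = ",")))
  invisible(x)
}

serialize_vbq_header <- function(h) {
  r <- raw(HEADER_BYTES)
  r[1:4] <- VBQ_MAGIC
  r[5] <- as.raw(FORMAT_VERSION)
  r[6] <- as.raw(h$encoding)
  bits <- sum(FEATURE_BITS[vapply(names(FEATURE_BITS), function(f)
    isTRUE(h[[f]]), logical(1))])
  r[7] <- as.raw(bits)
  r[9:16] <- u64_raw(h$virtual_block_size)
  r
}

parse_vbq_header <- function(r) {
  if (length(r) != HEADER_BYTES || !identical(r[1:4], VBQ_MAGIC))
    format_error("not a VBQ file: bad magic")
  if (as.integer(r[5]) != FORMAT_VERSION)
    format_error(sprintf("unsupported VBQ version %d", as.integer(r[5])))
  enc <- as.integer(r[6])
  if (!enc %in% c(2L, 4L))
    format_error(sprintf("invalid encoding field %d", enc))
  feat <- as.integer(r[7])
  if (any(r[c(8, 17:32)] != as.raw(0)))
    format_error("reserved header bytes are not zero")
  vbq_header(
    encoding = enc, virtual_block_size = raw_u64(r[9:16]),
    quality = bitwAnd(feat, 1L) > 0, compressed = bitwAnd(feat, 2L) > 0,
    paired = bitwAnd(feat, 4L) > 0, headers = bitwAnd(feat, 8L) > 0,
    flags = bitwAnd(feat, 16L) > 0
  )
}

# serialized byte count of each record under a header's features
vbq_record_bytes <- function(h, slen, xlen = NULL, hlen = NULL, ehlen = NULL) {
  B <- 64 / h$encoding
  sz <- 8 + (if (h$has_record_flags) 8 else 0) + (if (h$paired) 8 else 0)
  sz <- sz + 8 * ceiling(slen / B)
  if (h$paired) sz <- sz + 8 * ceiling(xlen / B)
  if (h$has_quality) sz <- sz + slen + (if (h$paired) xlen else 0)
  if (h$has_headers) sz <- sz + 2 + hlen + (if (h$paired) 2 + ehlen else 0)
  sz
}

#' Greedy block packing
#'
#' Given serialized record sizes, returns how many of the leading records
#' fit in one block: the maximal prefix whose total size does not exceed
#' the virtual block size. Records are never split across blocks.
#'
#' @param sizes serialized record sizes in bytes, in queue order.
#' @param virtual_block_size uncompressed block payload budget in bytes.
#' @return Number of records in the first block (0 for an empty queue).
#' @examples
#' pack_block(rep(100, 5), 256) # 2 records fit
#' @export
pack_block <- function(sizes, virtual_block_size) {
  if (!length(sizes)) return(0L)
  if (sizes[1] > virtual_block_size)
    config_error(sprintf(
      "record of %d bytes exceeds virtual block size %d; increase the block size",
      sizes[1], virtual_block_size))
  sum(cumsum(sizes) <= virtual_block_size)
}

#' Incremental VBQ writer
#'
#' Opens a VBQ file and returns a writer handle. `$write()` queues records;
#' whole blocks are flushed as soon as they fill (a block holds the maximal
#' prefix of queued records fitting the virtual block size). `$close()`
#' flushes the final partial block, appends the compressed block index and
#' footer, and returns a summary.
#'
#' @param path output file path.
#' @inheritParams vbq_header
#' @param level ZSTD compression level (when `compressed`).
#' @return A `vbq_writer` handle with `$write(primary, extended,
#'   qual_primary, qual_extended, header_primary, header_extended, flags)`,
#'   `$close()` and `$records_written()`.
#' @export
vbq_writer <- function(path, encoding = 2, virtual_block_size = 131072,
                       quality = FALSE, paired = FALSE, headers = FALSE,
                       flags = FALSE, compressed = TRUE, level = 3) {
  h <- vbq_header(encoding, virtual_block_size, quality, paired, headers,
                  flags, compressed)
  con <- file(path, "wb")
  writeBin(serialize_vbq_header(h), con)

  pend <- list(primary = character(0), extended = character(0),
               qual_primary = character(0), qual_extended = character(0),
               header_primary = character(0), header_extended = character(0),
               flags = numeric(0), sizes = numeric(0))
  offset <- HEADER_BYTES   # current write position
  ranges <- list()
  n_total <- 0

  take_pend <- function(k) {
    out <- lapply(pend[1:7], function(v) if (length(v)) v[seq_len(k)] else v)
    for (f in names(pend))
      pend[[f]] <<- if (length(pend[[f]])) pend[[f]][-seq_len(k)] else pend[[f]]
    out
  }

  flush_block <- function(k) {
    b <- take_pend(k)
    payload <- .cpp_vbq_serialize(
      b$primary,
      if (h$paired) b$extended else NULL,
      if (h$has_quality) b$qual_primary else NULL,
      if (h$has_quality && h$paired) b$qual_extended else NULL,
      if (h$has_headers) b$header_primary else NULL,
      if (h$has_headers && h$paired) b$header_extended else NULL,
      if (h$has_record_flags) b$flags else NULL,
      h$encoding, h$paired, h$has_quality, h$has_headers, h$has_record_flags)
    if (length(payload) > h$virtual_block_size)
      config_error("internal: block payload exceeds virtual block size")
    stored <- if (h$compressed) .cpp_zstd_compress(payload, as.integer(level))
              else payload
    bh <- raw(HEADER_BYTES)
    bh[1:4] <- BLK_MAGIC
    bh[5:12] <- u64_raw(length(stored))
    bh[13:20] <- u64_raw(k)
    writeBin(bh, con)
    writeBin(stored, con)
    ranges[[length(ranges) + 1L]] <<-
      c(offset = offset, stored_size = length(stored), n_records = k,
        cum_records = n_total)
    n_total <<- n_total + k
    offset <<- offset + HEADER_BYTES + length(stored)
  }

  flush_full <- function() {
    repeat {
      k <- pack_block(pend$sizes, h$virtual_block_size)
      if (k >= length(pend$sizes)) break  # queue may still grow: wait
      flush_block(k)
    }
  }

  self <- new.env(parent = emptyenv())

  self$write <- function(primary, extended = NULL, qual_primary = NULL,
                         qual_extended = NULL, header_primary = NULL,
                         header_extended = NULL, flags = NULL) {
    primary <- as.character(primary)
    n <- length(primary)
    need <- function(x, what) {
      if (is.null(x) || length(x) != n)
        argument_error(sprintf("%s required for every record (%d expected)",
                               what, n))
      as.character(x)
    }
    if (h$paired) extended <- need(extended, "extended sequences")
    if (h$has_quality) {
      qual_primary <- need(qual_primary, "primary qualities")
      if (any(nchar(qual_primary) != nchar(primary)))
        argument_error("quality length must equal sequence length")
      if (h$paired) {
        qual_extended <- need(qual_extended, "extended qualities")
        if (any(nchar(qual_extended) != nchar(extended)))
          argument_error("quality length must equal sequence length")
      }
    }
    if (h$has_headers) {
      header_primary <- need(header_primary, "sequence headers")
      if (h$paired) header_extended <- need(header_extended, "mate headers")
    }
    if (h$has_record_flags)
      flags <- if (is.null(flags)) numeric(n) else as.numeric(flags)

    sizes <- vbq_record_bytes(
      h, nchar(primary), if (h$paired) nchar(extended),
      if (h$has_headers) nchar(header_primary, type = "bytes"),
      if (h$has_headers && h$paired) nchar(header_extended, type = "bytes"))
    over <- which(sizes > h$virtual_block_size)
    if (length(over))
      config_error(sprintf(
        "record %d serializes to %d bytes, larger than the virtual block size %d; increase the block size",
        n_total + length(pend$sizes) + over[1], sizes[over[1]],
        h$virtual_block_size))

    pend$primary <<- c(pend$primary, primary)
    if (h$paired) pend$extended <<- c(pend$extended, extended)
    if (h$has_quality) {
      pend$qual_primary <<- c(pend$qual_primary, qual_primary)
      if (h$paired) pend$qual_extended <<- c(pend$qual_extended, qual_extended)
    }
    if (h$has_headers) {
      pend$header_primary <<- c(pend$header_primary, header_primary)
      if (h$paired) pend$header_extended <<- c(pend$header_extended, header_extended)
    }
    if (h$has_record_flags) pend$flags <<- c(pend$flags, flags)
    pend$sizes <<- c(pend$sizes, sizes)
    flush_full()
    invisible(self)
  }

  self$records_written <- function() n_total + length(pend$sizes)

  self$abort <- function() try(close(con), silent = TRUE)

  self$close <- function() {
    while (length(pend$sizes))
      flush_block(pack_block(pend$sizes, h$virtual_block_size))
    # trailing index: uncompressed index header, compressed ranges, footer
    data_bytes <- offset
    rng_raw <- if (length(ranges))
      u64_raw(as.numeric(t(do.call(rbind, ranges)))) else raw(0)
    comp <- .cpp_zstd_compress(rng_raw, as.integer(level))
    ih <- raw(HEADER_BYTES)
    ih[1:4] <- IDX_MAGIC
    ih[9:16] <- u64_raw(data_bytes)
    writeBin(ih, con)
    writeBin(comp, con)
    ft <- raw(FOOTER_BYTES)
    ft[1:8] <- u64_raw(HEADER_BYTES + length(comp))
    ft[9:12] <- END_MAGIC
    writeBin(ft, con)
    close(con)
    expect <- data_bytes + HEADER_BYTES + length(comp) + FOOTER_BYTES
    if (!isTRUE(file.size(path) == expect))
      format_error("file-size accounting violated on VBQ close")
    invisible(list(path = path, records = n_total, blocks = length(ranges),
                   bytes = file.size(path)))
  }

  class(self) <- "vbq_writer"
  self
}

#' Load the trailing block index of a VBQ file
#'
#' Reads the footer, verifies its magic, decompresses the range table and
#' cross-checks the index header's byte count against the observed
#' pre-index region (a quick check that index and file belong together).
#'
#' @param path a VBQ file.
#' @return A tibble with one row per block: `offset`, `stored_size`,
#'   `n_records`, `cum_records`.
#' @export
load_index <- function(path) {
  size <- file.size(path)
  if (is.na(size) || size < HEADER_BYTES + HEADER_BYTES + FOOTER_BYTES)
    format_error("file too small to hold a VBQ index")
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, size - FOOTER_BYTES, origin = "start")
  ft <- read_raw(con, FOOTER_BYTES, "index footer")
  if (!identical(ft[9:12], END_MAGIC))
    index_error("corrupt index: bad footer magic")
  index_bytes <- raw_u64(ft[1:8])
  if (index_bytes < HEADER_BYTES || index_bytes + FOOTER_BYTES > size)
    index_error("corrupt index: impossible index size")
  seek(con, size - FOOTER_BYTES - index_bytes, origin = "start")
  ih <- read_raw(con, HEADER_BYTES, "index header")
  if (!identical(ih[1:4], IDX_MAGIC))
    index_error("corrupt index: bad index header magic")
  data_bytes <- raw_u64(ih[9:16])
  observed <- size - FOOTER_BYTES - index_bytes
  if (data_bytes != observed)
    pairing_error(sprintf(
      "index/file pairing check failed: index records %d data bytes, file has %d",
      data_bytes, observed))
  comp <- read_raw(con, index_bytes - HEADER_BYTES, "index ranges")
  rng <- tryCatch(.cpp_zstd_decompress(comp),
                  error = function(e) index_error(
                    paste("corrupt index:", conditionMessage(e))))
  if (length(rng) %% RANGE_BYTES != 0)
    index_error("corrupt index: range table size not a multiple of 32")
  vals <- raw_u64(rng)
  m <- matrix(vals, ncol = 4, byrow = TRUE)
  idx <- tibble::tibble(offset = m[, 1], stored_size = m[, 2],
                        n_records = m[, 3], cum_records = m[, 4])
  if (nrow(idx)) {
    ends <- idx$offset + HEADER_BYTES + idx$stored_size
    if (is.unsorted(idx$offset, strictly = TRUE) ||
        any(ends[-nrow(idx)] > idx$offset[-1]) ||
        any(idx$cum_records != cumsum(c(0, idx$n_records[-nrow(idx)]))))
      index_error("corrupt index: ranges unsorted, overlapping or miscounted")
    if (ends[nrow(idx)] != data_bytes)
      index_error("corrupt index: ranges do not cover the data region")
  }
  idx
}

#' Read a VBQ header from disk
#'
#' @param path a VBQ file.
#' @return A `vbq_header`.
#' @export
read_vbq_header <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  parse_vbq_header(read_raw(con, HEADER_BYTES, "VBQ header"))
}

#' Open a VBQ file for record access
#'
#' Loads the header and trailing block index once and keeps the connection
#' open for repeated [read_block()] / [vbq_get_record()] calls.
#'
#' @param path a VBQ file.
#' @return A `vbq_file` handle with fields `header`, `index`, `n_records`.
#' @export
vbq_open <- function(path) {
  header <- read_vbq_header(path)
  index <- load_index(path)
  structure(
    list(path = path, con = file(path, "rb"), header = header, index = index,
         n_records = sum(index$n_records)),
    class = "vbq_file"
  )
}

#' @export
close.vbq_file <- function(con, ...) close(con$con)

#' @export
print.vbq_file <- function(x, ...) {
  cat(sprintf("<vbq_file: %s, %d records in %d blocks>\n",
              x$path, x$n_records, nrow(x$index)))
  invisible(x)
}

as_vbq_file <- function(x) {
  if (inherits(x, "vbq_file")) x else vbq_open(x)
}

vbq_cols <- function(h, parsed) {
  cols <- list(primary = parsed$primary)
  if (h$paired) cols$extended <- parsed$extended
  if (h$has_quality) {
    cols$qual_primary <- parsed$qual_primary
    if (h$paired) cols$qual_extended <- parsed$qual_extended
  }
  if (h$has_headers) {
    cols$header_primary <- parsed$header_primary
    if (h$paired) cols$header_extended <- parsed$header_extended
  }
  if (h$has_record_flags) cols$flag <- parsed$flag
  tibble::as_tibble(cols)
}

empty_vbq_tibble <- function(h) {
  vbq_cols(h, list(primary = character(0), extended = character(0),
                   qual_primary = character(0), qual_extended = character(0),
                   header_primary = character(0), header_extended = character(0),
                   flag = numeric(0)))
}

#' Decode one VBQ block
#'
#' Blocks are independently decodable: the stored payload is read at the
#' index offset, decompressed when the file is compressed, and parsed into
#' exactly `n_records` records.
#'
#' @param x a VBQ path or [vbq_open()] handle.
#' @param range one row of the block index (see [load_index()]).
#' @return A tibble of records (columns as in [vbq_read()]).
#' @export
read_block <- function(x, range) {
  f <- as_vbq_file(x)
  if (!inherits(x, "vbq_file")) on.exit(close(f))
  h <- f$header
  seek(f$con, range$offset, origin = "start")
  bh <- read_raw(f$con, HEADER_BYTES, "block header")
  if (!identical(bh[1:4], BLK_MAGIC))
    format_error(sprintf("block corruption: bad block magic at offset %d",
                         range$offset))
  stored_size <- raw_u64(bh[5:12])
  n_rec <- raw_u64(bh[13:20])
  if (stored_size != range$stored_size || n_rec != range$n_records)
    format_error("block corruption: block header disagrees with index")
  stored <- read_raw(f$con, stored_size, "block payload")
  payload <- if (h$compressed) .cpp_zstd_decompress(stored) else stored
  if (length(payload) > h$virtual_block_size)
    format_error("block corruption: payload exceeds virtual block size")
  parsed <- tryCatch(
    .cpp_vbq_parse(payload, n_rec, h$encoding, h$paired, h$has_quality,
                   h$has_headers, h$has_record_flags),
    error = function(e) format_error(conditionMessage(e)))
  vbq_cols(h, parsed)
}

#' Read VBQ records
#'
#' Decodes blocks in offset order (equivalently, record order) into one
#' tibble. Column set follows the file's features: always `primary`, plus
#' `extended`, `qual_primary`, `qual_extended`, `header_primary`,
#' `header_extended`, `flag` when stored.
#'
#' @param x a VBQ path or [vbq_open()] handle.
#' @param blocks optional integer vector of block numbers (1-based rows of
#'   the index) to restrict to.
#' @return A tibble of records.
#' @export
vbq_read <- function(x, blocks = NULL) {
  f <- as_vbq_file(x)
  if (!inherits(x, "vbq_file")) on.exit(close(f))
  idx <- f$index
  if (!is.null(blocks)) idx <- idx[blocks, , drop = FALSE]
  if (!nrow(idx)) return(empty_vbq_tibble(f$header))
  parts <- lapply(seq_len(nrow(idx)), function(j)
    read_block(f, idx[j, , drop = FALSE]))
  do.call(rbind, parts)
}

#' Random access to a VBQ record
#'
#' Locates the block containing global record `i` by binary search on the
#' cumulative record counts of the index, decodes that block only, and
#' returns the record.
#'
#' @param x a VBQ path or [vbq_open()] handle.
#' @param i zero-based record index.
#' @return A one-row tibble.
#' @export
vbq_get_record <- function(x, i) {
  f <- as_vbq_file(x)
  if (!inherits(x, "vbq_file")) on.exit(close(f))
  if (length(i) != 1 || is.na(i) || i < 0 || i >= f$n_records)
    range_error(sprintf("record index %s out of range [0, %d)",
                        format(i), f$n_records))
  j <- findInterval(i, f$index$cum_records)
  block <- read_block(f, f$index[j, , drop = FALSE])
  block[i - f$index$cum_records[j] + 1, , drop = FALSE]
}

#' Write records to a VBQ file
#'
#' One-shot writer around [vbq_writer()]: sanitizes (optionally), packs
#' records into blocks, compresses, and appends the block index. Features
#' are inferred from the supplied columns.
#'
#' @param primary character vector of primary sequences.
#' @param path output path.
#' @param extended,qual_primary,qual_extended,header_primary,header_extended
#'   optional per-record fields; supplying them enables the corresponding
#'   feature.
#' @param flags optional numeric per-record flags.
#' @param encoding bits per base, 2 or 4.
#' @param virtual_block_size uncompressed payload budget per block (bytes).
#' @param compressed ZSTD-compress block payloads?
#' @param level ZSTD level.
#' @param policy optional [invalid_policy()]; skip drops whole records
#'   (both mates) and counts them.
#' @return Invisibly, a list with `path`, `written`, `skipped`, `blocks`,
#'   `bytes`.
#' @export
write_vbq <- function(primary, path, extended = NULL, qual_primary = NULL,
                      qual_extended = NULL, header_primary = NULL,
                      header_extended = NULL, flags = NULL, encoding = 2,
                      virtual_block_size = 131072, compressed = TRUE,
                      level = 3, policy = NULL) {
  skipped <- 0L
  if (!is.null(policy)) {
    scheme <- encoding_scheme(encoding)
    primary <- sanitize(primary, policy, scheme)
    if (!is.null(extended)) extended <- sanitize(extended, policy, scheme)
    drop <- is.na(primary) | (if (is.null(extended)) FALSE else is.na(extended))
    skipped <- sum(drop)
    keep <- !drop
    primary <- primary[keep]
    sub <- function(v) if (is.null(v)) NULL else v[keep]
    extended <- sub(extended); qual_primary <- sub(qual_primary)
    qual_extended <- sub(qual_extended); header_primary <- sub(header_primary)
    header_extended <- sub(header_extended); flags <- sub(flags)
  }
  w <- vbq_writer(path, encoding = encoding,
                  virtual_block_size = virtual_block_size,
                  quality = !is.null(qual_primary),
                  paired = !is.null(extended),
                  headers = !is.null(header_primary),
                  flags = !is.null(flags),
                  compressed = compressed, level = level)
  if (length(primary))
    w$write(primary, extended, qual_primary, qual_extended,
            header_primary, header_extended, flags)
  res <- w$close()
  invisible(list(path = path, written = res$records, skipped = skipped,
                 blocks = res$blocks, bytes = res$bytes))
}
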