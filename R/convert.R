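# FASTQ/FASTA <-> BINSEQ conversion.
#
# FASTQ is read as strict 4-line records from a (possibly gzip) connection
# in chunks, so arbitrarily large inputs stream in bounded memory. FASTA
# may be multi-line on read and is written single-line. gzip inputs are
# auto-detected by their magic bytes.

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  identical(readBin(con, "raw", 2), as.raw(c(0x1f, 0x8b)))
}

#' Open a FASTX file for chunked reading
#'
#' Detects gzip compression (magic bytes) and record format (first
#' character: `@` FASTQ, `>` FASTA). The returned reader's
#' `$next_chunk(n)` yields a tibble of up to `n` records with columns
#' `header`, `sequence`, `quality` (`NA` for FASTA), or `NULL` at
#' end-of-file.
#'
#' @param path a FASTQ/FASTA file, plain or gzip.
#' @return A `fastx_reader` handle with `$format`, `$next_chunk(n)`,
#'   `$close()`.
#' @export
fastx_reader <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, 1L)
  if (!length(first)) format_error(sprintf("%s is empty", path))
  fmt <- if (startsWith(first, "@")) "fastq"
         else if (startsWith(first, ">")) "fasta"
         else format_error(sprintf("%s is neither FASTQ nor FASTA", path))
  self <- new.env(parent = emptyenv())
  self$format <- fmt
  self$close <- function() close(con)
  carry <- first  # first line of the next unconsumed record
  eof <- FALSE

  if (fmt == "fastq") {
    self$next_chunk <- function(n) {
      if (eof) return(NULL)
      lines <- c(carry, readLines(con, 4L * n - length(carry)))
      carry <<- character(0)
      if (!length(lines)) { eof <<- TRUE; return(NULL) }
      if (length(lines) %% 4L != 0L)
        format_error(sprintf("%s: truncated FASTQ record at end of file", path))
      if (length(lines) < 4L * n) eof <<- TRUE
      m <- matrix(lines, nrow = 4L)
      if (!all(startsWith(m[1, ], "@")) || !all(startsWith(m[3, ], "+")))
        format_error(sprintf("%s: malformed 4-line FASTQ record", path))
      if (any(nchar(m[2, ]) != nchar(m[4, ])))
        format_error(sprintf("%s: quality length differs from sequence length",
                             path))
      tibble::tibble(header = substring(m[1, ], 2), sequence = m[2, ],
                     quality = m[4, ])
    }
  } else {
    # FASTA: records may span lines; read everything once, serve in chunks
    lines <- c(carry, readLines(con))
    carry <- character(0)
    at_rec <- which(startsWith(lines, ">"))
    headers <- substring(lines[at_rec], 2)
    ends <- c(at_rec[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(at_rec), function(j) {
      if (at_rec[j] + 1L > ends[j]) ""
      else paste(lines[(at_rec[j] + 1L):ends[j]], collapse = "")
    }, character(1))
    served <- 0L
    self$next_chunk <- function(n) {
      if (served >= length(headers)) return(NULL)
      take <- seq.int(served + 1L, min(served + n, length(headers)))
      served <<- max(take)
      tibble::tibble(header = headers[take], sequence = seqs[take],
                     quality = NA_character_)
    }
  }
  class(self) <- "fastx_reader"
  self
}

infer_target <- function(output) {
  if (grepl("\\.bq$", output)) "bq"
  else if (grepl("\\.vbq$", output)) "vbq"
  else format_error("cannot infer target format: output must end in .bq or .vbq")
}

#' Encode FASTQ/FASTA into BQ or VBQ
#'
#' Streams one or two (paired) FASTX inputs into a BINSEQ file. BQ targets
#' enforce a fixed primary (and mate) length, taken from the first kept
#' record unless given; VBQ targets accept variable lengths. Records hit
#' by the `skip` policy (either mate) are dropped and counted. In archive
#' mode (VBQ only) four-bit encoding is forced and quality strings and
#' sequence headers are preserved, making the conversion lossless.
#'
#' @param input primary FASTQ/FASTA path (plain or gzip).
#' @param output output `.bq` / `.vbq` path.
#' @param input2 optional mate input for paired data.
#' @param target `"auto"` (from the output extension), `"bq"` or `"vbq"`.
#' @param encoding bits per base, 2 or 4.
#' @param policy an [invalid_policy()]; default skips records containing
#'   unencodable bases.
#' @param archive lossless VBQ mode: forces `encoding = 4`, `quality =
#'   TRUE`, `headers = TRUE`.
#' @param quality,headers store quality strings / sequence headers (VBQ
#'   only).
#' @param flag_enabled reserve the 64-bit per-record flag slot (BQ).
#' @param slen,xlen fixed lengths for BQ (default: from the first record).
#' @param virtual_block_size,compressed,level VBQ block options.
#' @param chunk_size records streamed per chunk.
#' @return Invisibly, a list with `written`, `skipped`, `path`.
#' @export
encode_fastx <- function(input, output, input2 = NULL,
                         target = c("auto", "bq", "vbq"), encoding = 2,
                         policy = invalid_policy("skip"), archive = FALSE,
                         quality = FALSE, headers = FALSE,
                         flag_enabled = FALSE, slen = NULL, xlen = NULL,
                         virtual_block_size = 131072, compressed = TRUE,
                         level = 3, chunk_size = 250000) {
  target <- match.arg(target)
  if (target == "auto") target <- infer_target(output)
  if (archive) {
    if (target != "vbq")
      config_error("archive mode preserves qualities and headers and requires a VBQ target")
    encoding <- 4
    quality <- TRUE
    headers <- TRUE
  }
  if (target == "bq" && (quality || headers))
    config_error("BQ stores neither qualities nor headers; use VBQ")
  scheme <- encoding_scheme(encoding)
  paired <- !is.null(input2)
  r1 <- fastx_reader(input)
  on.exit(r1$close(), add = TRUE)
  r2 <- NULL
  if (paired) {
    r2 <- fastx_reader(input2)
    on.exit(r2$close(), add = TRUE)
  }
  if (quality && r1$format != "fastq")
    config_error("cannot store qualities: input has none (FASTA)")

  writer <- NULL
  finished <- FALSE
  on.exit(if (!finished && !is.null(writer)) writer$abort(), add = TRUE)
  written <- 0
  skipped <- 0
  ordinal <- 0

  repeat {
    c1 <- r1$next_chunk(chunk_size)
    c2 <- if (paired) r2$next_chunk(chunk_size)
    n1 <- if (is.null(c1)) 0L else nrow(c1)
    n2 <- if (is.null(c2)) 0L else nrow(c2)
    if (paired && n1 != n2)
      pairing_error(sprintf(
        "paired inputs diverge after record %d: %s and %s have different record counts",
        ordinal + min(n1, n2), input, input2))
    if (n1 == 0L) break

    p <- sanitize(c1$sequence, policy, scheme)
    x <- if (paired) sanitize(c2$sequence, policy, scheme)
    drop <- is.na(p) | (if (paired) is.na(x) else FALSE)
    skipped <- skipped + sum(drop)
    keep <- which(!drop)
    ordinal_chunk <- ordinal
    ordinal <- ordinal + n1
    if (!length(keep)) next
    p <- p[keep]
    x <- if (paired) x[keep]

    if (is.null(writer)) {
      if (target == "bq") {
        if (is.null(slen)) slen <- nchar(p[1])
        if (paired && is.null(xlen)) xlen <- nchar(x[1])
        writer <- bq_writer(output, slen = slen,
                            xlen = if (paired) xlen else 0,
                            encoding = encoding, flag_enabled = flag_enabled)
      } else {
        writer <- vbq_writer(output, encoding = encoding,
                             virtual_block_size = virtual_block_size,
                             quality = quality, paired = paired,
                             headers = headers, compressed = compressed,
                             level = level)
      }
    }

    if (target == "bq") {
      bad <- which(nchar(p) != slen)
      if (!length(bad) && paired) bad <- which(nchar(x) != xlen)
      if (length(bad))
        format_error(sprintf(
          "record %d: read length differs from the fixed record length; use a VBQ target for variable-length reads",
          ordinal_chunk + keep[bad[1]]))
      writer$write(p, x)
    } else {
      writer$write(p, x,
                   qual_primary = if (quality) c1$quality[keep],
                   qual_extended = if (quality && paired) c2$quality[keep],
                   header_primary = if (headers) c1$header[keep],
                   header_extended = if (headers && paired) c2$header[keep])
    }
    written <- written + length(keep)
  }

  if (is.null(writer)) {
    if (target == "bq")
      argument_error("no encodable records: cannot create an empty BQ file without a fixed length")
    writer <- vbq_writer(output, encoding = encoding,
                         virtual_block_size = virtual_block_size,
                         quality = quality, paired = paired,
                         headers = headers, compressed = compressed,
                         level = level)
  }
  writer$close()
  finished <- TRUE
  invisible(list(written = written, skipped = skipped, path = output))
}

write_fastx_chunk <- function(con, ids, seqs, quals, fasta) {
  if (fasta) {
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), con)
  } else {
    writeLines(fastq_lines(ids, seqs, quals), con)
  }
}

#' Decode BQ/VBQ back to FASTQ or FASTA
#'
#' BQ stores neither qualities nor identifiers, so it decodes to FASTA by
#' default with zero-padded ordinal identifiers (`r000000001`, ...); FASTQ
#' output needs `fake_qual`, a constant quality character. VBQ decodes to
#' FASTQ when qualities are stored (with the stored headers, when
#' present), else like BQ. Paired files decode to two mate files in record
#' order.
#'
#' @param input a `.bq` / `.vbq` file.
#' @param output output FASTQ/FASTA path (`.gz` for gzip).
#' @param output2 mate output path (required for paired inputs).
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @param fake_qual single character used as constant quality when
#'   requesting FASTQ from a source without stored qualities.
#' @param chunk_size records written per chunk.
#' @return Invisibly, a list with `records`, `path`, `path2`.
#' @export
decode_binseq <- function(input, output, output2 = NULL,
                          format = c("auto", "fastq", "fasta"),
                          fake_qual = NULL, chunk_size = 250000) {
  format <- match.arg(format)
  f <- binseq_open(input)
  on.exit(close(f), add = TRUE)
  is_bq <- inherits(f, "bq_file")
  paired <- if (is_bq) f$header$xlen > 0 else f$header$paired
  has_qual <- if (is_bq) FALSE else f$header$has_quality
  has_head <- if (is_bq) FALSE else f$header$has_headers
  if (paired && is.null(output2))
    pairing_error("paired input decodes to two mate files: supply output2")
  if (format == "auto") format <- if (has_qual || !is.null(fake_qual)) "fastq" else "fasta"
  if (format == "fastq" && !has_qual && is.null(fake_qual))
    format_error("source stores no quality scores; pass fake_qual for FASTQ output")
  fasta <- format == "fasta"

  con1 <- open_write(output)
  on.exit(close(con1), add = TRUE)
  con2 <- NULL
  if (paired) {
    con2 <- open_write(output2)
    on.exit(close(con2), add = TRUE)
  }

  emit <- function(chunk, base_ordinal) {
    n <- nrow(chunk)
    ids <- if (has_head) chunk$header_primary
           else sprintf("r%09d", base_ordinal + seq_len(n))
    ids2 <- if (has_head && !is.null(chunk$header_extended)) chunk$header_extended
            else ids
    q1 <- if (has_qual) chunk$qual_primary
          else if (!fasta) strrep(fake_qual, nchar(chunk$primary))
    write_fastx_chunk(con1, ids, chunk$primary, q1, fasta)
    if (paired) {
      q2 <- if (has_qual) chunk$qual_extended
            else if (!fasta) strrep(fake_qual, nchar(chunk$extended))
      write_fastx_chunk(con2, ids2, chunk$extended, q2, fasta)
    }
    n
  }

  done <- 0
  if (is_bq) {
    total <- f$header$n_records
    while (done < total) {
      take <- min(chunk_size, total - done)
      done <- done + emit(bq_read(f, first = done, n = take), done)
    }
  } else {
    for (j in seq_len(nrow(f$index)))
      done <- done + emit(read_block(f, f$index[j, , drop = FALSE]), done)
  }
  invisible(list(records = done, path = output, path2 = output2))
}

#' Summarize a BINSEQ file
#'
#' @param input a `.bq` / `.vbq` file.
#' @return A one-row tibble: `format`, `encoding`, `records`, `paired`,
#'   plus `slen`/`xlen`/`flag_enabled` (BQ) or `blocks`,
#'   `virtual_block_size`, feature switches (VBQ), and `file_bytes`.
#' @export
binseq_info <- function(input) {
  f <- binseq_open(input)
  on.exit(close(f))
  if (inherits(f, "bq_file")) {
    h <- f$header
    tibble::tibble(format = "bq", encoding = h$encoding,
                   records = h$n_records, paired = h$xlen > 0,
                   slen = h$slen, xlen = h$xlen,
                   flag_enabled = h$flag_enabled,
                   record_bytes = record_size(h),
                   file_bytes = file.size(input))
  } else {
    h <- f$header
    tibble::tibble(format = "vbq", encoding = h$encoding,
                   records = f$n_records, paired = h$paired,
                   blocks = nrow(f$index),
                   virtual_block_size = h$virtual_block_size,
                   compressed = h$compressed, quality = h$has_quality,
                   headers = h$has_headers, record_flags = h$has_record_flags,
                   file_bytes = file.size(input))
  }
}
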