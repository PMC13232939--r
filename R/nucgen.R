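# Deterministic synthetic read generator: uniform i.i.d. bases over
# {A,C,G,T}, constant quality character (default "?"), identifiers
# "r<ordinal>". Bases are drawn from R's RNG stream record by record
# (primary then mate), so output is a pure function of (spec, seed) and is
# independent of internal chunking.

#' Generate uniform-random reads
#'
#' Draws each base i.i.d. uniformly from `{A,C,G,T}` and attaches a
#' constant quality string, emulating a simple short-read benchmark input.
#'
#' @param n number of records.
#' @param length read length in bp (>= 1).
#' @param mate_length optional second-mate length in bp; produces paired
#'   records.
#' @param seed integer seed; identical `(n, length, mate_length, seed,
#'   quality_char)` yields identical output. `NULL` continues the session
#'   RNG stream.
#' @param quality_char single character repeated as the quality string.
#' @return A tibble with columns `header`, `primary`, `qual_primary` and,
#'   for paired specs, `extended`, `qual_extended`.
#' @examples
#' generate_reads(3, 10, seed = 1)
#' @export
generate_reads <- function(n, length, mate_length = NULL, seed = NULL,
                           quality_char = "?") {
  n <- as.integer(n)
  length <- as.integer(length)
  if (is.na(n) || n < 0) argument_error("n must be >= 0")
  if (is.na(length) || length < 1) argument_error("length must be >= 1")
  if (nchar(quality_char) != 1)
    argument_error("quality_char must be a single character")
  if (!is.null(seed)) set.seed(as.integer(seed))
  hdr <- sprintf("r%d", seq_len(n))
  if (is.null(mate_length)) {
    tibble::tibble(
      header = hdr,
      primary = .cpp_random_seqs(n, length),
      qual_primary = rep(strrep(quality_char, length), n))
  } else {
    mate_length <- as.integer(mate_length)
    if (is.na(mate_length) || mate_length < 1)
      argument_error("mate_length must be >= 1")
    pair <- .cpp_random_pairs(n, length, mate_length)
    tibble::tibble(
      header = hdr,
      primary = pair$primary,
      qual_primary = rep(strrep(quality_char, length), n),
      extended = pair$extended,
      qual_extended = rep(strrep(quality_char, mate_length), n))
  }
}

fastq_lines <- function(header, seq, qual) {
  as.vector(rbind(paste0("@", header), seq, "+", qual))
}

open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Write generated reads straight to FASTQ
#'
#' Streams [generate_reads()] output to one (single-end) or two (paired)
#' 4-line FASTQ files in chunks; output bytes depend only on the spec and
#' seed, not on `chunk_size`. `.gz` paths are gzip-compressed.
#'
#' @inheritParams generate_reads
#' @param path output FASTQ path (primary / single-end).
#' @param path2 output FASTQ path for the mate (required iff
#'   `mate_length` is given).
#' @param chunk_size records generated per chunk.
#' @return Invisibly, a list with `records` and the path(s).
#' @export
generate_fastq <- function(path, n, length, mate_length = NULL, path2 = NULL,
                           seed = NULL, quality_char = "?",
                           chunk_size = 250000) {
  if (!is.null(mate_length) && is.null(path2))
    argument_error("paired generation needs path2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  con1 <- open_write(path)
  on.exit(close(con1), add = TRUE)
  con2 <- NULL
  if (!is.null(mate_length)) {
    con2 <- open_write(path2)
    on.exit(close(con2), add = TRUE)
  }
  done <- 0L
  while (done < n) {
    take <- min(chunk_size, n - done)
    reads <- generate_reads(take, length, mate_length,
                            quality_char = quality_char)
    hdr <- sprintf("r%d", done + seq_len(take))
    writeLines(fastq_lines(hdr, reads$primary, reads$qual_primary), con1)
    if (!is.null(con2))
      writeLines(fastq_lines(hdr, reads$extended, reads$qual_extended), con2)
    done <- done + take
  }
  invisible(list(records = n, path = path, path2 = path2))
}
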