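#' Nucleotide packing schemes
#'
#' A scheme describes how bases are packed into 64-bit little-endian words:
#' two-bit packing stores 32 bases per word and covers `{A,C,G,T}`; four-bit
#' packing stores 16 bases per word and additionally covers `N`. The
#' two-bit code values (A=0, C=1, G=2, T=3) are preserved in the low bits of
#' the four-bit codes; `N` uses code 8, setting the fourth bit. Base 0 of a
#' sequence sits in the least-significant bits of the first word, so the
#' serialized byte stream is position-monotone.
#'
#' @param bits bits per base, 2 or 4 (an existing scheme is passed through).
#' @return An `encoding_scheme` object with fields `mode`, `bits_per_base`,
#'   `bases_per_word` and `word_size` (bytes, always 8).
#' @examples
#' encoding_scheme(2)
#' code_table(encoding_scheme(4))
#' @export
encoding_scheme <- function(bits = 2) {
  if (inherits(bits, "encoding_scheme")) return(bits)
  bits <- as.integer(bits)
  if (length(bits) != 1 || !bits %in% c(2L, 4L))
    argument_error("bits per base must be 2 or 4")
  structure(
    list(
      mode = if (bits == 2L) "two_bit" else "four_bit",
      bits_per_base = bits,
      bases_per_word = 64L %/% bits,
      word_size = 8L
    ),
    class = "encoding_scheme"
  )
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme: %s, %d bases/word, %d-byte words>\n",
              x$mode, x$bases_per_word, x$word_size))
  invisible(x)
}

#' @rdname encoding_scheme
#' @param scheme an `encoding_scheme` (or bits per base).
#' @export
code_table <- function(scheme = encoding_scheme(2)) {
  scheme <- encoding_scheme(scheme)
  if (scheme$bits_per_base == 2L) {
    tibble::tibble(base = c("A", "C", "G", "T"), code = c(0L, 1L, 2L, 3L))
  } else {
    tibble::tibble(base = c("A", "C", "G", "T", "N"),
                   code = c(0L, 1L, 2L, 3L, 8L))
  }
}

#' Words needed to store a sequence
#'
#' Number of 64-bit words occupied by `n_bases` packed bases, the
#' `ceiling(N / B)` term of the fixed record-size identity. Pad bits of the
#' final word are always zero.
#'
#' @param n_bases non-negative sequence length(s) in bases.
#' @param scheme packing scheme (see [encoding_scheme()]).
#' @return Integer word count(s).
#' @examples
#' words_needed(100, encoding_scheme(2)) # 4
#' words_needed(150, encoding_scheme(4)) # 10
#' @export
words_needed <- function(n_bases, scheme = encoding_scheme(2)) {
  scheme <- encoding_scheme(scheme)
  if (any(is.na(n_bases)) || any(n_bases < 0))
    argument_error("sequence length must be non-negative")
  as.integer(ceiling(n_bases / scheme$bases_per_word))
}

#' Invalid-nucleotide policies
#'
#' Bases that a scheme cannot encode (anything outside `ACGT`, or outside
#' `ACGTN` for four-bit) are handled by a configurable policy: drop the
#' whole record (`skip`), replace each invalid base with an i.i.d. uniform
#' draw from `{A,C,G,T}` (`random_replace`, reproducible under `seed`), or
#' replace with one predetermined base (`fixed_replace`).
#'
#' @param kind one of `"skip"`, `"random_replace"`, `"fixed_replace"`.
#' @param fixed_base replacement base in `{A,C,G,T}` (fixed_replace only).
#' @param seed integer RNG seed (required for random_replace). The policy
#'   object carries its own RNG stream, so repeated [sanitize()] calls
#'   continue the stream and a fresh policy with the same seed reproduces
#'   the same replacements.
#' @return An `invalid_policy` object.
#' @export
invalid_policy <- function(kind = c("skip", "random_replace", "fixed_replace"),
                           fixed_base = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed_replace") {
    if (is.null(fixed_base) || !fixed_base %in% c("A", "C", "G", "T"))
      argument_error("fixed_replace requires fixed_base in {A,C,G,T}")
  }
  if (kind == "random_replace") {
    if (is.null(seed)) argument_error("random_replace requires an RNG seed")
    seed <- as.integer(seed)
  }
  structure(
    list(kind = kind, fixed_base = fixed_base, seed = seed,
         rng = new.env(parent = emptyenv())),
    class = "invalid_policy"
  )
}

# run expr under the policy's private RNG stream without disturbing the
# session RNG
with_policy_rng <- function(policy, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(policy$rng$state)) set.seed(policy$seed)
  else assign(".Random.seed", policy$rng$state, envir = globalenv())
  val <- force(expr)
  policy$rng$state <- get(".Random.seed", globalenv())
  val
}

#' Apply an invalid-nucleotide policy
#'
#' Case-folds input to upper case, then resolves every base the scheme
#' cannot encode according to the policy. Under four-bit packing `N` is a
#' valid base and is never touched. `U` is treated as invalid, not silently
#' mapped to `T`. The skip policy operates on whole records and marks them
#' with `NA` (the skip signal).
#'
#' @param seqs character vector of sequences.
#' @param policy an [invalid_policy()].
#' @param scheme packing scheme (see [encoding_scheme()]).
#' @return Character vector of encodable sequences, with `NA_character_`
#'   for records skipped by the `skip` policy.
#' @examples
#' p <- invalid_policy("fixed_replace", fixed_base = "A")
#' sanitize("ACNT", p)                       # "ACAT"
#' sanitize("ACNT", p, encoding_scheme(4))   # "ACNT": N is encodable
#' @export
sanitize <- function(seqs, policy, scheme = encoding_scheme(2)) {
  scheme <- encoding_scheme(scheme)
  if (!inherits(policy, "invalid_policy"))
    argument_error("policy must be an invalid_policy object")
  seqs <- toupper(as.character(seqs))
  pat <- if (scheme$bits_per_base == 2L) "[^ACGT]" else "[^ACGTN]"
  bad <- which(grepl(pat, seqs))
  if (!length(bad)) return(seqs)

  if (policy$kind == "skip") {
    seqs[bad] <- NA_character_
  } else if (policy$kind == "fixed_replace") {
    seqs[bad] <- gsub(pat, policy$fixed_base, seqs[bad])
  } else {
    chars <- strsplit(seqs[bad], "", fixed = TRUE)
    pos <- lapply(chars, function(ch) grep(pat, ch))
    total <- sum(lengths(pos))
    repl <- with_policy_rng(policy,
      c("A", "C", "G", "T")[sample.int(4L, total, replace = TRUE)])
    at <- 0L
    for (j in seq_along(bad)) {
      k <- length(pos[[j]])
      chars[[j]][pos[[j]]] <- repl[at + seq_len(k)]
      at <- at + k
    }
    seqs[bad] <- vapply(chars, paste, character(1), collapse = "")
  }
  seqs
}

#' Pack and unpack nucleotide sequences
#'
#' `pack_bases()` packs a sequence of encodable bases into the dense
#' bit representation; `unpack_bases()` is its exact inverse. The packed
#' payload is the little-endian serialization of the underlying 64-bit
#' words, `8 * ceiling(n_bases / B)` bytes long.
#'
#' @param seq a single sequence over the scheme's alphabet.
#' @param scheme packing scheme (see [encoding_scheme()]).
#' @return `pack_bases()` returns a `packed_dna` object with fields `data`
#'   (raw payload), `n_bases` and `bits`; `unpack_bases()` returns the
#'   sequence string.
#' @examples
#' p <- pack_bases("ACGT")
#' as.integer(p$data[1]) # 228 = 0xE4: codes 0,1,2,3 packed LSB-first
#' unpack_bases(p)
#' @export
pack_bases <- function(seq, scheme = encoding_scheme(2)) {
  scheme <- encoding_scheme(scheme)
  if (length(seq) != 1 || is.na(seq))
    argument_error("pack_bases() packs a single non-NA sequence")
  data <- tryCatch(
    .cpp_pack(seq, scheme$bits_per_base),
    error = function(e) binseq_error(conditionMessage(e), "binseq_encoding_error")
  )
  structure(
    list(data = data, n_bases = nchar(seq), bits = scheme$bits_per_base),
    class = "packed_dna"
  )
}

#' @rdname pack_bases
#' @param x a `packed_dna` object, or a raw payload (then give `n_bases`
#'   and `scheme`).
#' @param n_bases number of bases stored in a raw payload.
#' @export
unpack_bases <- function(x, n_bases = NULL, scheme = NULL) {
  if (inherits(x, "packed_dna")) {
    n_bases <- x$n_bases
    bits <- x$bits
    x <- x$data
  } else {
    if (is.null(n_bases) || is.null(scheme))
      argument_error("raw payloads need n_bases and scheme")
    bits <- encoding_scheme(scheme)$bits_per_base
  }
  tryCatch(
    .cpp_unpack(x, as.numeric(n_bases), bits)[[1]],
    error = function(e) binseq_error(conditionMessage(e), "binseq_encoding_error")
  )
}

#' @export
print.packed_dna <- function(x, ...) {
  cat(sprintf("<packed_dna: %d bases, %d-bit, %d bytes>\n",
              x$n_bases, x$bits, length(x$data)))
  invisible(x)
}
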