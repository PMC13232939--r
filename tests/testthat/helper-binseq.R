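# Shared fixtures and an independent scalar packing oracle.

# reference packer: per-base shift-or into a byte array, written without
# any of the package's codec machinery so it can arbitrate bit layout
ref_pack <- function(seq, bits) {
  codes <- c(A = 0, C = 1, G = 2, T = 3, N = 8)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  per_byte <- 8 %/% bits
  B <- 64 %/% bits
  bytes <- integer(8 * ceiling(length(ch) / B))
  for (i in seq_along(ch)) {
    b <- (i - 1) %/% per_byte + 1
    bytes[b] <- bytes[b] + codes[[ch[i]]] * 2^(((i - 1) %% per_byte) * bits)
  }
  as.raw(bytes)
}

# random sequences drawn without the package's generator
rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_seqs <- function(n, lens, alphabet = c("A", "C", "G", "T")) {
  vapply(rep_len(lens, n), rand_seq, character(1), alphabet = alphabet)
}

rand_quals <- function(seqs) {
  vapply(nchar(seqs), function(L)
    rawToChar(as.raw(sample(33:74, L, replace = TRUE))), character(1))
}

local_file <- function(ext, env = parent.frame()) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = env)
  path
}

# total record count of a source via the processing interface
processed_count <- function(source, n_workers = 1, batch_size = 4096) {
  proc <- record_processor(
    init_state = function() 0, init_result = function() 0,
    map = function(s, r) s + 1, reduce = `+`, combine = `+`)
  process_parallel(source, proc, n_workers, batch_size)
}

# collect all primary sequences (order within partitions preserved)
collect_primary <- function(source, n_workers = 1, batch_size = 4096) {
  proc <- record_processor(
    init_state = function() character(0),
    init_result = function() character(0),
    map = function(s, r) c(s, r$primary),
    reduce = c, combine = c)
  process_parallel(source, proc, n_workers, batch_size)
}
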