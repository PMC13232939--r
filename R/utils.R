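# Shared low-level helpers: classed error conditions and little-endian
# integer (de)serialization for the fixed-width header fields. Integer
# fields are carried as R doubles; all on-disk values (offsets, sizes,
# counts) stay far below 2^53 so the arithmetic is exact.

binseq_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "binseq_error"), call = call))
}

format_error  <- function(msg) binseq_error(msg, "binseq_format_error")
pairing_error <- function(msg) binseq_error(msg, "binseq_pairing_error")
range_error   <- function(msg) binseq_error(msg, "binseq_range_error")
config_error  <- function(msg) binseq_error(msg, "binseq_config_error")
index_error   <- function(msg) binseq_error(msg, "binseq_corrupt_index_error")
argument_error <- function(msg) binseq_error(msg, "binseq_argument_error")

# little-endian unsigned integers <-> raw; vectorized over values
u64_raw <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x) | x < 0 | x >= 2^53))
    argument_error("u64 fields must be in [0, 2^53)")
  m <- floor(outer(x, 256^(0:7), "/")) %% 256
  as.raw(t(m))
}

raw_u64 <- function(r) {
  m <- matrix(as.integer(r), nrow = 8)
  as.numeric(colSums(m * 256^(0:7)))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x) | x < 0 | x >= 2^32))
    argument_error("u32 fields must be in [0, 2^32)")
  m <- floor(outer(x, 256^(0:3), "/")) %% 256
  as.raw(t(m))
}

raw_u32 <- function(r) {
  m <- matrix(as.integer(r), nrow = 4)
  as.numeric(colSums(m * 256^(0:3)))
}

# magic constants of the container family
BQ_MAGIC  <- as.raw(c(0x42, 0x53, 0x51, 0x01)) # "BSQ\x01"
VBQ_MAGIC <- as.raw(c(0x56, 0x42, 0x51, 0x01)) # "VBQ\x01"
BLK_MAGIC <- charToRaw("VBLK")
IDX_MAGIC <- charToRaw("VIDX")
END_MAGIC <- charToRaw("VEND")
FORMAT_VERSION <- 1L
HEADER_BYTES <- 32L

read_raw <- function(con, n, what = "data") {
  r <- readBin(con, "raw", n = n)
  if (length(r) != n)
    format_error(sprintf("unexpected end of file while reading %s", what))
  r
}
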