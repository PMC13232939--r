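test_that("block packing takes the maximal record prefix", {
  expect_equal(pack_block(rep(100, 5), 256), 2)
  expect_equal(pack_block(256, 256), 1)          # exact fit
  expect_equal(pack_block(numeric(0), 256), 0)
  expect_equal(pack_block(c(100, 100, 56, 1), 256), 3)
  expect_error(pack_block(257, 256), "block size",
               class = "binseq_config_error")
})

test_that("VBQ and block headers serialize to exactly 32 bytes", {
  h <- vbq_header(encoding = 4, virtual_block_size = 4096, quality = TRUE,
                  paired = TRUE, headers = TRUE, flags = TRUE,
                  compressed = FALSE)
  r <- binseqr:::serialize_vbq_header(h)
  expect_length(r, 32)
  back <- binseqr:::parse_vbq_header(r)
  expect_equal(back, h)
  bad <- r; bad[2] <- as.raw(0)
  expect_error(binseqr:::parse_vbq_header(bad), class = "binseq_format_error")

  # block headers observed on disk: 32 bytes before each payload
  path <- local_file(".vbq")
  write_vbq("ACGT", path, compressed = FALSE)
  bh <- readBin(path, "raw", 64)[33:64]
  expect_identical(bh[1:4], charToRaw("VBLK"))
  expect_equal(binseqr:::raw_u64(bh[13:20]), 1) # n_records
})

test_that("round trip is lossless across all feature combinations", {
  set.seed(21)
  grid <- expand.grid(paired = c(FALSE, TRUE), quality = c(FALSE, TRUE),
                      headers = c(FALSE, TRUE), flags = c(FALSE, TRUE),
                      compressed = c(FALSE, TRUE), bits = c(2, 4))
  # a representative subset keeps the suite quick but covers every switch
  grid <- grid[sample(nrow(grid), 20), ]
  for (g in seq_len(nrow(grid))) {
    cfg <- grid[g, ]
    alpha <- if (cfg$bits == 2) c("A", "C", "G", "T") else c("A", "C", "G", "T", "N")
    n <- 120
    p <- rand_seqs(n, sample(c(0, 1, 5:80), n, replace = TRUE), alpha)
    x <- if (cfg$paired) rand_seqs(n, sample(5:120, n, replace = TRUE), alpha)
    qp <- if (cfg$quality) rand_quals(p)
    qx <- if (cfg$quality && cfg$paired) rand_quals(x)
    hp <- if (cfg$headers) ifelse(seq_len(n) %% 7 == 0, "",
                                  rand_seqs(n, 12, c(LETTERS, " ", ":")))
    hx <- if (cfg$headers && cfg$paired) rand_seqs(n, 9, LETTERS)
    fl <- if (cfg$flags) as.numeric(sample(0:2^20, n))

    path <- local_file(".vbq")
    write_vbq(p, path, extended = x, qual_primary = qp, qual_extended = qx,
              header_primary = hp, header_extended = hx, flags = fl,
              encoding = cfg$bits, virtual_block_size = 1024,
              compressed = cfg$compressed)
    got <- vbq_read(path)
    expect_identical(got$primary, p)
    if (cfg$paired) expect_identical(got$extended, x)
    if (cfg$quality) expect_identical(got$qual_primary, qp)
    if (cfg$quality && cfg$paired) expect_identical(got$qual_extended, qx)
    if (cfg$headers) expect_identical(got$header_primary, hp)
    if (cfg$flags) expect_equal(got$flag, fl)
  }
})

test_that("the trailing index describes every block exactly", {
  set.seed(22)
  path <- local_file(".vbq")
  p <- rand_seqs(500, 40)
  write_vbq(p, path, virtual_block_size = 512)
  idx <- load_index(path)
  expect_gt(nrow(idx), 5)
  expect_equal(sum(idx$n_records), 500)
  expect_equal(idx$cum_records, cumsum(c(0, idx$n_records[-nrow(idx)])))
  expect_false(is.unsorted(idx$offset, strictly = TRUE))
  # decompressed payload of every block fits the virtual size
  f <- vbq_open(path)
  on.exit(close(f))
  for (j in seq_len(nrow(idx)))
    expect_lte(nrow(read_block(f, idx[j, ])), 512 %/% 8) # >= 8 B per record
})

test_that("index corruption and file pairing are distinguishable", {
  set.seed(23)
  path <- local_file(".vbq")
  write_vbq(rand_seqs(50, 30), path, virtual_block_size = 256)
  bytes <- readBin(path, "raw", file.size(path))

  # truncating the footer breaks the index magic
  writeBin(bytes[-length(bytes)], path)
  expect_error(load_index(path), class = "binseq_corrupt_index_error")

  # perturbing the recorded data-byte count breaks the pairing check
  ft <- bytes[(length(bytes) - 15):length(bytes)]
  index_bytes <- binseqr:::raw_u64(ft[1:8])
  ih_at <- length(bytes) - 16 - index_bytes  # 0-based offset of index header
  tampered <- bytes
  tampered[ih_at + 9] <- as.raw(as.integer(tampered[ih_at + 9]) + 1L)
  writeBin(tampered, path)
  expect_error(load_index(path), class = "binseq_pairing_error")
})

test_that("an empty VBQ file has an index with zero ranges", {
  path <- local_file(".vbq")
  w <- vbq_writer(path)
  res <- w$close()
  expect_equal(res$records, 0)
  idx <- load_index(path)
  expect_equal(nrow(idx), 0)
  expect_equal(nrow(vbq_read(path)), 0)
  # pre-index region is just the 32-byte file header
  bytes <- readBin(path, "raw", file.size(path))
  ft <- bytes[(length(bytes) - 15):length(bytes)]
  ih_at <- length(bytes) - 16 - binseqr:::raw_u64(ft[1:8])
  expect_equal(binseqr:::raw_u64(bytes[ih_at + (9:16)]), 32)
})

test_that("records never straddle blocks and oversize records error", {
  set.seed(24)
  path <- local_file(".vbq")
  # 100-byte serialized records (8 slen + 23 data bytes -> padded): use
  # fixed 64 bp two-bit reads: 8 + 16 = 24 B each; block 100 B -> 4/block
  p <- rand_seqs(10, 64)
  write_vbq(p, path, virtual_block_size = 100, compressed = FALSE)
  idx <- load_index(path)
  expect_equal(idx$n_records, c(4, 4, 2)) # final partial block is smaller
  w <- vbq_writer(local_file(".vbq"), virtual_block_size = 64)
  expect_error(w$write(strrep("A", 2000)), "block size",
               class = "binseq_config_error")
  w$abort()
})

test_that("global record access by index binary search matches iteration", {
  set.seed(25)
  path <- local_file(".vbq")
  p <- rand_seqs(300, sample(10:60, 300, replace = TRUE))
  write_vbq(p, path, virtual_block_size = 600)
  f <- vbq_open(path)
  on.exit(close(f))
  all <- vbq_read(f)
  expect_identical(all$primary, p)
  for (i in c(0, 1, sample(0:299, 20), 299))
    expect_identical(vbq_get_record(f, i)$primary, p[i + 1])
  expect_error(vbq_get_record(f, 300), class = "binseq_range_error")
})

test_that("compressed VBQ beats BQ on fixed-length random reads", {
  set.seed(26)
  p <- rand_seqs(2000, 100)
  bq <- local_file(".bq"); vbq <- local_file(".vbq")
  write_bq(p, bq)
  write_vbq(p, vbq)
  expect_lt(file.size(vbq), file.size(bq))
})
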