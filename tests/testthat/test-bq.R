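test_that("record size follows S = F + W * sum(ceiling(len/B))", {
  expect_equal(record_size(bq_header(100)), 32)
  expect_equal(record_size(bq_header(100, flag_enabled = TRUE)), 40)
  expect_equal(record_size(bq_header(50, 150)), 56)
  expect_equal(record_size(bq_header(100, encoding = 4)), 56)

  h <- bq_header(100)
  expect_equal(record_offset(0, h), 32)
  expect_equal(record_offset(10, h), 352)
  expect_equal(record_offset(1, bq_header(50, 150)), 88)
  expect_error(record_offset(-1, h), class = "binseq_argument_error")
})

test_that("headers serialize to exactly 32 bytes and survive a round trip", {
  h <- bq_header(slen = 151, xlen = 27, encoding = 4, flag_enabled = TRUE)
  r <- binseqr:::serialize_bq_header(h)
  expect_length(r, 32)
  back <- binseqr:::parse_bq_header(r)
  expect_equal(back[c("slen", "xlen", "encoding", "flag_enabled")],
               h[c("slen", "xlen", "encoding", "flag_enabled")])

  bad <- r; bad[1] <- as.raw(0)
  expect_error(binseqr:::parse_bq_header(bad), "magic",
               class = "binseq_format_error")
  bad <- r; bad[20] <- as.raw(7)
  expect_error(binseqr:::parse_bq_header(bad), "reserved",
               class = "binseq_format_error")
})

test_that("write/read round trip preserves sequences, flags and order", {
  set.seed(7)
  path <- local_file(".bq")
  p <- rand_seqs(40, 33)
  x <- rand_seqs(40, 75)
  flg <- as.numeric(sample(0:1e6, 40))
  rep <- write_bq(p, path, extended = x, flags = flg, encoding = 2)
  expect_equal(rep$written, 40)
  expect_equal(rep$bytes, file.size(path))

  h <- read_bq_header(path)
  expect_equal(h$n_records, 40)
  expect_equal(file.size(path), 32 + 40 * record_size(h))

  got <- bq_read(path)
  expect_identical(got$primary, p)
  expect_identical(got$extended, x)
  expect_equal(got$flag, flg)
})

test_that("random access equals sequential access at every index", {
  set.seed(8)
  path <- local_file(".bq")
  p <- rand_seqs(100, 21)
  write_bq(p, path)
  f <- bq_open(path)
  on.exit(close(f))
  seqd <- bq_read(f)$primary
  for (k in sample(0:99, 25)) # spot-check; full sweep in the acceptance suite
    expect_identical(bq_get_record(f, k)$primary, seqd[k + 1])
  expect_identical(bq_get_record(f, 99)$primary, p[100])
  expect_error(bq_get_record(f, 100), class = "binseq_range_error")
  expect_error(bq_get_record(f, -1), class = "binseq_range_error")
  # slices
  expect_identical(bq_read(f, first = 10, n = 5)$primary, p[11:15])
})

test_that("trailing pad bits of stored words are zero", {
  path <- local_file(".bq")
  write_bq("T", path)  # 1 base in a 32-base word
  raw_rec <- readBin(path, "raw", n = file.size(path))[-(1:32)]
  expect_length(raw_rec, 8)
  expect_equal(as.integer(raw_rec[1]), 0x03)
  expect_identical(raw_rec[2:8], raw(7))

  path2 <- local_file(".bq")
  write_bq(strrep("G", 33), path2) # one full word + 1 base
  rec <- readBin(path2, "raw", n = file.size(path2))[-(1:32)]
  expect_equal(as.integer(rec[9]), 0x02)
  expect_identical(rec[10:16], raw(7))
})

test_that("malformed files and length mismatches are rejected", {
  path <- local_file(".bq")
  writeBin(as.raw(1:40), path)
  expect_error(read_bq_header(path), "magic", class = "binseq_format_error")

  write_bq(rand_seqs(3, 10), path)
  # data section no longer a record-size multiple
  con <- file(path, "ab"); writeBin(as.raw(1), con); close(con)
  expect_error(read_bq_header(path), "multiple", class = "binseq_format_error")

  w <- bq_writer(local_file(".bq"), slen = 10)
  expect_error(w$write(c("ACGTACGTAC", "ACGT")), "VBQ",
               class = "binseq_format_error")
  expect_error(w$write("ACGTACGTAC", extended = "ACGT"),
               class = "binseq_argument_error")
  w$close()
})

test_that("skip policy drops whole records and counts them", {
  path <- local_file(".bq")
  p <- c("ACGTACGTAC", "ACGTNCGTAC", "TTTTTTTTTT")
  rep <- write_bq(p, path, policy = invalid_policy("skip"))
  expect_equal(rep$written, 2)
  expect_equal(rep$skipped, 1)
  expect_identical(bq_read(path)$primary, p[c(1, 3)])
})

test_that("an empty BQ file is a bare header with zero records", {
  path <- local_file(".bq")
  w <- bq_writer(path, slen = 10)
  w$close()
  expect_equal(file.size(path), 32)
  h <- read_bq_header(path)
  expect_equal(h$n_records, 0)
  expect_equal(nrow(bq_read(path)), 0)
})
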