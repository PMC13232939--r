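write_fastq_file <- function(headers, seqs, quals = NULL, gz = FALSE,
                             env = parent.frame()) {
  path <- local_file(if (gz) ".fastq.gz" else ".fastq", env = env)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(as.vector(rbind(paste0("@", headers), seqs, "+", quals)), con)
  close(con)
  path
}

test_that("fixed-length FASTQ encodes to BQ with the exact file size", {
  set.seed(51)
  seqs <- rand_seqs(4, 100)
  fq <- write_fastq_file(paste0("read", 1:4), seqs)
  out <- local_file(".bq")
  rep <- encode_fastx(fq, out)
  expect_equal(rep$written, 4)
  expect_equal(rep$skipped, 0)
  expect_equal(file.size(out), 32 + 4 * 32)   # 8 * ceiling(100/32) per record
  expect_identical(bq_read(out)$primary, seqs)
})

test_that("the skip policy drops N-containing reads and reports them", {
  seqs <- c("ACGTACGTAC", "ACGTNCGTAC", "TTTTACGTAC", "GGGGACGTAC")
  fq <- write_fastq_file(paste0("r", 1:4), seqs)
  out <- local_file(".bq")
  rep <- encode_fastx(fq, out, policy = invalid_policy("skip"))
  expect_equal(rep$written, 3)
  expect_equal(rep$skipped, 1)
  expect_identical(bq_read(out)$primary, seqs[-2])

  # replacement policies keep all reads
  out2 <- local_file(".bq")
  rep2 <- encode_fastx(fq, out2,
                       policy = invalid_policy("fixed_replace", fixed_base = "G"))
  expect_equal(rep2$written, 4)
  expect_identical(bq_read(out2)$primary[2], "ACGTGCGTAC")
})

test_that("paired inputs become one paired file; count mismatch errors", {
  set.seed(52)
  s1 <- rand_seqs(6, 50); s2 <- rand_seqs(6, 150)
  f1 <- write_fastq_file(paste0("p", 1:6), s1)
  f2 <- write_fastq_file(paste0("p", 1:6), s2, gz = TRUE)
  out <- local_file(".bq")
  encode_fastx(f1, out, input2 = f2)
  h <- read_bq_header(out)
  expect_equal(h$slen, 50)
  expect_equal(h$xlen, 150)
  got <- bq_read(out)
  expect_identical(got$extended, s2)

  f3 <- write_fastq_file(paste0("q", 1:4), rand_seqs(4, 150))
  expect_error(encode_fastx(f1, local_file(".bq"), input2 = f3),
               class = "binseq_pairing_error")
})

test_that("BQ length mismatches point the user at VBQ, with the ordinal", {
  fq <- write_fastq_file(c("a", "b"), c("ACGTACGT", "ACGT"))
  err <- expect_error(encode_fastx(fq, local_file(".bq")),
                      class = "binseq_format_error")
  expect_match(conditionMessage(err), "record 2")
  expect_match(conditionMessage(err), "VBQ")
  # VBQ accepts the same input
  out <- local_file(".vbq")
  expect_equal(encode_fastx(fq, out)$written, 2)
  expect_identical(vbq_read(out)$primary, c("ACGTACGT", "ACGT"))
})

test_that("archive round trips are lossless and re-encoding is idempotent", {
  set.seed(53)
  n <- 300
  s1 <- rand_seqs(n, sample(20:70, n, replace = TRUE),
                  c("A", "C", "G", "T", "N"))
  s2 <- rand_seqs(n, sample(20:70, n, replace = TRUE))
  h1 <- sprintf("inst1:%d 1:N:0:ACGT", seq_len(n))
  f1 <- write_fastq_file(h1, s1, rand_quals(s1))
  f2 <- write_fastq_file(h1, s2, rand_quals(s2), gz = TRUE)

  vbq1 <- local_file(".vbq")
  encode_fastx(f1, vbq1, input2 = f2, archive = TRUE)
  o1 <- local_file(".fastq"); o2 <- local_file(".fastq")
  decode_binseq(vbq1, o1, output2 = o2)
  expect_identical(readLines(o1), readLines(f1))
  g <- gzfile(f2, "rt"); l2 <- readLines(g); close(g)
  expect_identical(readLines(o2), l2)

  # second encode of the decoded files reproduces the first byte stream
  vbq2 <- local_file(".vbq")
  encode_fastx(o1, vbq2, input2 = o2, archive = TRUE)
  expect_identical(readBin(vbq1, "raw", file.size(vbq1)),
                   readBin(vbq2, "raw", file.size(vbq2)))
  # archive demands a VBQ target
  expect_error(encode_fastx(f1, local_file(".bq"), archive = TRUE),
               class = "binseq_config_error")
})

test_that("BQ decodes to FASTA by default, FASTQ only with a fake quality", {
  set.seed(54)
  seqs <- rand_seqs(5, 30)
  bq <- local_file(".bq")
  write_bq(seqs, bq)
  fa <- local_file(".fasta")
  decode_binseq(bq, fa)
  lines <- readLines(fa)
  expect_identical(lines[c(2, 4)], seqs[1:2])
  expect_match(lines[1], "^>r0+1$")                  # zero-padded ordinals

  expect_error(decode_binseq(bq, local_file(".fastq"), format = "fastq"),
               "fake_qual", class = "binseq_format_error")
  fqo <- local_file(".fastq")
  decode_binseq(bq, fqo, format = "fastq", fake_qual = "?")
  m <- matrix(readLines(fqo), nrow = 4)
  expect_identical(m[2, ], seqs)
  expect_true(all(m[4, ] == strrep("?", 30)))

  # paired BQ decodes to two synchronized mate files
  bq2 <- local_file(".bq")
  write_bq(seqs, bq2, extended = rand_seqs(5, 40))
  expect_error(decode_binseq(bq2, local_file(".fasta")),
               class = "binseq_pairing_error")
  oa <- local_file(".fasta"); ob <- local_file(".fasta")
  decode_binseq(bq2, oa, output2 = ob)
  expect_equal(length(readLines(oa)), length(readLines(ob)))
})

test_that("multi-line FASTA input is accepted and re-encoded", {
  fa <- local_file(".fasta")
  writeLines(c(">chunk1 desc", "ACGTACGT", "ACGTAC", ">chunk2", "TTTT"), fa)
  out <- local_file(".vbq")
  rep <- encode_fastx(fa, out)
  expect_equal(rep$written, 2)
  expect_identical(vbq_read(out)$primary, c("ACGTACGTACGTAC", "TTTT"))
  # storing qualities from FASTA is impossible
  expect_error(encode_fastx(fa, local_file(".vbq"), quality = TRUE),
               class = "binseq_config_error")
})

test_that("the FASTQ writer agrees with an independent parser", {
  path <- local_file(".fastq")
  generate_fastq(path, 50, 40, seed = 55)
  ref <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_equal(length(ref), 50)
  expect_identical(as.character(unname(ref)),
                   matrix(readLines(path), nrow = 4)[2, ])
  expect_identical(names(ref), sprintf("r%d", 1:50))
})

test_that("info summarizes both container formats", {
  set.seed(56)
  bq <- local_file(".bq")
  write_bq(rand_seqs(10, 60), bq)
  i <- binseq_info(bq)
  expect_equal(i$format, "bq")
  expect_equal(i$records, 10)
  expect_equal(i$record_bytes, 16)

  vbq <- local_file(".vbq")
  write_vbq(rand_seqs(10, 60), vbq, qual_primary = rep(strrep("I", 60), 10))
  i <- binseq_info(vbq)
  expect_equal(i$format, "vbq")
  expect_true(i$quality)
  expect_equal(i$records, 10)
})

test_that("the CLI maps error classes to exit codes", {
  set.seed(57)
  fq <- write_fastq_file("x", "ACGTACGT")
  out <- local_file(".bq")
  expect_equal(binseq(c("encode", "-i", fq, "-o", out)), 0L)
  expect_equal(binseq(c("info", "-i", out)), 0L)
  # not a BINSEQ file -> format error -> 2
  expect_equal(suppressMessages(binseq(c("info", "-i", fq))), 2L)
  # paired count mismatch -> 3
  f1 <- write_fastq_file(c("a", "b"), rand_seqs(2, 10))
  f2 <- write_fastq_file("a", rand_seqs(1, 10))
  expect_equal(suppressMessages(
    binseq(c("encode", "-i", f1, "-I", f2, "-o", local_file(".vbq")))), 3L)
  # unknown option -> generic failure
  expect_equal(suppressMessages(binseq(c("encode", "--bogus"))), 1L)
})

test_that("CLI generate/count/scan compose end to end", {
  td <- withr::local_tempdir()
  fq <- file.path(td, "g.fastq")
  vbq <- file.path(td, "g.vbq")
  tsv <- file.path(td, "k.tsv")
  expect_equal(binseq(c("generate", "-n", "80", "-l", "25", "--seed", "3",
                        "-o", fq)), 0L)
  expect_equal(binseq(c("encode", "-i", fq, "-o", vbq)), 0L)
  expect_equal(binseq(c("count", "-i", vbq, "-k", "5", "-t", "2",
                        "-o", tsv)), 0L)
  tab <- read.delim(tsv, header = FALSE)
  expect_equal(sum(tab$V2), 80 * (25 - 5 + 1))
  out <- capture.output(code <- binseq(c("scan", "-i", vbq)))
  expect_equal(code, 0L)
  expect_match(out, "records\t80", all = FALSE)
})
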