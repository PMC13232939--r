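test_that("schemes and word arithmetic follow the packing geometry", {
  two <- encoding_scheme(2)
  four <- encoding_scheme(4)
  expect_equal(two$bases_per_word, 32L)
  expect_equal(four$bases_per_word, 16L)
  expect_equal(two$bits_per_base * two$bases_per_word, 64L)
  expect_equal(four$bits_per_base * four$bases_per_word, 64L)

  expect_equal(words_needed(100, two), 4L)
  expect_equal(words_needed(0, four), 0L)
  expect_equal(words_needed(150, two), 5L)
  expect_equal(words_needed(150, four), 10L)
  expect_error(words_needed(-1, two), class = "binseq_argument_error")
  expect_error(encoding_scheme(3), class = "binseq_argument_error")
})

test_that("code tables are value-preserving across schemes", {
  t2 <- code_table(2)
  t4 <- code_table(4)
  expect_setequal(t2$code, 0:3)                       # distinct in [0,3]
  expect_equal(t4$code[match(t2$base, t4$base)], t2$code)
  n_code <- t4$code[t4$base == "N"]
  expect_false(n_code %in% t2$code)
  expect_true(n_code >= 4)                            # uses a bit above the low two
  # round trip base -> code -> base through the real codec
  for (b in t4$base)
    expect_identical(unpack_bases(pack_bases(b, 4)), b)
})

test_that("sanitize applies each invalid-base policy", {
  skip_p <- invalid_policy("skip")
  expect_identical(sanitize("ACGT", skip_p), "ACGT")
  expect_identical(sanitize("ACNT", skip_p), NA_character_)
  expect_identical(sanitize(c("ACNT", "GGGG"), skip_p), c(NA, "GGGG"))

  fixed <- invalid_policy("fixed_replace", fixed_base = "A")
  expect_identical(sanitize("ACNT", fixed), "ACAT")
  # four-bit: N is encodable and never touched
  expect_identical(sanitize("ACNT", fixed, encoding_scheme(4)), "ACNT")
  expect_identical(sanitize("ACNT", skip_p, encoding_scheme(4)), "ACNT")
  # case folding before lookup; U stays invalid (no silent RNA mapping)
  expect_identical(sanitize("acgt", skip_p), "ACGT")
  expect_identical(sanitize("ACUT", fixed), "ACAT")
  expect_error(invalid_policy("fixed_replace", fixed_base = "N"),
               class = "binseq_argument_error")
  expect_error(invalid_policy("random_replace"),
               class = "binseq_argument_error")
})

test_that("random_replace is seed-reproducible and only touches invalids", {
  seqs <- c(paste0("A", strrep("N", 20), "A"), "CGXCG", "TTTT")
  a <- sanitize(seqs, invalid_policy("random_replace", seed = 11))
  b <- sanitize(seqs, invalid_policy("random_replace", seed = 11))
  d <- sanitize(seqs, invalid_policy("random_replace", seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, d) && identical(b, d)) # different stream
  expect_false(any(grepl("[^ACGT]", a)))
  # valid positions untouched
  expect_identical(substr(a[1], 1, 1), "A")
  expect_identical(substr(a[1], 22, 22), "A")
  expect_identical(a[3], "TTTT")
  # a policy consumes its stream across calls but restores the session RNG
  set.seed(99); before <- runif(1)
  p <- invalid_policy("random_replace", seed = 5)
  set.seed(99)
  s1 <- sanitize("NNNN", p); invisible(sanitize("NNNN", p))
  expect_identical(runif(1), before)
  expect_identical(s1, sanitize("NNNN", invalid_policy("random_replace", seed = 5)))
})

test_that("pack places codes LSB-first in little-endian words", {
  p <- pack_bases(strrep("A", 32))
  expect_identical(p$data, raw(8))                 # A=0 throughout one word
  expect_equal(p$n_bases, 32)

  p <- pack_bases("ACGT")
  expect_equal(as.integer(p$data[1]), 0xE4)        # 0b11100100
  expect_identical(p$data[2:8], raw(7))

  p <- pack_bases("")
  expect_identical(p$data, raw(0))
  expect_equal(p$n_bases, 0)

  expect_error(pack_bases("ACXT"), "position 3",
               class = "binseq_encoding_error")
  expect_error(pack_bases("ACNT"), class = "binseq_encoding_error")
  expect_silent(pack_bases("ACNT", 4))
})

test_that("unpack inverts pack and rejects corrupt four-bit codes", {
  s <- strrep("ACGT", 25)
  expect_identical(unpack_bases(pack_bases(s, 2)), s)
  expect_identical(unpack_bases(pack_bases(s, 4)), s)
  expect_identical(unpack_bases(pack_bases("ACGTN", 4)), "ACGTN")
  expect_identical(unpack_bases(as.raw(c(0xE4, rep(0, 7))), 4, 2), "ACGT")
  # four-bit code 5 has no table entry
  expect_error(unpack_bases(as.raw(c(0x05, rep(0, 7))), 1, 4),
               class = "binseq_encoding_error")
})

test_that("round trip is identity and matches the scalar oracle", {
  set.seed(42)
  lens <- c(0, 1, 15, 16, 17, 31, 32, 33, 63, 64, 65,
            sample(0:1000, 25))
  for (bits in c(2, 4)) {
    alpha <- if (bits == 2) c("A", "C", "G", "T") else c("A", "C", "G", "T", "N")
    for (L in lens) {
      s <- rand_seq(L, alpha)
      p <- pack_bases(s, bits)
      expect_identical(unpack_bases(p), s)
      expect_identical(p$data, ref_pack(s, bits))
      expect_equal(length(p$data), 8 * ceiling(L / (64 / bits)))
    }
  }
})
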