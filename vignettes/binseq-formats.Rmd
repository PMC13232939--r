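---
title: "BQ and VBQ: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BQ and VBQ: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binseqr)
```

This vignette is the package's account of what the two container formats
store, the conventions they fix, the choices that were genuinely open and
how they were settled, and what the test suite does and does not
demonstrate.

## Why binary containers for reads

Most sequence analysis over raw reads touches only the nucleotide string.
FASTQ spends more than three quarters of its bytes on everything else
(identifiers, qualities, separators, ASCII bases) and, once gzipped, can
only be consumed through a single sequential decompression stream. The two
formats here make the opposite trade: store the minimum needed, packed
densely, in layouts where the location of work is computable, so that many
workers can read disjoint parts of one file at once.

## Base packing

A packing scheme maps bases to small integer codes and packs them into
64-bit little-endian words:

* two-bit: A=0, C=1, G=2, T=3; 32 bases per word;
* four-bit: the same values in the low bits, plus N=8 (the fourth bit
  set); 16 bases per word.

Base 0 occupies the least-significant bits of the first word. Because the
words are serialized little-endian, the byte stream is position-monotone:
byte `i %/% 4` (two-bit) holds bases `4i..4i+3`, which lets the codec work
byte-wise without any 64-bit arithmetic in R. Pad bits after the final
base are always zero, which makes files deterministic and helps the block
compressor. These code assignments are a convention of this package: files
written here are internally consistent and fully specified, but
bit-compatibility with other implementations of the same idea is not
claimed.

Unencodable input (anything outside the scheme's alphabet after case
folding — including `U`, which is deliberately not mapped to `T`) is
resolved by an `invalid_policy()`: `skip` drops the whole record (the
record, not the base, is the unit a downstream aligner consumes),
`fixed_replace` substitutes one chosen base, `random_replace` substitutes
i.i.d. uniform draws from `{A,C,G,T}`. A random policy owns a private RNG
stream seeded at construction: repeated calls continue the stream, a fresh
policy with the same seed reproduces it exactly, and the session RNG is
left untouched.

## BQ: fixed records, closed-form access

A BQ file is a 32-byte header followed by `n` identical-size records:
optional 8-byte flag word, then the packed primary sequence, then (for
paired files) the packed mate. With word size $W = 8$, bases per word $B$,
flag size $F \in \{0, 8\}$ and lengths $N, M$:

$$S = F + W\left(\lceil N/B\rceil + \lceil M/B\rceil\right), \qquad
  P_i = 32 + i\,S.$$

Everything follows from these two identities: `n = (filesize - 32) / S` is
validated on open, `file.size == 32 + n S` is asserted after every write,
and `bq_get_record()` is one seek plus one record decode regardless of
`i`. The flag word defaults to off — the sizes above are then pure
sequence payload — and to 0 when enabled but not supplied.

Header layout (all little-endian): magic `BSQ\x01`, version, encoding
bits, flag switch, one reserved byte, `slen` and `xlen` as u32, and zero
reserved bytes to 32. Reserved bytes must read back as zero; this is the
cheap forward-compatibility check.

## VBQ: blocks, compression, trailing index

VBQ trades O(1) record access for flexibility: records may vary in length
and optionally carry qualities, headers, flags and a mate. Records are
serialized as

    [flag u64]? [slen u64] [xlen u64]? [primary words] [extended words]?
    [qual bytes]? [u16 len + header]? ...

and packed greedily into blocks: each block holds the maximal prefix of
pending records whose total serialized size fits the *virtual block size*,
the fixed uncompressed byte budget declared in the file header. Records
never straddle blocks, so every block decodes independently — that is the
format's unit of parallelism. A record larger than the budget is a
configuration error telling the user to raise it.

Choices that the design left open, settled here:

* **Virtual block size counts payload only** (the 32-byte block header is
  excluded); default 128 KiB — large enough that two-bit 100–150 bp reads
  give thousands of records per block, small enough for fine-grained
  scheduling.
* **The stored size in the block header is the post-compression byte
  count** — it is what a reader must consume from disk.
* **Qualities are raw Phred+33 bytes**, no offset or re-encoding;
  losslessness is then byte-trivial.
* **The final partial block is a normal, smaller block.**
* **ZSTD level 3** by default. Compressed sizes depend on the zstd version
  and level, so no exact compressed size is ever asserted anywhere in the
  package — only the direction of comparisons (e.g. compressed two-bit
  VBQ of fixed-length random reads is smaller than the corresponding BQ,
  which it must be, since compression recovers the pad zeros and the
  constant per-record length field).
* **The index is embedded at the end of the file**, not a sidecar: a
  32-byte uncompressed index header (magic plus the byte count of the
  pre-index region), the ZSTD-compressed 32-byte ranges
  `(offset, stored_size, n_records, cum_records)`, and a 16-byte footer
  (index byte count plus magic). Readers load it first: footer magic, then
  the byte-count cross-check — a mismatch there is reported as a *pairing*
  error (index and data region disagree), distinct from a *corruption*
  error (bad magic, undecodable ranges, inconsistent cumulative counts).
  `cum_records` makes global record lookup a binary search.

## The parallel contract

`process_parallel()` implements per-record map / per-batch reduce hooks: a
worker folds each record into local state, and every `batch_size` records
(default 4096) the reduce hook merges that state into the worker's running
result and the state is reset; a drain-time reduce fires whenever records
are pending after the last full batch, so the hook runs at least once
after a worker's final record. BQ partitions are contiguous record ranges
(cheap because offsets are closed-form); VBQ partitions are whole blocks.
Workers are forked processes, so cross-worker merging happens through an
explicit `combine` function rather than a shared table; `combine` must be
commutative and associative, and then the result is identical for every
worker count and scheduling — which the suite checks rather than assumes.
With one worker the machinery reduces to a plain serial loop.

The k-mer counter is the interface's exemplar: map appends each record's
literal length-`k` windows to local state, reduce tabulates and merges
them into the worker's count table, combine sums tables. (A per-record
hash-table update would satisfy the same contract; batching the tabulation
is simply the efficient shape for this runtime, and the observable result
— the merged table — is identical.) No reverse-complement
canonicalization is applied, and windows containing `N` count as literal
strings; both are caller-side policies if wanted. The conservation
invariant $\sum \text{counts} = \sum_i \max(0, L_i - k + 1)$ over all
sequences (both mates of a pair) is the oracle the tests use.

`composite_score()` implements the min–max-normalized time/storage
trade-off score $m_i = (\bar t_i + \bar s_i)/2$: 0 means best on both
axes, 1 worst on both. It refuses degenerate inputs (equal minima and
maxima) rather than dividing by zero.

## The read generator

`generate_reads()` / `generate_fastq()` produce the package's benchmark
and test inputs: every base i.i.d. uniform over `{A,C,G,T}`, constant
quality `"?"`, identifiers `r1, r2, ...`. The defaults mirror the
conditions the storage identities are quoted for: 10 M records, 100 bp
single-end, 50+150 bp paired. Bases are drawn from R's RNG record by
record (primary then mate), so output is a pure function of the spec and
seed and independent of internal chunking — the determinism the
idempotence tests rely on.

What the generator deliberately does not emulate: real base composition
(GC skew, homopolymers), quality-score distributions, duplicate reads,
adapters, or platform error profiles. Consequences: BQ sizes on real data
are identical (they depend only on lengths), but compressed VBQ sizes and
any compression-ratio conclusions transfer only directionally — uniform
random sequence is the incompressible worst case for the nucleotide
payload, while constant qualities are the compressible best case.

## Numerical and degenerate-input choices

* All on-disk u64 fields are carried as R doubles; every value that can
  occur (offsets, sizes, counts) is far below $2^{53}$, where double
  arithmetic is exact. Record flags above $2^{53}$ are therefore not
  representable through the R API.
* Empty inputs are legal everywhere they can be: a zero-record BQ file is
  a bare header; a zero-record VBQ file has an index with zero ranges and
  a data-byte count of 32; zero-length sequences pack to zero words and
  round-trip.
* Sequence headers are length-prefixed with u16, capping them at 65,535
  bytes — beyond any real FASTQ description line.
* FASTQ is read as strict 4-line records (the dialect the writer also
  emits); multi-line FASTA is accepted on input and written single-line.
  gzip inputs are detected by magic bytes, not file extension.

## Problem sizes in the test suite

The suite exercises the full property space at sizes chosen to keep a
complete run in tens of seconds: round-trip and oracle properties on
thousands of random sequences with lengths 0–1000; access-equivalence
sweeps on 1000-record files; losslessness on 10,000 generated pairs;
storage identities measured at 100,000 records and checked against the
closed form, which is then evaluated at 10 M records where it reproduces
305.18 / 534.06 / 534.06 / 1068.12 MiB. `scripts/acceptance.R` performs
the 10 M-record encodes for real.

## Known limitations

* No claim of bit-compatibility with other implementations of these
  layouts (magic numbers and code assignments here are package
  conventions).
* Compressed VBQ sizes are zstd-version- and level-dependent; only
  directions, never exact compressed sizes, are guaranteed.
* Wall-clock parallel speedup is a hardware property, not a format
  guarantee: forked workers help only when multiple cores are actually
  available, and on a single-core machine extra workers degrade wall
  clock through oversubscription while still producing identical results.
  The suite's scaling smoke test (4 workers no slower than 1.25× one
  worker) therefore assumes at least two usable cores; the correctness
  tests do not.
* Per-block integrity is magic-plus-structure validation, not a checksum;
  silent bit rot inside a compressed payload is caught only insofar as
  zstd or the record parser notices.
* No mid-file appends or concurrent writers; a file is written once,
  front to back.
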