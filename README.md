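# binseqr

Binary container formats for nucleotide sequence records, with tools to
convert, inspect and process them in parallel.

## The problem

High-throughput sequencing runs produce 10⁷–10⁹ reads, almost always stored
as gzip-compressed FASTQ. That format forces single-threaded decompression
and sequential parsing of irregularly sized records, so embarrassingly
parallel workloads (k-mer counting, alignment, assembly) end up I/O-bound:
throughput is limited by the parser, not the CPUs. `binseqr` implements two
complementary binary containers designed around parallel access:

- **BQ** (`.bq`) — for fixed-length reads. A 32-byte header followed by
  fixed-size records with two-bit (`{A,C,G,T}`) or four-bit (`{A,C,G,T,N}`)
  base packing into little-endian 64-bit words. Record *i* sits at a
  closed-form offset, so any record is reachable in O(1) without touching
  the rest of the file. Qualities and identifiers are deliberately not
  stored.
- **VBQ** (`.vbq`) — for variable-length reads. Records (optionally with
  Phred+33 qualities, sequence headers, per-record 64-bit flags, and a
  mate sequence) are packed into blocks of a fixed *virtual* (uncompressed)
  byte budget, each independently ZSTD-compressed, with a trailing
  compressed block index. Blocks decode independently, so files are
  processed block-parallel.

Both formats store single- and paired-end data in one file, eliminating
synchronized mate files.

## Core identities

With `W = 8` the word size in bytes, `B` the bases per word (32 two-bit, 16
four-bit), `F ∈ {0, 8}` the optional flag-field size, and `N`, `M` the
primary/mate lengths, the BQ record size is

    S = F + W * ( ceil(N/B) + ceil(M/B) )      (the M term only when paired)

and record *i* starts at byte

    P_i = H + i * S,   H = 32 (the header size).

A BQ file holding `n` records is therefore exactly `32 + n * S` bytes —
asserted on every write. For 10 M single-end 100 bp reads this gives
320,000,032 B = 305.18 MiB (two-bit) and 534.06 MiB (four-bit); for 10 M
pairs of 50+150 bp, 534.06 MiB (two-bit) and 1068.12 MiB (four-bit).

Bases use codes A=0, C=1, G=2, T=3 (four-bit additionally N=8), placed
least-significant-first within each word; words serialize little-endian, so
`"ACGT"` packs to the byte `0xE4` (`0b11100100`). Unencodable bases are
resolved by a configurable policy: skip the record, replace with seeded
random bases, or replace with a fixed base.

## Worked example

```r
library(binseqr)

fq <- "reads.fastq"
generate_fastq(fq, 5000, 100, seed = 42)   # uniform random 100 bp reads
rep <- encode_fastx(fq, "reads.bq")
rep$written
#> [1] 5000

binseq_info("reads.bq")
#> # A tibble: 1 x 9
#>   format encoding records paired  slen  xlen flag_enabled record_bytes
#>   <chr>     <int>   <dbl> <lgl>  <dbl> <dbl> <lgl>               <dbl>
#> 1 bq            2    5000 FALSE    100     0 FALSE                  32

file.size("reads.bq")                      # 32 + 5000 * 32
#> [1] 160032

bq_get_record("reads.bq", 4999)$primary |> substr(1, 40)
#> [1] "ATAATATTTACTAAGTGTTTAGTTGCACGACTTCGGGGCG"

head(count_kmers("reads.bq", k = 8, n_workers = 2), 3)
#> # A tibble: 3 x 2
#>   kmer     count
#>   <chr>    <dbl>
#> 1 AAAAAAAA     3
#> 2 AAAAAAAC     5
#> 3 AAAAAAAG    12
```

The record count, file size and record access come straight from the fixed
layout: 5000 records of `8 * ceil(100/32) = 32` bytes after a 32-byte
header, with record 4999 read by one seek. The k-mer table is produced by
the hook-based map-reduce interface ([`process_parallel()`]); identical
tables are returned for any worker count.

Lossless archiving round-trips FASTQ exactly:

```r
encode_fastx("r1.fastq", "a.vbq", input2 = "r2.fastq", archive = TRUE)
decode_binseq("a.vbq", "o1.fastq", output2 = "o2.fastq")
# o1/o2 are byte-identical to r1/r2
```

A command-line front end is installed as `exec/binseq` (subcommands
`encode`, `decode`, `info`, `generate`, `count`, `scan`):

```sh
binseq encode -i R1.fastq.gz -I R2.fastq.gz -o run.vbq --archive
binseq info -i run.vbq
binseq count -i run.vbq -k 8 -t 8 -o kmers.tsv
```

## See also

The methods vignette (`vignettes/binseq-formats.Rmd`) documents the format
layouts, the encoding and policy conventions, the block/index design, the
parallel-processing contract, and known limitations.
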