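---
title: "The partialign execution model: pairing, partitioning and map-reduce alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The partialign execution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partialign)
```

## The model

`partialign` implements the map/reduce execution model that cluster
wrappers place around an unmodified short-read aligner, as a local,
inspectable pipeline in four stages:

1. **Prepare.** Paired-end FASTQ input is turned into a stream of mate
   pairs keyed by normalized read identifier. Two interchangeable
   strategies exist. The *join* strategy reads both files and groups
   records under their shared key, so it tolerates arbitrary record order
   in either file at the cost of holding both in memory; an optional
   variant additionally sorts the output by key. The *interleave* strategy
   streams both files in lockstep, relying on the FASTQ convention that
   mates occupy the same relative position in the two files, verifying key
   equality record by record, and writing one combined line per pair; its
   peak memory is bounded by the streaming chunk size, independent of file
   size. Both strategies produce the same multiset of pairs — that
   equivalence is the pipeline's first testable contract.
2. **Partition.** The prepared stream is cut into contiguous, 0-indexed
   slices, either a fixed number of balanced partitions (sizes differing
   by at most one) or greedily packed to a serialized-byte bound. Because
   the unit of slicing is the prepared record — a whole pair in paired
   mode — pair atomicity holds by construction.
3. **Map.** Each partition becomes one backend invocation. The scheduler
   runs at most `maxConcurrentMappers` invocations simultaneously
   (fork-based waves), and each invocation is told how many threads it may
   use (`threadsPerMapper`; a value above 1 is the *hybrid* two-level
   mode, processes × threads). A failed invocation is retried once, then
   the run aborts with a stage-tagged diagnostic. Fragments are collected
   in partition-index order regardless of completion order.
4. **Reduce (optional).** Per-partition SAM fragments are merged into one
   file: the header of the lowest-index fragment is emitted once, `@PG`
   lines of all fragments are appended deduplicated, fragments with
   conflicting `@SQ` dictionaries refuse to merge, and alignment lines are
   concatenated in partition-index order. Without the reducer, the
   per-partition files `part-<index>.sam` are the output.

The central assumption the whole model rests on is that the aligner
treats reads independently, so any partitioning of the input and any
scheduling of the partitions yields the same set of alignments. That is
exactly true for the built-in deterministic backend and is the tested
invariance; for real aligners it is true of mapping coordinates but not of
mapping-quality scores, which depend on insert-size statistics estimated
per invocation on sample windows of the input — different splits see
different windows. The external cross-check therefore compares
coordinates, not MAPQ.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sortMode` | 0 (join) | 0 join, 1 join + sort-by-key, 2 streaming interleave |
| `partitionCount` | `NA` (auto) | number of mapper work units; `NA` splits by `blockBytes` |
| `blockBytes` | 128 MiB | serialized-bytes bound per partition in auto mode, the conventional distributed-filesystem block size |
| `threadsPerMapper` | 1 | threads per backend invocation; > 1 enables hybrid mode |
| `maxConcurrentMappers` | available processors | simultaneous mapper processes |
| `algorithm` | 0 (MEM) | 0 MEM, 1 backtrack, 2 SW — forwarded to the external backend |
| `useReducer` | `FALSE` | merge per-partition SAMs into one file |
| toy `seedLen` | 20 bp | exact-match seed length of the built-in aligner |
| toy `mapq` | 37 | fixed MAPQ reported for mapped reads |

On a single machine, regular mode (`threadsPerMapper = 1`, more mappers)
uses a fixed core budget more efficiently than hybrid mode, whose extra
threads pay synchronization overhead inside the aligner; hybrid mode is
the right choice only when per-mapper memory (for real aligners, the
resident reference index) limits how many mapper processes fit. The
results are identical either way; only resource usage differs.

## Key normalization

Mate files encode pair membership either as a trailing `/1`, `/2` (legacy
convention) or by differing only in the whitespace-separated comment field
(modern convention). `normalizeKey()` strips the comment first, then
exactly one trailing mate designator. One deliberate consequence: the rule
is idempotent on realistic identifier domains, where designators are never
stacked; an artificial identifier ending in `/1/1` would lose one suffix
per application and is outside the supported domain. Duplicate keys within
one file violate the key-value model and are always a hard error; orphan
keys fail by default, with an opt-in `drop` policy that counts what it
discards (`pairsEmitted + orphans` equals the per-file input count — the
conservation identity).

## The interleaved dialect

One pair per line: the key, mate 1's four FASTQ fields, a separator, mate
2's four fields. Fields are tab-delimited and the separator is the
sentinel `<TAB>::pair::<TAB>`; since FASTQ line fields cannot contain
tabs, the separator cannot arise from content, and the writer additionally
refuses fields containing the bare sentinel core. The token is a versioned
constant of the format. Identifiers containing literal tabs are not
supported by this dialect (the join path handles them).

## Numerical and procedural choices

* **Strict parsing.** A malformed quartet is an error naming the line, a
  sequence/quality length mismatch an error naming the record. Nothing is
  skipped silently.
* **Join output order.** An unsorted key join has no natural order; to
  keep runs reproducible it is fixed to the insertion order of file 1.
  The sorted variant uses radix order (C locale) on keys.
* **Byte-bounded packing** measures records after preparation (the
  interleaved line for a pair), closes a partition when the next record
  would overflow `blockBytes`, but never leaves a partition empty — a
  record larger than the block gets its own partition rather than looping.
* **Toy aligner.** Seeds are the first `seedLen` bases of the read and of
  its reverse complement; every (overlapping) exact seed occurrence where
  the whole read fits is extended by whole-read Hamming comparison; the
  minimal-mismatch placement wins, ties break to the smallest
  `(refName, pos)` with the forward strand preferred on exact ties; reads
  whose best mismatch fraction exceeds 0.25 are unmapped. Scoring is byte
  comparison: `N` matches nothing but `N`, and case matters. Reverse
  strand support exists because the synthetic generator, like real
  paired-end chemistry, puts mate 2 on the opposite strand. The toy
  backend is a test double with a fully documented rule — not a BWA
  substitute: no indels, no quality awareness, fixed MAPQ, TLEN reported
  as 0.
* **Degenerate inputs.** Empty input yields zero partitions, zero
  fragments, and (with the reducer) a valid header-only SAM. An empty
  partition yields a header-only fragment. Merging zero fragments writes
  a minimal `@HD`-only file.
* **Output layout.** `outputPath` is a directory: `part-<index>.sam` per
  mapper, `merged.sam` when reducing, `run-manifest.json` always (options,
  partition manifest with byte sizes, per-stage timings, pairing
  counters).
* **Retry policy.** One retry per failed partition approximates, at local
  scale, the lineage-based task re-execution a cluster scheduler provides;
  a second failure aborts the run rather than degrading the output.

## What the synthetic generator emulates — and what it does not

`generatePairs()` emulates a miniature resequencing experiment: a uniform
random reference, fragments of fixed insert size sampled uniformly, mate 1
forward, mate 2 reverse-complemented from the fragment's far end, per-base
substitutions at a configurable rate, constant high-quality strings, and
ground truth recorded per pair. Orphans, duplicate keys and file-2
shuffling can be injected exactly, so the error paths are testable with
known expected counts. Defaults (10 kb reference, 500 pairs of 100 bp,
insert 300 bp, 1% substitutions) are sized like a toy Illumina panel.

It deliberately does not model indels, quality-dependent error profiles,
insert-size distributions, repeat structure, or chimeric fragments.
Passing tests therefore demonstrate the orchestration contract — pairing
equivalence, pair atomicity, partition/mode invariance, conservation,
byte-exact round trips — on clean data; they say nothing about aligner
accuracy on real libraries, which is the delegated backend's concern.

## Test and verification sizes

The suites run at desk scale by choice: pairing equivalence on 50
randomized datasets of up to 2,000 pairs; partition invariance on 150
pairs across partition counts {1, 2, 3, 7, 16} and concurrency budgets
{1, 4}; mode equivalence across 1, 2 and 4 threads per mapper; the toy
aligner against an exhaustive minimal-Hamming scan on 500 reads with up to
two substitutions placed outside the seed region (keeping the seed intact
by construction, so the exhaustive scan and the seeded search must agree
exactly); 20-file byte-exact round trips including gzip; 100 randomized
option sets for console/builder agreement; and an external cross-check
that indexes the synthetic reference with `bwa index` and compares the
partitioned pipeline's mapping coordinates against one sequential
`bwa mem` run. When a dataset is generated with shuffled mate order — a
join-path stress — the interleave strategy is fed the positionally
ordered rendering of the same dataset, since positional synchrony is its
stated precondition; on synchronized files both strategies must and do
agree.

## Known limitations

* The join strategy holds both mate files in memory; for inputs beyond
  memory, use the interleave strategy (that trade-off is the reason both
  exist).
* The interleave dialect requires tab-free identifier lines.
* Hybrid-mode threads are forwarded to the backend; the toy backend
  accepts and records them but executes single-threaded (its determinism
  is the point).
* SAM output of the toy backend is minimal-but-valid (11 mandatory
  fields); it does not emit optional tags.
* The scheduler's concurrency budget bounds *processes*; it does not
  police what an external aligner does with its thread allowance.
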