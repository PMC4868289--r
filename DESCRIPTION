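Package: partialign
Title: Partitioned Map-Reduce Orchestration for Short-Read Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, cluster-free re-implementation of the
    map/reduce execution model used by big-data wrappers around the
    Burrows-Wheeler Aligner. Paired-end FASTQ files are paired either by an
    in-memory identifier join (optionally sorted by key) or by a streaming
    interleave of positionally matched mates, split into pair-atomic
    partitions, fanned out to a pluggable aligner backend under a
    process-by-thread (regular or hybrid) concurrency budget, and reduced to
    a single valid SAM file. Ships an external-command backend driving a
    real 'bwa' executable and a deterministic seed-and-extend Hamming toy
    aligner plus a synthetic paired-read generator, so the whole pipeline is
    testable hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    parallel,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: bwa (optional, for the external aligner backend)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
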