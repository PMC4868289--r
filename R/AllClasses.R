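#' @import methods
NULL

#' FastqReads: a column-parallel set of FASTQ records
#'
#' Holds an ordered set of FASTQ reads as four parallel character vectors:
#' the identifier line (without the leading \code{@}), the bases, the
#' \code{+}-separator payload (text after the \code{+}, possibly empty) and
#' the ASCII-encoded per-base qualities. Qualities and the separator payload
#' are carried verbatim and never reinterpreted; base case is preserved.
#'
#' @slot id character, identifier lines without the leading \code{@}.
#' @slot seq character, nucleotide strings over \code{A,C,G,T,N} (case kept).
#' @slot plus character, \code{+}-line payloads (may be empty strings).
#' @slot qual character, quality strings, same length as \code{seq} per read.
#'
#' @exportClass FastqReads
setClass("FastqReads",
  representation(id = "character", seq = "character",
                 plus = "character", qual = "character"))

setValidity("FastqReads", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@plus) != n ||
      length(object@qual) != n)
    return("id, seq, plus and qual must have equal length")
  if (n == 0L) return(TRUE)
  if (any(!nzchar(object@id)))
    return("read identifiers must be non-empty")
  if (any(grepl("\n", object@id, fixed = TRUE)))
    return("read identifiers must not contain newlines")
  bad <- nchar(object@seq) != nchar(object@qual)
  if (any(bad))
    return(sprintf("sequence/quality length mismatch in record %d",
                   which(bad)[1L]))
  TRUE
})

#' Prepared (keyed) read streams fed to the partitioner
#'
#' Virtual parent of the two record streams the map phase accepts:
#' \linkS4class{PairedReads} (paired-end, one normalized key per mate pair)
#' and \linkS4class{KeyedReads} (single-end, one key per read).
#'
#' @exportClass PreparedReads
setClass("PreparedReads", representation("VIRTUAL"))

#' KeyedReads: single-end reads with their normalized pairing keys
#'
#' @slot key character, normalized identifier of each read.
#' @slot id,seq,plus,qual character, the FASTQ fields (see
#'   \linkS4class{FastqReads}).
#'
#' @exportClass KeyedReads
setClass("KeyedReads", contains = "PreparedReads",
  representation(key = "character", id = "character", seq = "character",
                 plus = "character", qual = "character"))

setValidity("KeyedReads", function(object) {
  n <- length(object@key)
  lens <- c(length(object@id), length(object@seq), length(object@plus),
            length(object@qual))
  if (any(lens != n)) return("all field vectors must share one length")
  if (n && !identical(object@key, normalizeKey(object@id)))
    return("key must equal normalizeKey(id) for every read")
  TRUE
})

#' PairedReads: mate pairs joined under one normalized key
#'
#' One row per proper pair: the shared normalized key plus the four FASTQ
#' fields of each mate. The invariant \code{normalizeKey(id1) ==
#' normalizeKey(id2) == key} holds for every pair.
#'
#' @slot key character, normalized pair keys.
#' @slot id1,seq1,plus1,qual1 character, mate-1 FASTQ fields.
#' @slot id2,seq2,plus2,qual2 character, mate-2 FASTQ fields.
#'
#' @exportClass PairedReads
setClass("PairedReads", contains = "PreparedReads",
  representation(key = "character",
                 id1 = "character", seq1 = "character",
                 plus1 = "character", qual1 = "character",
                 id2 = "character", seq2 = "character",
                 plus2 = "character", qual2 = "character"))

setValidity("PairedReads", function(object) {
  n <- length(object@key)
  lens <- vapply(c("id1", "seq1", "plus1", "qual1",
                   "id2", "seq2", "plus2", "qual2"),
                 function(s) length(slot(object, s)), integer(1))
  if (any(lens != n)) return("all field vectors must share one length")
  if (n == 0L) return(TRUE)
  if (!identical(object@key, normalizeKey(object@id1)) ||
      !identical(object@key, normalizeKey(object@id2)))
    return("both mates must normalize to the pair key")
  if (any(nchar(object@seq1) != nchar(object@qual1)) ||
      any(nchar(object@seq2) != nchar(object@qual2)))
    return("sequence/quality length mismatch")
  TRUE
})

#' PairingReport: accounting of a pairing pass
#'
#' @slot pairsEmitted integer, proper pairs emitted.
#' @slot orphansFile1 integer, reads of file 1 whose key had no mate.
#' @slot orphansFile2 integer, reads of file 2 whose key had no mate.
#' @slot duplicateKeys integer, duplicated keys detected within one file.
#'
#' @exportClass PairingReport
setClass("PairingReport",
  representation(pairsEmitted = "integer", orphansFile1 = "integer",
                 orphansFile2 = "integer", duplicateKeys = "integer"),
  prototype(pairsEmitted = 0L, orphansFile1 = 0L, orphansFile2 = 0L,
            duplicateKeys = 0L))

setValidity("PairingReport", function(object) {
  v <- c(object@pairsEmitted, object@orphansFile1, object@orphansFile2,
         object@duplicateKeys)
  if (any(is.na(v)) || any(v < 0L)) return("all counters must be >= 0")
  TRUE
})

#' ReadPartition: one mapper work unit
#'
#' A contiguous, indexed slice of the prepared record stream. Pairs are
#' never split across partitions: the unit of slicing is the prepared
#' record (a whole pair in paired mode).
#'
#' @slot index integer, 0-based partition ordinal.
#' @slot records a \linkS4class{PreparedReads} slice.
#'
#' @exportClass ReadPartition
setClass("ReadPartition",
  representation(index = "integer", records = "PreparedReads"))

setValidity("ReadPartition", function(object) {
  if (length(object@index) != 1L || is.na(object@index) || object@index < 0L)
    return("index must be a single non-negative integer")
  TRUE
})

#' SamFragment: the SAM output of one mapper
#'
#' @slot partitionIndex integer, the originating partition's ordinal.
#' @slot header character, header lines (each starting \code{@}).
#' @slot alignments character, tab-separated alignment lines (>= 11 fields).
#'
#' @exportClass SamFragment
setClass("SamFragment",
  representation(partitionIndex = "integer", header = "character",
                 alignments = "character"))

setValidity("SamFragment", function(object) {
  if (length(object@partitionIndex) != 1L || object@partitionIndex < 0L)
    return("partitionIndex must be a single non-negative integer")
  if (length(object@header) && any(substr(object@header, 1L, 1L) != "@"))
    return("every header line must start with '@'")
  if (length(object@alignments)) {
    nf <- lengths(strsplit(object@alignments, "\t", fixed = TRUE))
    if (any(nf < 11L))
      return(sprintf("alignment line %d has fewer than 11 fields",
                     which(nf < 11L)[1L]))
  }
  TRUE
})

#' RunOptions: the full option set governing a run
#'
#' Mirrors the classic option surface of distributed BWA wrappers: optional
#' reducer, partition count (NA = split by serialized block size), pairing
#' strategy code (0 join, 1 join+sort-by-key, 2 streaming interleave),
#' threads per mapper (hybrid mode when > 1), algorithm code (0 MEM,
#' 1 backtrack, 2 SW), paired/single mode, index and input/output paths,
#' and the local concurrency budget.
#'
#' @exportClass RunOptions
setClass("RunOptions",
  representation(useReducer = "logical", partitionCount = "integer",
                 sortMode = "integer", threadsPerMapper = "integer",
                 algorithm = "integer", paired = "logical",
                 indexPath = "character", inputPath = "character",
                 inputPath2 = "character", outputPath = "character",
                 maxConcurrentMappers = "integer", blockBytes = "numeric"),
  prototype(useReducer = FALSE, partitionCount = NA_integer_,
            sortMode = 0L, threadsPerMapper = 1L, algorithm = 0L,
            paired = TRUE, inputPath2 = NA_character_,
            maxConcurrentMappers = 1L, blockBytes = 128 * 1024^2))

setValidity("RunOptions", function(object) {
  scalar <- function(x) length(x) == 1L
  if (!all(vapply(slotNames(object), function(s) scalar(slot(object, s)),
                  logical(1))))
    return("all options must be scalars")
  if (!object@sortMode %in% 0:2)
    return("sortMode must be 0 (join), 1 (join+sort) or 2 (interleave)")
  if (!object@algorithm %in% 0:2)
    return("algorithm must be 0 (MEM), 1 (backtrack) or 2 (SW)")
  if (is.na(object@threadsPerMapper) || object@threadsPerMapper < 1L)
    return("threadsPerMapper must be >= 1")
  if (is.na(object@maxConcurrentMappers) || object@maxConcurrentMappers < 1L)
    return("maxConcurrentMappers must be >= 1")
  if (!is.na(object@partitionCount) && object@partitionCount < 1L)
    return("partitionCount must be >= 1 when given")
  if (is.na(object@blockBytes) || object@blockBytes < 1)
    return("blockBytes must be >= 1")
  if (!nzchar(object@indexPath)) return("indexPath is mandatory")
  if (!nzchar(object@inputPath)) return("inputPath is mandatory")
  if (!nzchar(object@outputPath)) return("outputPath is mandatory")
  if (object@paired &&
      (is.na(object@inputPath2) || !nzchar(object@inputPath2)))
    return("paired mode requires inputPath2")
  TRUE
})

#' RunResult: summary of a completed run
#'
#' @slot fragmentsWritten integer, per-partition SAM files produced.
#' @slot pairsAligned integer, prepared records (pairs in paired mode) that
#'   went through the map phase.
#' @slot mergedOutput character, path of the merged SAM (NA if no reducer).
#' @slot stageLog data.frame with columns \code{stage} and \code{seconds}.
#'
#' @exportClass RunResult
setClass("RunResult",
  representation(fragmentsWritten = "integer", pairsAligned = "integer",
                 mergedOutput = "character", stageLog = "data.frame"))

#' Aligner backends
#'
#' \code{AlignerBackend} is the virtual contract the orchestrator programs
#' against: a backend turns one \linkS4class{BackendRequest} into one
#' \linkS4class{SamFragment} via \code{\link{runBackend}}.
#'
#' \code{ToyBackend} is the built-in deterministic seed-and-extend Hamming
#' aligner used for hermetic testing: it is a test double with a documented
#' scoring rule, not a BWA equivalent. \code{ExternalBackend} shells out to
#' a real aligner executable (\code{bwa} conventions: \code{mem},
#' \code{aln}+\code{sampe}/\code{samse}, \code{bwasw}).
#'
#' @slot reference named character, reference sequences (toy backend).
#' @slot seedLen integer, exact-match seed length (toy backend).
#' @slot mapq integer, fixed mapping quality reported for mapped reads
#'   (toy backend).
#'
#' @exportClass AlignerBackend
#' @aliases ToyBackend-class ExternalBackend-class
setClass("AlignerBackend", representation("VIRTUAL"))

#' @exportClass ToyBackend
setClass("ToyBackend", contains = "AlignerBackend",
  representation(reference = "character", seedLen = "integer",
                 mapq = "integer"),
  prototype(seedLen = 20L, mapq = 37L))

setValidity("ToyBackend", function(object) {
  if (!length(object@reference)) return("reference must be non-empty")
  if (is.null(names(object@reference)) || any(!nzchar(names(object@reference))))
    return("reference sequences must be named")
  if (object@seedLen < 1L) return("seedLen must be >= 1")
  TRUE
})

#' @exportClass ExternalBackend
#' @slot executable character, the aligner executable (default "bwa").
#' @slot timeout numeric, per-invocation timeout in seconds.
#' @rdname AlignerBackend-class
setClass("ExternalBackend", contains = "AlignerBackend",
  representation(executable = "character", timeout = "numeric"),
  prototype(executable = "bwa", timeout = 3600))

#' BackendRequest: one mapper invocation
#'
#' @slot algorithm character, one of \code{"MEM"}, \code{"BACKTRACK"},
#'   \code{"SW"}.
#' @slot paired logical, paired-end mode.
#' @slot threads integer, threads the backend may use (hybrid mode when > 1).
#' @slot indexRef character, index prefix (external) or FASTA path (toy).
#' @slot partition the \linkS4class{ReadPartition} to align.
#' @slot workdir character, scratch directory; the per-partition SAM file is
#'   persisted here as \code{part-<index>.sam}.
#'
#' @exportClass BackendRequest
setClass("BackendRequest",
  representation(algorithm = "character", paired = "logical",
                 threads = "integer", indexRef = "character",
                 partition = "ReadPartition", workdir = "character"))

setValidity("BackendRequest", function(object) {
  if (!object@algorithm %in% c("MEM", "BACKTRACK", "SW"))
    return("algorithm must be one of MEM, BACKTRACK, SW")
  if (length(object@threads) != 1L || is.na(object@threads) ||
      object@threads < 1L)
    return("threads must be a single integer >= 1")
  TRUE
})

#' FixtureSpec: parameters of the synthetic paired-read generator
#'
#' The generator emulates a small resequencing experiment: a uniform random
#' reference, mate pairs sampled at a fixed insert size with mate 2 on the
#' reverse strand, per-base substitution noise, and optional injected
#' faults (orphans, duplicate keys, file-2 shuffling) to exercise the
#' pairing error paths. All outputs are pure functions of the spec.
#'
#' @slot refLength integer, reference length in bases.
#' @slot nPairs integer, proper pairs to generate.
#' @slot readLength integer, read length in bases.
#' @slot substitutionRate numeric in [0,1], per-base substitution probability.
#' @slot insertSize integer, outer fragment length (mate-2 end offset).
#' @slot orphanCount integer, reads stranded deliberately (alternating files).
#' @slot duplicateKeyCount integer, deliberate key collisions within file 1.
#' @slot shuffleFile2 logical, permute file-2 record order.
#' @slot seed integer, RNG seed; fixed seed implies byte-identical outputs.
#'
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(refLength = "integer", nPairs = "integer",
                 readLength = "integer", substitutionRate = "numeric",
                 insertSize = "integer", orphanCount = "integer",
                 duplicateKeyCount = "integer", shuffleFile2 = "logical",
                 seed = "integer"),
  prototype(refLength = 10000L, nPairs = 500L, readLength = 100L,
            substitutionRate = 0.01, insertSize = 300L, orphanCount = 0L,
            duplicateKeyCount = 0L, shuffleFile2 = FALSE, seed = 1L))

setValidity("FixtureSpec", function(object) {
  if (object@readLength > object@refLength)
    return("readLength must not exceed refLength")
  if (object@substitutionRate < 0 || object@substitutionRate > 1)
    return("substitutionRate must lie in [0, 1]")
  if (object@insertSize < object@readLength)
    return("insertSize must be >= readLength")
  if (object@insertSize > object@refLength)
    return("insertSize must not exceed refLength")
  if (object@nPairs < 0L || object@orphanCount < 0L ||
      object@duplicateKeyCount < 0L)
    return("counts must be non-negative")
  TRUE
})
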