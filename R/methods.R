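# length, subset, accessor and show methods for the core containers.

#' Accessors for partialign containers
#'
#' Small read-only accessors so user code never touches slots directly:
#' \code{readIds}, \code{readBases}, \code{plusLines}, \code{readQualities}
#' for FASTQ field vectors; \code{pairKeys} for normalized keys;
#' \code{recordBytes} for per-record serialized size; \code{partitionIndex}
#' and \code{partitionRecords} for partitions; \code{samHeader} and
#' \code{samAlignments} for SAM fragments; \code{pairsEmitted} and
#' \code{orphanCounts} for pairing reports.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
readIds <- function(x) {
  if (is(x, "FastqReads") || is(x, "KeyedReads")) x@id
  else stop("no single identifier vector for class ", class(x))
}

#' @rdname accessors
#' @export
readBases <- function(x) {
  if (is(x, "FastqReads") || is(x, "KeyedReads")) x@seq
  else stop("no single base vector for class ", class(x))
}

#' @rdname accessors
#' @export
plusLines <- function(x) x@plus

#' @rdname accessors
#' @export
readQualities <- function(x) x@qual

#' @export
setMethod("length", "FastqReads", function(x) length(x@id))

#' @export
setMethod("length", "KeyedReads", function(x) length(x@key))

#' @export
setMethod("length", "PairedReads", function(x) length(x@key))

#' @export
setMethod("length", "ReadPartition", function(x) length(x@records))

.subsetSlots <- function(x, i) {
  for (s in slotNames(x)) slot(x, s) <- slot(x, s)[i]
  validObject(x)
  x
}

#' @export
setMethod("[", "FastqReads", function(x, i, j, ..., drop = TRUE)
  .subsetSlots(x, i))

#' @export
setMethod("[", "KeyedReads", function(x, i, j, ..., drop = TRUE)
  .subsetSlots(x, i))

#' @export
setMethod("[", "PairedReads", function(x, i, j, ..., drop = TRUE)
  .subsetSlots(x, i))

setMethod("pairKeys", "KeyedReads", function(x) x@key)
setMethod("pairKeys", "PairedReads", function(x) x@key)

# Serialized size in bytes of each record: the 4 FASTQ lines (+ newlines)
# for single-end reads, the interleaved pair line (+ newline) for pairs.
setMethod("recordBytes", "KeyedReads", function(x) {
  if (!length(x)) return(numeric(0))
  nchar(x@id, type = "bytes") + nchar(x@seq, type = "bytes") +
    nchar(x@plus, type = "bytes") + nchar(x@qual, type = "bytes") + 6L
})

setMethod("recordBytes", "PairedReads", function(x) {
  if (!length(x)) return(numeric(0))
  nchar(interleaveLines(x), type = "bytes") + 1L
})

setMethod("partitionIndex", "ReadPartition", function(x) x@index)
setMethod("partitionRecords", "ReadPartition", function(x) x@records)
setMethod("samHeader", "SamFragment", function(x) x@header)
setMethod("samAlignments", "SamFragment", function(x) x@alignments)
setMethod("partitionIndex", "SamFragment", function(x) x@partitionIndex)
setMethod("pairsEmitted", "PairingReport", function(x) x@pairsEmitted)
setMethod("orphanCounts", "PairingReport", function(x)
  c(file1 = x@orphansFile1, file2 = x@orphansFile2))

#' @export
setMethod("show", "FastqReads", function(object) {
  cat("FastqReads with", length(object), "reads\n")
  if (length(object))
    cat("  first: @", object@id[1L], " (", nchar(object@seq[1L]),
        " bp)\n", sep = "")
})

#' @export
setMethod("show", "PairedReads", function(object) {
  cat("PairedReads with", length(object), "pairs\n")
  if (length(object))
    cat("  first key:", object@key[1L], "\n")
})

#' @export
setMethod("show", "KeyedReads", function(object) {
  cat("KeyedReads with", length(object), "single-end reads\n")
})

#' @export
setMethod("show", "ReadPartition", function(object) {
  cat("ReadPartition #", object@index, " holding ", length(object),
      " records\n", sep = "")
})

#' @export
setMethod("show", "SamFragment", function(object) {
  cat("SamFragment from partition", object@partitionIndex, "with",
      length(object@header), "header and", length(object@alignments),
      "alignment lines\n")
})

#' @export
setMethod("show", "PairingReport", function(object) {
  cat("PairingReport: ", object@pairsEmitted, " pairs, orphans ",
      object@orphansFile1, "/", object@orphansFile2, ", duplicates ",
      object@duplicateKeys, "\n", sep = "")
})

#' @export
setMethod("show", "RunOptions", function(object) {
  cat("RunOptions:\n")
  cat("  mode      :", if (object@paired) "paired-end" else "single-end", "\n")
  cat("  strategy  :", c("join", "join+sortByKey", "interleave")[
    object@sortMode + 1L], "\n")
  cat("  algorithm :", c("MEM", "BACKTRACK", "SW")[object@algorithm + 1L], "\n")
  cat("  partitions:", if (is.na(object@partitionCount)) "auto (by bytes)"
      else object@partitionCount, "\n")
  cat("  threads/mapper:", object@threadsPerMapper,
      if (object@threadsPerMapper > 1L) "(hybrid mode)" else "", "\n")
  cat("  reducer   :", object@useReducer, "\n")
})

#' @export
setMethod("show", "RunResult", function(object) {
  cat("RunResult:", object@fragmentsWritten, "fragment(s),",
      object@pairsAligned, "record(s) aligned\n")
  if (!is.na(object@mergedOutput))
    cat("  merged SAM:", object@mergedOutput, "\n")
})

#' @export
setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec:", object@nPairs, "pairs of", object@readLength,
      "bp from a", object@refLength, "bp reference (seed",
      object@seed, ")\n")
})
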