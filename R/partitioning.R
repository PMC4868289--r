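# Splitting the prepared record stream into mapper work units. Slices are
# contiguous and in input order, so concatenating all partitions reproduces
# the stream exactly, and a pair can never straddle two partitions because
# the unit of slicing is the prepared record (a whole pair in paired mode).

.newPartitions <- function(records, starts, ends) {
  if (!length(starts)) return(list())
  lapply(seq_along(starts), function(i)
    new("ReadPartition", index = i - 1L,
        records = records[starts[i]:ends[i]]))
}

#' Split records into a fixed number of balanced partitions
#'
#' Produces \code{min(numPartitions, n)} non-empty contiguous partitions
#' whose sizes differ by at most one (the first \code{n %% p} partitions
#' take the extra record). Empty input yields zero partitions.
#'
#' @param records a \linkS4class{PreparedReads} stream.
#' @param numPartitions target number of partitions (>= 1).
#' @return a list of \linkS4class{ReadPartition}, indices consecutive from 0.
#' @export
makePartitions <- function(records, numPartitions) {
  if (length(numPartitions) != 1L || is.na(numPartitions) ||
      numPartitions < 1L)
    stop("numPartitions must be a single integer >= 1")
  numPartitions <- as.integer(numPartitions)
  n <- length(records)
  if (n == 0L) return(list())
  p <- min(numPartitions, n)
  base <- n %/% p
  sizes <- rep.int(base, p) + (seq_len(p) <= n %% p)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  .newPartitions(records, starts, ends)
}

#' Split records into partitions of bounded serialized size
#'
#' Greedy contiguous packing in input order: a partition is closed when
#' adding the next record would exceed \code{blockBytes}, unless the
#' partition is still empty — so every record is placed and a record larger
#' than the block gets a partition of its own. Record size is its
#' serialized byte length (4-line FASTQ for single-end records, the
#' interleaved pair line for pairs).
#'
#' @param records a \linkS4class{PreparedReads} stream.
#' @param blockBytes partition size bound in bytes (>= 1); default 128 MiB,
#'   the conventional distributed-filesystem block size.
#' @return a list of \linkS4class{ReadPartition}.
#' @export
makePartitionsByBytes <- function(records, blockBytes = 128 * 1024^2) {
  if (length(blockBytes) != 1L || is.na(blockBytes) || blockBytes < 1)
    stop("blockBytes must be a single value >= 1")
  n <- length(records)
  if (n == 0L) return(list())
  bytes <- recordBytes(records)
  starts <- 1L
  acc <- 0
  for (i in seq_len(n)) {
    if (acc > 0 && acc + bytes[i] > blockBytes) {
      starts <- c(starts, i)
      acc <- 0
    }
    acc <- acc + bytes[i]
  }
  ends <- c(starts[-1L] - 1L, n)
  .newPartitions(records, starts, ends)
}

# Partition manifest used in the run manifest and logs.
partitionManifest <- function(partitions) {
  data.frame(
    index = vapply(partitions, partitionIndex, integer(1)),
    records = vapply(partitions, length, integer(1)),
    bytes = vapply(partitions, function(p)
      sum(recordBytes(partitionRecords(p))), numeric(1)))
}
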