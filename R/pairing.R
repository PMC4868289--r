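# Paired-end record preparation: the in-memory identifier join (optionally
# sorted by key) and the streaming positional interleave. Both produce the
# same logical stream of mate pairs; the join tolerates arbitrary file-2
# order at the cost of memory, the interleave streams with bounded memory
# but requires the standard FASTQ convention that mates sit at the same
# relative position in both files.

# Separator between the two mates' fields on one interleaved line. Fields
# within a mate are tab-separated; the sentinel core "::pair::" is flanked
# by tabs so it can never arise from field content (FASTQ line fields
# contain no tabs). Versioned config constant: change only with the format.
PAIR_SEPARATOR <- "\t::pair::\t"
.PAIR_SEP_CORE <- "::pair::"

PairedReads <- function(key = character(),
                        id1 = character(), seq1 = character(),
                        plus1 = character(), qual1 = character(),
                        id2 = character(), seq2 = character(),
                        plus2 = character(), qual2 = character()) {
  new("PairedReads", key = key, id1 = id1, seq1 = seq1, plus1 = plus1,
      qual1 = qual1, id2 = id2, seq2 = seq2, plus2 = plus2, qual2 = qual2)
}

KeyedReads <- function(key, id, seq, plus, qual)
  new("KeyedReads", key = key, id = id, seq = seq, plus = plus, qual = qual)

.checkDuplicates <- function(keys, label) {
  dup <- unique(keys[duplicated(keys)])
  if (length(dup))
    stop("duplicate read identifiers in ", label, " (keys must be unique ",
         "per file): ", paste(utils::head(dup, 10L), collapse = ", "),
         if (length(dup) > 10L) ", ..." else "")
  invisible(length(dup))
}

#' Pair two read sets by normalized identifier (join strategy)
#'
#' Groups the records of the two mate files under their normalized keys and
#' emits one pair per key present in both inputs — the in-memory equivalent
#' of a key join, so file 2 may be in any order. With \code{sort = FALSE}
#' the output order is the insertion order of file 1 (deterministic without
#' paying the sort cost); with \code{sort = TRUE} keys are emitted in
#' nondecreasing lexicographic order (C locale).
#'
#' @param reads1,reads2 \linkS4class{FastqReads} for mate 1 and mate 2.
#' @param sort logical, sort the emitted pairs by key.
#' @param orphanPolicy \code{"fail"} (default: any unmatched key is an
#'   error) or \code{"drop"} (unmatched reads are dropped and counted).
#' @return a list with elements \code{pairs} (\linkS4class{PairedReads})
#'   and \code{report} (\linkS4class{PairingReport}).
#' @export
pairJoin <- function(reads1, reads2, sort = FALSE,
                     orphanPolicy = c("fail", "drop")) {
  orphanPolicy <- match.arg(orphanPolicy)
  stopifnot(is(reads1, "FastqReads"), is(reads2, "FastqReads"))
  k1 <- if (length(reads1)) normalizeKey(reads1@id) else character(0)
  k2 <- if (length(reads2)) normalizeKey(reads2@id) else character(0)
  .checkDuplicates(k1, "file 1")
  .checkDuplicates(k2, "file 2")
  pos2 <- match(k1, k2)
  matched1 <- !is.na(pos2)
  orphans1 <- sum(!matched1)
  orphans2 <- length(k2) - sum(matched1)
  if ((orphans1 || orphans2) && orphanPolicy == "fail") {
    off <- c(k1[!matched1], setdiff(k2, k1))
    stop("unmatched (orphan) read identifiers between mate files: ",
         paste(utils::head(off, 10L), collapse = ", "),
         if (length(off) > 10L) ", ..." else "")
  }
  i1 <- which(matched1)
  i2 <- pos2[matched1]
  if (sort) {
    o <- order(k1[i1], method = "radix")
    i1 <- i1[o]; i2 <- i2[o]
  }
  pairs <- PairedReads(
    key = k1[i1],
    id1 = reads1@id[i1], seq1 = reads1@seq[i1],
    plus1 = reads1@plus[i1], qual1 = reads1@qual[i1],
    id2 = reads2@id[i2], seq2 = reads2@seq[i2],
    plus2 = reads2@plus[i2], qual2 = reads2@qual[i2])
  report <- new("PairingReport", pairsEmitted = length(i1),
                orphansFile1 = orphans1, orphansFile2 = orphans2,
                duplicateKeys = 0L)
  list(pairs = pairs, report = report)
}

# Serialize pairs to interleaved lines: key, tab, mate-1 fields, separator,
# mate-2 fields.
interleaveLines <- function(pairs) {
  stopifnot(is(pairs, "PairedReads"))
  if (!length(pairs)) return(character(0))
  fields <- c(pairs@key, pairs@id1, pairs@seq1, pairs@plus1, pairs@qual1,
              pairs@id2, pairs@seq2, pairs@plus2, pairs@qual2)
  if (any(grepl(.PAIR_SEP_CORE, fields, fixed = TRUE)))
    stop("a FASTQ field contains the reserved pair-separator token '",
         .PAIR_SEP_CORE, "' and cannot be interleaved")
  paste0(pairs@key, "\t",
         pairs@id1, "\t", pairs@seq1, "\t", pairs@plus1, "\t", pairs@qual1,
         PAIR_SEPARATOR,
         pairs@id2, "\t", pairs@seq2, "\t", pairs@plus2, "\t", pairs@qual2)
}

#' Merge positionally matched mate files into an interleaved pair file
#'
#' Streaming preprocessing pass (the low-memory alternative to
#' \code{\link{pairJoin}}): co-iterates the two FASTQ files in fixed-size
#' chunks, verifies that the records at the same relative position
#' normalize to the same key, and writes one interleaved line per pair.
#' Peak memory is bounded by the chunk size, independent of file size.
#'
#' @param path1,path2 mate FASTQ files (plain or gzip), mates in the same
#'   relative order.
#' @param outPath output path for the interleaved pair file (\code{.gz}
#'   compresses).
#' @param chunkRecords records held in memory per file at a time.
#' @return a \linkS4class{PairingReport}, invisibly.
#' @export
pairInterleave <- function(path1, path2, outPath, chunkRecords = 5000L) {
  con1 <- .openInput(path1)
  on.exit(close(con1), add = TRUE)
  con2 <- .openInput(path2)
  on.exit(close(con2), add = TRUE)
  out <- .openOutput(outPath)
  on.exit(close(out), add = TRUE)
  nl <- 4L * as.integer(chunkRecords)
  emitted <- 0L
  repeat {
    l1 <- readLines(con1, n = nl, warn = FALSE)
    l2 <- readLines(con2, n = nl, warn = FALSE)
    if (!length(l1) && !length(l2)) break
    r1 <- parseFastqLines(l1)
    r2 <- parseFastqLines(l2)
    if (length(r1) != length(r2))
      stop("mate files have unequal record counts (files are not ",
           "mate-synchronized): difference first seen after record ",
           emitted + min(length(r1), length(r2)))
    k1 <- normalizeKey(r1@id)
    k2 <- normalizeKey(r2@id)
    bad <- which(k1 != k2)
    if (length(bad))
      stop("mate files are not mate-synchronized at record ",
           emitted + bad[1L], ": '", k1[bad[1L]], "' vs '", k2[bad[1L]], "'")
    pairs <- PairedReads(
      key = k1, id1 = r1@id, seq1 = r1@seq, plus1 = r1@plus, qual1 = r1@qual,
      id2 = r2@id, seq2 = r2@seq, plus2 = r2@plus, qual2 = r2@qual)
    writeLines(interleaveLines(pairs), out)
    emitted <- emitted + length(pairs)
  }
  invisible(new("PairingReport", pairsEmitted = emitted,
                orphansFile1 = 0L, orphansFile2 = 0L, duplicateKeys = 0L))
}

#' Read an interleaved pair file back into PairedReads
#'
#' Exact inverse of the serialization performed by
#' \code{\link{pairInterleave}}; order is preserved.
#'
#' @param path interleaved pair file (plain or gzip).
#' @return a \linkS4class{PairedReads} in file order.
#' @export
readInterleaved <- function(path) {
  con <- .openInput(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) return(PairedReads())
  halves <- strsplit(lines, PAIR_SEPARATOR, fixed = TRUE)
  bad <- which(lengths(halves) != 2L)
  if (length(bad))
    stop("interleaved file line ", bad[1L], " does not contain exactly one ",
         "pair separator")
  left <- strsplit(vapply(halves, `[[`, character(1), 1L), "\t", fixed = TRUE)
  right <- strsplit(vapply(halves, `[[`, character(1), 2L), "\t", fixed = TRUE)
  bad <- which(lengths(left) != 5L | lengths(right) != 4L)
  if (length(bad))
    stop("interleaved file line ", bad[1L], " has a malformed field layout")
  f <- function(lst, i) vapply(lst, `[[`, character(1), i)
  PairedReads(key = f(left, 1L),
              id1 = f(left, 2L), seq1 = f(left, 3L),
              plus1 = f(left, 4L), qual1 = f(left, 5L),
              id2 = f(right, 1L), seq2 = f(right, 2L),
              plus2 = f(right, 3L), qual2 = f(right, 4L))
}

#' Wrap single-end reads with their pairing keys
#'
#' Identity wrapping: no pairing is performed, each read keeps its position
#' and gains the normalized key derived from its identifier.
#'
#' @param reads a \linkS4class{FastqReads}.
#' @return a \linkS4class{KeyedReads} in the same order.
#' @export
prepareSingleEnd <- function(reads) {
  stopifnot(is(reads, "FastqReads"))
  key <- if (length(reads)) normalizeKey(reads@id) else character(0)
  KeyedReads(key = key, id = reads@id, seq = reads@seq,
             plus = reads@plus, qual = reads@qual)
}
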