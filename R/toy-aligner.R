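# Built-in deterministic seed-and-extend Hamming aligner and its backend.
#
# This is a hermetic test double for the delegated aligner layer: exact
# seed match, whole-read Hamming extension, minimal-mismatch placement with
# a fixed tie-break. It has a documented scoring rule and is never a BWA
# equivalent — no indels, no quality use, fixed MAPQ.

# Reverse complement preserving case; N maps to N.
revComp <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

.hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# All (possibly overlapping) exact occurrences of pattern in text, 1-based.
.findAllFixed <- function(pattern, text) {
  res <- integer(0)
  from <- 1L
  n <- nchar(text)
  while (from <= n) {
    m <- regexpr(pattern, substring(text, from), fixed = TRUE)
    if (m == -1L) break
    pos <- from + as.integer(m) - 1L
    res <- c(res, pos)
    from <- pos + 1L
  }
  res
}

#' Align one read against a small reference by seed-and-extend Hamming
#'
#' Exact-matches the first \code{seedLen} bases of the read (and of its
#' reverse complement) at every reference offset; every seed hit where the
#' whole read fits is extended by full-length Hamming comparison. The hit
#' with the fewest mismatches wins; ties break to the smallest
#' \code{(refName, pos)}, and to the forward strand between equal
#' forward/reverse placements. The read is unmapped when no seed hits or
#' when the best mismatch fraction exceeds \code{maxMismatchFrac}.
#'
#' @param seq a single read sequence.
#' @param reference named character vector of reference sequences.
#' @param seedLen exact-match seed length (must not exceed the read length).
#' @param maxMismatchFrac maximal tolerated mismatch fraction (default 0.25).
#' @return a list (a ToyHit): \code{refName}, \code{pos} (1-based leftmost,
#'   \code{NA} if unmapped), \code{mismatches}, \code{strand} (\code{"+"} or
#'   \code{"-"}), \code{mapped}.
#' @export
toyAlign <- function(seq, reference, seedLen = 20L, maxMismatchFrac = 0.25) {
  stopifnot(length(seq) == 1L, length(reference) >= 1L)
  len <- nchar(seq)
  if (len < seedLen)
    stop("read (", len, " bp) is shorter than the seed length (", seedLen,
         ")")
  unmappedHit <- list(refName = NA_character_, pos = NA_integer_,
                      mismatches = NA_integer_, strand = NA_character_,
                      mapped = FALSE)
  best <- NULL
  refNames <- sort(names(reference), method = "radix")
  for (strand in c("+", "-")) {
    query <- if (strand == "+") seq else revComp(seq)
    seed <- substr(query, 1L, seedLen)
    for (rn in refNames) {
      refseq <- reference[[rn]]
      hits <- .findAllFixed(seed, refseq)
      hits <- hits[hits + len - 1L <= nchar(refseq)]
      for (pos in hits) {
        mm <- .hamming(query, substr(refseq, pos, pos + len - 1L))
        if (is.null(best) || mm < best$mismatches) {
          best <- list(refName = rn, pos = as.integer(pos),
                       mismatches = as.integer(mm), strand = strand,
                       mapped = TRUE)
        }
        # equal-score hits: keep the earlier (refName, pos); strands are
        # evaluated forward first, so a reverse tie never displaces forward
      }
    }
  }
  if (is.null(best) || best$mismatches / len > maxMismatchFrac)
    return(unmappedHit)
  best
}

# SAM FLAG bits.
.FLAG_PAIRED <- 0x1L
.FLAG_UNMAPPED <- 0x4L
.FLAG_MATE_UNMAPPED <- 0x8L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_FIRST <- 0x40L
.FLAG_SECOND <- 0x80L

#' Render one toy-aligner hit as a SAM alignment line
#'
#' Produces a syntactically valid 11-field SAM record. FLAG encodes the
#' paired / mate-number / strand / unmapped bits; POS is 1-based; CIGAR is
#' a full-length match (\code{<len>M}) for mapped reads and \code{*}
#' otherwise; MAPQ is the backend's fixed constant for mapped reads and 0
#' for unmapped. Reverse-strand reads store the reverse-complemented
#' sequence and reversed qualities, per SAM convention. TLEN is reported
#' as 0 (the toy aligner does not model insert sizes).
#'
#' @param id read identifier (QNAME is its normalized key).
#' @param seq,qual the read's bases and qualities as read from FASTQ.
#' @param hit a hit from \code{\link{toyAlign}}.
#' @param paired logical, whether the read belongs to a pair.
#' @param mateNumber 1 or 2 (ignored for single-end).
#' @param mateHit the mate's hit (for RNEXT/PNEXT and mate flags), or NULL.
#' @param mapq fixed mapping quality for mapped reads.
#' @return a single SAM alignment line.
#' @export
toyHitToSam <- function(id, seq, qual, hit, paired = FALSE, mateNumber = 1L,
                        mateHit = NULL, mapq = 37L) {
  flag <- 0L
  if (paired) {
    flag <- flag + .FLAG_PAIRED +
      (if (mateNumber == 1L) .FLAG_FIRST else .FLAG_SECOND)
    if (!is.null(mateHit)) {
      if (!mateHit$mapped) flag <- flag + .FLAG_MATE_UNMAPPED
      else if (mateHit$strand == "-") flag <- flag + .FLAG_MATE_REVERSE
    }
  }
  if (!hit$mapped) {
    flag <- flag + .FLAG_UNMAPPED
    fields <- c(normalizeKey(id), flag, "*", 0L, 0L, "*", "*", 0L, 0L,
                seq, qual)
    return(paste(fields, collapse = "\t"))
  }
  if (hit$strand == "-") {
    flag <- flag + .FLAG_REVERSE
    seq <- revComp(seq)
    qual <- intToUtf8(rev(utf8ToInt(qual)))
  }
  rnext <- "*"; pnext <- 0L
  if (paired && !is.null(mateHit) && mateHit$mapped) {
    rnext <- if (identical(mateHit$refName, hit$refName)) "="
             else mateHit$refName
    pnext <- mateHit$pos
  }
  fields <- c(normalizeKey(id), flag, hit$refName, hit$pos, mapq,
              paste0(nchar(seq), "M"), rnext, pnext, 0L, seq, qual)
  paste(fields, collapse = "\t")
}

#' Construct the built-in toy aligner backend
#'
#' @param reference either a path to a FASTA file or a named character
#'   vector of reference sequences.
#' @param seedLen exact-match seed length.
#' @param mapq fixed MAPQ reported for mapped reads.
#' @return a \linkS4class{ToyBackend}.
#' @export
ToyBackend <- function(reference, seedLen = 20L, mapq = 37L) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(ss),
                                 sub("\\s.*$", "", names(ss)))
  }
  new("ToyBackend", reference = reference, seedLen = as.integer(seedLen),
      mapq = as.integer(mapq))
}

# SAM header for the toy backend: @HD, one @SQ per reference sequence, @PG.
.toyHeader <- function(backend) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(backend@reference),
            nchar(backend@reference)),
    sprintf("@PG\tID:partialign-toy\tPN:partialign-toy\tVN:%s",
            as.character(utils::packageVersion("partialign"))))
}

.persistFragment <- function(fragment, workdir) {
  if (is.na(workdir) || !nzchar(workdir)) return(invisible(NULL))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(workdir,
                    sprintf("part-%05d.sam", fragment@partitionIndex))
  writeLines(c(fragment@header, fragment@alignments), path)
  invisible(path)
}

#' @describeIn runBackend deterministic in-process toy alignment; the
#'   algorithm code is accepted but does not change the (single) toy
#'   scoring rule.
#' @export
setMethod("runBackend", signature(backend = "ToyBackend",
                                  request = "BackendRequest"),
  function(backend, request) {
    recs <- partitionRecords(request@partition)
    header <- .toyHeader(backend)
    aln <- character(0)
    if (is(recs, "PairedReads") && length(recs)) {
      for (i in seq_len(length(recs))) {
        h1 <- toyAlign(recs@seq1[i], backend@reference, backend@seedLen)
        h2 <- toyAlign(recs@seq2[i], backend@reference, backend@seedLen)
        aln <- c(aln,
          toyHitToSam(recs@id1[i], recs@seq1[i], recs@qual1[i], h1,
                      paired = TRUE, mateNumber = 1L, mateHit = h2,
                      mapq = backend@mapq),
          toyHitToSam(recs@id2[i], recs@seq2[i], recs@qual2[i], h2,
                      paired = TRUE, mateNumber = 2L, mateHit = h1,
                      mapq = backend@mapq))
      }
    } else if (is(recs, "KeyedReads") && length(recs)) {
      for (i in seq_len(length(recs))) {
        h <- toyAlign(recs@seq[i], backend@reference, backend@seedLen)
        aln <- c(aln, toyHitToSam(recs@id[i], recs@seq[i], recs@qual[i], h,
                                  paired = FALSE, mapq = backend@mapq))
      }
    }
    fragment <- new("SamFragment",
                    partitionIndex = partitionIndex(request@partition),
                    header = header, alignments = aln)
    .persistFragment(fragment, request@workdir)
    fragment
  })

#' Construct a backend request
#'
#' @param partition a \linkS4class{ReadPartition}.
#' @param algorithm "MEM", "BACKTRACK" or "SW".
#' @param paired logical.
#' @param threads threads the backend may use.
#' @param indexRef index prefix (external backend) or FASTA path (toy).
#' @param workdir scratch directory for the persisted per-partition SAM.
#' @return a \linkS4class{BackendRequest}.
#' @export
backendRequest <- function(partition, algorithm = "MEM", paired = TRUE,
                           threads = 1L, indexRef = NA_character_,
                           workdir = NA_character_) {
  new("BackendRequest", algorithm = algorithm, paired = paired,
      threads = as.integer(threads), indexRef = indexRef,
      partition = partition, workdir = workdir)
}
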