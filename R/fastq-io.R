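# FASTQ read/write and key normalization.
#
# The readers are strict by design: a malformed quartet is a hard error
# naming the offending line, never a skipped record — silent data loss in a
# pairing pipeline is worse than failure. Qualities and the '+'-line payload
# are carried verbatim; base case is preserved. parse-then-serialize is the
# identity on bytes for any valid 4-line FASTQ stream.

#' Construct a FastqReads object
#'
#' @param id character, identifier lines without the leading \code{@}.
#' @param seq character, base strings.
#' @param plus character, \code{+}-line payloads (recycled "" by default).
#' @param qual character, quality strings.
#' @return a \linkS4class{FastqReads}.
#' @export
FastqReads <- function(id = character(), seq = character(),
                       plus = character(length(id)), qual = character()) {
  plus[is.na(plus)] <- ""
  new("FastqReads", id = as.character(id), seq = as.character(seq),
      plus = as.character(plus), qual = as.character(qual))
}

# Open a text connection, transparently inflating gzip input (detected by
# the 1f 8b magic bytes, not the file extension).
.openInput <- function(path) {
  stopifnot(length(path) == 1L)
  if (!file.exists(path)) stop("input file not found: ", path)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) &&
      magic[2L] == as.raw(0x8b)) gzfile(path, "rt") else file(path, "rt")
}

.openOutput <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read a FASTQ file into a FastqReads object
#'
#' Strict 4-line FASTQ parser: every quartet must hold an \code{@}
#' identifier line, the bases, a \code{+} separator line and a quality
#' string of the same length as the bases. Gzip-compressed input is
#' accepted transparently (detected by magic bytes). Record order is file
#' order; wrapped sequence lines are not supported.
#'
#' @param path path to a FASTQ file (plain or gzip).
#' @return a \linkS4class{FastqReads} in file order.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path) {
  con <- .openInput(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  parseFastqLines(lines)
}

# Parse a character vector of FASTQ lines; shared by file and in-memory use.
parseFastqLines <- function(lines) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4; ",
         "last complete record ends at line ", 4L * (n %/% 4L))
  if (n == 0L) return(FastqReads())
  at <- seq.int(1L, n, by = 4L)
  idLine <- lines[at]
  seqs <- lines[at + 1L]
  plusLine <- lines[at + 2L]
  quals <- lines[at + 3L]
  bad <- which(substr(idLine, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ: line ", at[bad[1L]],
         " must start with '@', got: ", substr(idLine[bad[1L]], 1L, 40L))
  bad <- which(substr(plusLine, 1L, 1L) != "+")
  if (length(bad))
    stop("malformed FASTQ: line ", at[bad[1L]] + 2L,
         " must start with '+', got: ", substr(plusLine[bad[1L]], 1L, 40L))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1L], " ('",
         sub("^@", "", idLine[bad[1L]]),
         "') has sequence and quality of different lengths")
  FastqReads(id = substring(idLine, 2L), seq = seqs,
             plus = substring(plusLine, 2L), qual = quals)
}

# Serialize to the 4-line representation (no trailing newline handling here).
fastqLines <- function(reads) {
  n <- length(reads)
  if (n == 0L) return(character(0))
  out <- character(4L * n)
  at <- seq.int(1L, 4L * n, by = 4L)
  out[at] <- paste0("@", reads@id)
  out[at + 1L] <- reads@seq
  out[at + 2L] <- paste0("+", reads@plus)
  out[at + 3L] <- reads@qual
  out
}

#' Write a FastqReads object to a FASTQ file
#'
#' Emits exactly four lines per record in input order. Paths ending in
#' \code{.gz} are written gzip-compressed.
#'
#' @param reads a \linkS4class{FastqReads}.
#' @param path output path.
#' @return invisibly, the number of lines written (\code{4 * length(reads)}).
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is(reads, "FastqReads"))
  con <- .openOutput(path)
  on.exit(close(con))
  lines <- fastqLines(reads)
  writeLines(lines, con)
  invisible(length(lines))
}

#' Normalize a read identifier to its pairing key
#'
#' Strips any whitespace-delimited comment (everything from the first space
#' or tab on), then one trailing mate designator of the form \code{/1} or
#' \code{/2} if present. Both mates of a proper pair — whether they use the
#' legacy \code{/1,/2} suffix convention or the modern comment-field
#' convention — map to the same key.
#'
#' @param rawId character vector of identifier lines (without \code{@}).
#' @return character vector of normalized keys.
#' @examples
#' normalizeKey("SRR0001.7/1")                    # "SRR0001.7"
#' normalizeKey("M00001:12:000:1:1101 2:N:0:ACG") # comment stripped
#' @export
normalizeKey <- function(rawId) {
  if (any(!nzchar(rawId) | is.na(rawId)))
    stop("read identifiers must be non-empty")
  key <- sub("[ \t].*$", "", rawId)
  sub("/[12]$", "", key)
}
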