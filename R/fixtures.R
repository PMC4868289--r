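# Synthetic data generator: a uniform random reference plus paired reads
# with known ground-truth placement, so the whole pipeline is testable
# without any external download. All outputs are pure functions of the
# FixtureSpec (seeded, byte-reproducible).

#' Construct a fixture specification
#'
#' @param refLength reference length in bases.
#' @param nPairs proper pairs to generate.
#' @param readLength read length in bases.
#' @param substitutionRate per-base substitution probability in [0,1].
#' @param insertSize outer fragment length; mate 2 is the reverse
#'   complement of the fragment's far end.
#' @param orphanCount deliberately stranded reads (alternating between the
#'   two files).
#' @param duplicateKeyCount deliberate key collisions within file 1.
#' @param shuffleFile2 permute file-2 record order (exercises the join
#'   path; breaks the positional precondition of the interleave path).
#' @param seed RNG seed.
#' @return a validated \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(refLength = 10000L, nPairs = 500L, readLength = 100L,
                        substitutionRate = 0.01, insertSize = 300L,
                        orphanCount = 0L, duplicateKeyCount = 0L,
                        shuffleFile2 = FALSE, seed = 1L) {
  new("FixtureSpec", refLength = as.integer(refLength),
      nPairs = as.integer(nPairs), readLength = as.integer(readLength),
      substitutionRate = as.numeric(substitutionRate),
      insertSize = as.integer(insertSize),
      orphanCount = as.integer(orphanCount),
      duplicateKeyCount = as.integer(duplicateKeyCount),
      shuffleFile2 = as.logical(shuffleFile2), seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate the fixture reference sequence
#'
#' A uniform random A/C/G/T sequence named \code{chr1}, written as wrapped
#' FASTA and returned in memory. Reproducible: the same spec always yields
#' identical bytes.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param path output FASTA path (default: a tempfile).
#' @return list with \code{path} (FASTA file) and \code{sequences} (named
#'   character vector).
#' @export
generateReference <- function(spec, path = tempfile(fileext = ".fasta")) {
  stopifnot(is(spec, "FixtureSpec"))
  seqchr <- .withSeed(spec@seed, paste(
    sample(c("A", "C", "G", "T"), spec@refLength, replace = TRUE),
    collapse = ""))
  ref <- c(chr1 = seqchr)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path,
                              width = 70L)
  list(path = path, sequences = ref)
}

.mutate <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate paired FASTQ files with ground truth
#'
#' Samples \code{nPairs} fragments uniformly from the reference; mate 1 is
#' the fragment's first \code{readLength} bases on the forward strand,
#' mate 2 the reverse complement of its last \code{readLength} bases.
#' Per-base substitutions are applied at \code{substitutionRate}.
#' Identifiers follow the legacy convention \code{<key>/1}, \code{<key>/2};
#' qualities are a constant high-quality character (never interpreted by
#' the pipeline). Orphans, duplicate keys and file-2 shuffling are injected
#' as requested. The truth table records, per key, the 1-based mapping
#' positions of both mates and mate 2's strand.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param reference result of \code{\link{generateReference}} (regenerated
#'   from \code{spec} when missing).
#' @param dir output directory (default: a fresh temp directory).
#' @return list with \code{fastq1}, \code{fastq2} (paths), \code{truth}
#'   (data.frame: key, refName, pos1, pos2, strand2) and \code{truthPath}
#'   (TSV file).
#' @export
generatePairs <- function(spec, reference = generateReference(spec),
                          dir = tempfile("fixture-")) {
  stopifnot(is(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refseq <- reference$sequences[[1L]]
  refName <- names(reference$sequences)[1L]
  L <- spec@readLength
  .withSeed(spec@seed + 1L, {
    n <- spec@nPairs
    maxStart <- spec@refLength - spec@insertSize + 1L
    starts <- if (n) sample.int(maxStart, n, replace = TRUE) else integer(0)
    pos2 <- starts + spec@insertSize - L
    keys <- sprintf("sim.%06d", seq_len(n))
    m1 <- substring(refseq, starts, starts + L - 1L)
    m2 <- revComp(substring(refseq, pos2, pos2 + L - 1L))
    m1 <- .mutate(m1, spec@substitutionRate)
    m2 <- .mutate(m2, spec@substitutionRate)
    qual <- strrep("I", L)
    reads1 <- FastqReads(id = paste0(keys, "/1"), seq = m1,
                         plus = character(n), qual = rep(qual, n))
    reads2 <- FastqReads(id = paste0(keys, "/2"), seq = m2,
                         plus = character(n), qual = rep(qual, n))
    truth <- data.frame(key = keys, refName = rep(refName, n),
                        pos1 = starts, pos2 = pos2,
                        strand2 = rep("-", n), stringsAsFactors = FALSE)
    # injected faults -----------------------------------------------------
    if (spec@orphanCount) {
      opos <- sample.int(max(maxStart, 1L), spec@orphanCount, replace = TRUE)
      oseq <- substring(refseq, opos, opos + L - 1L)
      okey <- sprintf("orphan.%03d", seq_len(spec@orphanCount))
      toFile1 <- seq_len(spec@orphanCount) %% 2L == 1L
      o1 <- FastqReads(id = paste0(okey[toFile1], "/1"),
                       seq = oseq[toFile1],
                       plus = character(sum(toFile1)),
                       qual = rep(qual, sum(toFile1)))
      o2 <- FastqReads(id = paste0(okey[!toFile1], "/2"),
                       seq = oseq[!toFile1],
                       plus = character(sum(!toFile1)),
                       qual = rep(qual, sum(!toFile1)))
      reads1 <- .concatReads(reads1, o1)
      reads2 <- .concatReads(reads2, o2)
    }
    if (spec@duplicateKeyCount) {
      k <- min(spec@duplicateKeyCount, length(reads1))
      reads1 <- .concatReads(reads1, reads1[seq_len(k)])
    }
    if (spec@shuffleFile2 && length(reads2) > 1L)
      reads2 <- reads2[sample.int(length(reads2))]
    fastq1 <- file.path(dir, "reads_1.fastq")
    fastq2 <- file.path(dir, "reads_2.fastq")
    writeFastq(reads1, fastq1)
    writeFastq(reads2, fastq2)
    truthPath <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fastq1 = fastq1, fastq2 = fastq2, truth = truth,
         truthPath = truthPath)
  })
}

.concatReads <- function(a, b)
  FastqReads(id = c(a@id, b@id), seq = c(a@seq, b@seq),
             plus = c(a@plus, b@plus), qual = c(a@qual, b@qual))
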