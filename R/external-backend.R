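# External-command aligner backend. Only the public command line of the
# aligner is used (bwa conventions), so the pipeline stays version-agnostic
# with respect to the aligner: mem / bwasw are single invocations, while the
# backtrack flow (aln per mate file, then sampe/samse) is encapsulated here
# and fully transparent to the caller.

#' Construct an external-command aligner backend
#'
#' @param executable the aligner executable (default \code{"bwa"}); may be
#'   an absolute path.
#' @param timeout per-invocation timeout in seconds.
#' @return an \linkS4class{ExternalBackend}.
#' @export
ExternalBackend <- function(executable = "bwa", timeout = 3600) {
  new("ExternalBackend", executable = executable, timeout = as.numeric(timeout))
}

# Run one external command; on nonzero exit raise an error carrying the
# captured stderr diagnostics.
.runCommand <- function(exe, args, stdoutFile, timeout) {
  errFile <- tempfile("backend-stderr-")
  on.exit(unlink(errFile))
  status <- suppressWarnings(
    system2(exe, args, stdout = stdoutFile, stderr = errFile,
            timeout = timeout))
  if (!identical(status, 0L)) {
    diag <- if (file.exists(errFile))
      paste(utils::tail(readLines(errFile, warn = FALSE), 20L),
            collapse = "\n") else ""
    stop("external aligner failed (exit status ", status, "): ", exe, " ",
         paste(args, collapse = " "), "\n", diag)
  }
  invisible(status)
}

# Write the partition's records as mate FASTQ files under dir.
.partitionToFastq <- function(recs, dir) {
  if (is(recs, "PairedReads")) {
    f1 <- file.path(dir, "reads_1.fastq")
    f2 <- file.path(dir, "reads_2.fastq")
    writeFastq(FastqReads(recs@id1, recs@seq1, recs@plus1, recs@qual1), f1)
    writeFastq(FastqReads(recs@id2, recs@seq2, recs@plus2, recs@qual2), f2)
    c(f1, f2)
  } else {
    f1 <- file.path(dir, "reads.fastq")
    writeFastq(FastqReads(recs@id, recs@seq, recs@plus, recs@qual), f1)
    f1
  }
}

#' @describeIn runBackend shells out to the external aligner; the request's
#'   \code{threads} value is passed verbatim as \code{-t}. The backtrack
#'   algorithm runs its three phases (aln per input, then sampe/samse)
#'   internally.
#' @export
setMethod("runBackend", signature(backend = "ExternalBackend",
                                  request = "BackendRequest"),
  function(backend, request) {
    if (is.na(request@indexRef) || !nzchar(request@indexRef))
      stop("external backend requires an index prefix (indexRef)")
    if (!file.exists(request@indexRef) &&
        !any(file.exists(paste0(request@indexRef,
                                c(".bwt", ".amb", ".ann")))))
      stop("aligner index not found at prefix: ", request@indexRef)
    scratch <- tempfile(
      sprintf("mapper-%05d-", partitionIndex(request@partition)))
    dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
    on.exit(unlink(scratch, recursive = TRUE), add = TRUE)
    recs <- partitionRecords(request@partition)
    fq <- .partitionToFastq(recs, scratch)
    samFile <- file.path(scratch, "out.sam")
    exe <- backend@executable
    idx <- request@indexRef
    thr <- as.character(request@threads)
    if (request@algorithm == "MEM") {
      .runCommand(exe, c("mem", "-t", thr, idx, fq), samFile,
                  backend@timeout)
    } else if (request@algorithm == "SW") {
      .runCommand(exe, c("bwasw", "-t", thr, idx, fq), samFile,
                  backend@timeout)
    } else {  # BACKTRACK: aln per file, then sampe (paired) or samse
      sai <- character(length(fq))
      for (i in seq_along(fq)) {
        sai[i] <- file.path(scratch, sprintf("aln_%d.sai", i))
        .runCommand(exe, c("aln", "-t", thr, idx, fq[i]), sai[i],
                    backend@timeout)
      }
      if (length(fq) == 2L)
        .runCommand(exe, c("sampe", idx, sai, fq), samFile, backend@timeout)
      else
        .runCommand(exe, c("samse", idx, sai, fq), samFile, backend@timeout)
    }
    lines <- readLines(samFile, warn = FALSE)
    isHeader <- startsWith(lines, "@")
    fragment <- new("SamFragment",
                    partitionIndex = partitionIndex(request@partition),
                    header = lines[isHeader],
                    alignments = lines[!isHeader])
    .persistFragment(fragment, request@workdir)
    fragment
  })
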