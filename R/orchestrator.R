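# The driver: prepare -> partition -> map -> (optional) reduce.
#
# Preparation is lazy: no input byte is read before runAlignment() is
# called. The map phase honours a local concurrency budget (processes) and
# a per-mapper thread count (hybrid mode); the reduce phase concatenates
# fragments in partition-index order, so results are independent of how
# the work was split or scheduled.

.stageError <- function(stage, e) {
  stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
}

#' Fan partitions out to the aligner backend under a concurrency budget
#'
#' Processes the partitions in waves of at most
#' \code{maxConcurrentMappers} simultaneous backend invocations (forked
#' processes), each invocation receiving \code{threadsPerMapper} threads
#' (> 1 is the hybrid two-level mode). A failed partition is retried once,
#' then aborts the run. Fragments are returned in partition-index order
#' regardless of completion order.
#'
#' @param partitions list of \linkS4class{ReadPartition}.
#' @param options a \linkS4class{RunOptions}.
#' @param backend an \linkS4class{AlignerBackend}.
#' @param workdir directory where per-partition SAM files are persisted.
#' @return list of \linkS4class{SamFragment} in partition-index order.
#' @export
mapPhase <- function(partitions, options, backend,
                     workdir = NA_character_) {
  if (!length(partitions)) return(list())
  algo <- names(.ALGORITHMS)[options@algorithm + 1L]
  runOne <- function(partition) {
    req <- backendRequest(partition, algorithm = algo,
                          paired = options@paired,
                          threads = options@threadsPerMapper,
                          indexRef = options@indexPath,
                          workdir = workdir)
    runBackend(backend, req)
  }
  attemptOne <- function(partition) {
    tryCatch(runOne(partition), error = function(e)
      structure(list(message = conditionMessage(e)),
                class = "backendFailure"))
  }
  budget <- options@maxConcurrentMappers
  waves <- split(partitions,
                 (seq_along(partitions) - 1L) %/% budget)
  fragments <- vector("list", length(partitions))
  k <- 0L
  for (wave in waves) {
    res <- if (budget > 1L && length(wave) > 1L)
      parallel::mclapply(wave, attemptOne,
                         mc.cores = min(budget, length(wave)),
                         mc.preschedule = FALSE)
    else lapply(wave, attemptOne)
    for (j in seq_along(res)) {
      frag <- res[[j]]
      if (inherits(frag, "backendFailure") || inherits(frag, "try-error")) {
        # one retry, serially, before giving up (bounded local stand-in
        # for framework-level fault tolerance)
        frag <- attemptOne(wave[[j]])
        if (inherits(frag, "backendFailure"))
          stop("map stage: partition ", partitionIndex(wave[[j]]),
               " failed twice: ", frag$message, call. = FALSE)
      }
      fragments[[k + j]] <- frag
    }
    k <- k + length(wave)
  }
  ord <- order(vapply(fragments, partitionIndex, integer(1)))
  fragments[ord]
}

#' Merge per-partition SAM fragments into one SAM file
#'
#' The header is emitted once, taken from the lowest-index fragment, with
#' the \code{@PG} lines of all fragments appended (deduplicated).
#' Fragments must share one reference dictionary: conflicting \code{@SQ}
#' line sets are a merge error naming the mismatch. Alignment lines are
#' concatenated in partition-index order. With zero fragments a minimal
#' header-only SAM is written.
#'
#' @param fragments list of \linkS4class{SamFragment}.
#' @param outPath path of the merged SAM file.
#' @return \code{outPath}, invisibly.
#' @export
reducePhase <- function(fragments, outPath) {
  if (!length(fragments)) {
    writeLines("@HD\tVN:1.6\tSO:unsorted", outPath)
    return(invisible(outPath))
  }
  ord <- order(vapply(fragments, partitionIndex, integer(1)))
  fragments <- fragments[ord]
  sq <- lapply(fragments, function(f)
    samHeader(f)[startsWith(samHeader(f), "@SQ")])
  for (i in seq_along(sq)[-1L]) {
    if (!identical(sq[[i]], sq[[1L]]))
      stop("cannot merge fragments with conflicting reference ",
           "dictionaries:\n  fragment ", partitionIndex(fragments[[1L]]),
           ": ", paste(sq[[1L]], collapse = " | "), "\n  fragment ",
           partitionIndex(fragments[[i]]), ": ",
           paste(sq[[i]], collapse = " | "))
  }
  h1 <- samHeader(fragments[[1L]])
  pg <- unique(unlist(lapply(fragments, function(f)
    samHeader(f)[startsWith(samHeader(f), "@PG")])))
  header <- c(h1[!startsWith(h1, "@PG")], pg)
  aln <- unlist(lapply(fragments, samAlignments))
  writeLines(c(header, aln), outPath)
  invisible(outPath)
}

# Prepare the record stream according to the pairing strategy. Returns the
# PreparedReads plus the PairingReport (NULL report for single-end).
.prepareRecords <- function(options) {
  if (!options@paired) {
    reads <- readFastq(options@inputPath)
    return(list(records = prepareSingleEnd(reads), report = NULL))
  }
  if (options@sortMode %in% c(0L, 1L)) {
    r1 <- readFastq(options@inputPath)
    r2 <- readFastq(options@inputPath2)
    res <- pairJoin(r1, r2, sort = options@sortMode == 1L)
    list(records = res$pairs, report = res$report)
  } else {
    interPath <- tempfile("interleaved-", fileext = ".txt")
    report <- pairInterleave(options@inputPath, options@inputPath2,
                             interPath)
    records <- readInterleaved(interPath)
    unlink(interPath)
    list(records = records, report = report)
  }
}

#' Run the complete alignment workflow
#'
#' Executes prepare, partition, map and (optionally) reduce. Input is not
#' touched before this call. With \code{useReducer = FALSE} the output
#' directory holds one \code{part-<index>.sam} per partition; with
#' \code{useReducer = TRUE} it additionally holds the single merged
#' \code{merged.sam}. A JSON run manifest (options, partition manifest,
#' per-stage timings, pairing counters) is written alongside. Any stage
#' error aborts with a stage-tagged diagnostic and removes the partial
#' outputs of this run.
#'
#' @param options a validated \linkS4class{RunOptions};
#'   \code{options@outputPath} is created as a directory.
#' @param backend an \linkS4class{AlignerBackend} (defaults to an external
#'   \code{bwa} backend).
#' @return a \linkS4class{RunResult}.
#' @export
runAlignment <- function(options, backend = ExternalBackend()) {
  validObject(options)
  outDir <- options@outputPath
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      unlink(created)
      .stageError(stage, e)
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    r
  }
  prep <- clock("prepare", .prepareRecords(options))
  partitions <- clock("partition", {
    if (!is.na(options@partitionCount))
      makePartitions(prep$records, options@partitionCount)
    else
      makePartitionsByBytes(prep$records, options@blockBytes)
  })
  fragments <- clock("map", {
    frags <- mapPhase(partitions, options, backend, workdir = outDir)
    created <- c(created, file.path(outDir, sprintf("part-%05d.sam",
      vapply(frags, partitionIndex, integer(1)))))
    frags
  })
  mergedPath <- NA_character_
  if (options@useReducer) {
    mergedPath <- file.path(outDir, "merged.sam")
    clock("reduce", {
      created <- c(created, mergedPath)
      reducePhase(fragments, mergedPath)
    })
  }
  stageLog <- data.frame(stage = names(timings),
                         seconds = unname(unlist(timings)))
  report <- prep$report
  manifest <- list(
    options = list(
      useReducer = options@useReducer,
      partitionCount = options@partitionCount,
      sortMode = options@sortMode,
      threadsPerMapper = options@threadsPerMapper,
      algorithm = options@algorithm,
      paired = options@paired,
      indexPath = options@indexPath,
      inputPath = options@inputPath,
      inputPath2 = options@inputPath2,
      outputPath = options@outputPath,
      maxConcurrentMappers = options@maxConcurrentMappers),
    partitions = partitionManifest(partitions),
    timings = stageLog,
    pairing = if (!is.null(report)) list(
      pairsEmitted = report@pairsEmitted,
      orphansFile1 = report@orphansFile1,
      orphansFile2 = report@orphansFile2,
      duplicateKeys = report@duplicateKeys) else NULL)
  jsonlite::write_json(manifest, file.path(outDir, "run-manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  new("RunResult",
      fragmentsWritten = length(fragments),
      pairsAligned = length(prep$records),
      mergedOutput = mergedPath,
      stageLog = stageLog)
}
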