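# End-to-end workflow: map-phase scheduling, reduce-phase merging, and the
# invariances the map/reduce design must guarantee.

runFixture <- function(fxl, ..., backend = ToyBackend(fxl$ref$path)) {
  opts <- bwaOptions(indexPath = fxl$ref$path, inputPath = fxl$fx$fastq1,
                     inputPath2 = fxl$fx$fastq2,
                     outputPath = tempfile("run-"), useReducer = TRUE, ...)
  list(opts = opts, result = runAlignment(opts, backend = backend))
}

test_that("a reduced run conserves records: 2 alignment lines per pair", {
  fxl <- smallFixture(nPairs = 60L, seed = 61L)
  run <- runFixture(fxl, partitionCount = 4L)
  expect_identical(run$result@fragmentsWritten, 4L)
  expect_identical(run$result@pairsAligned, 60L)
  merged <- readLines(run$result@mergedOutput)
  aln <- merged[!startsWith(merged, "@")]
  expect_length(aln, 2L * 60L)
  # sum of per-partition fragments equals the merged count
  parts <- list.files(run$opts@outputPath, pattern = "^part-.*\\.sam$",
                      full.names = TRUE)
  expect_length(parts, 4L)
  perPart <- vapply(parts, function(p) {
    l <- readLines(p); sum(!startsWith(l, "@"))
  }, integer(1))
  expect_identical(sum(perPart), length(aln))
  # manifest is written and counts agree
  manifest <- jsonlite::read_json(
    file.path(run$opts@outputPath, "run-manifest.json"),
    simplifyVector = TRUE)
  expect_identical(manifest$pairing$pairsEmitted, 60L)
  expect_identical(sum(manifest$partitions$records), 60L)
})

test_that("empty paired input still produces a valid header-only SAM", {
  e1 <- tempfile(fileext = ".fastq"); file.create(e1)
  e2 <- tempfile(fileext = ".fastq"); file.create(e2)
  ref <- generateReference(fixtureSpec(refLength = 400L, seed = 3L))
  opts <- bwaOptions(indexPath = ref$path, inputPath = e1, inputPath2 = e2,
                     outputPath = tempfile("empty-"), useReducer = TRUE,
                     partitionCount = 4L)
  res <- runAlignment(opts, backend = ToyBackend(ref$path))
  expect_identical(res@fragmentsWritten, 0L)
  lines <- readLines(res@mergedOutput)
  expect_true(all(startsWith(lines, "@")))
  expect_identical(sum(startsWith(lines, "@HD")), 1L)
})

test_that("merged output is invariant to the partition count", {
  fxl <- smallFixture(nPairs = 70L, seed = 62L)
  sams <- lapply(c(1L, 2L, 7L), function(p)
    samAlignmentMultiset(runFixture(fxl, partitionCount = p)$result@mergedOutput))
  expect_identical(sams[[2L]], sams[[1L]])
  expect_identical(sams[[3L]], sams[[1L]])
  expect_length(sams[[1L]], 140L)
})

test_that("merged output is invariant to the concurrency budget", {
  fxl <- smallFixture(nPairs = 40L, seed = 63L)
  a <- runFixture(fxl, partitionCount = 5L, maxConcurrentMappers = 1L)
  b <- runFixture(fxl, partitionCount = 5L, maxConcurrentMappers = 4L)
  expect_identical(samAlignmentMultiset(a$result@mergedOutput),
                   samAlignmentMultiset(b$result@mergedOutput))
})

test_that("regular and hybrid thread counts give identical merged output", {
  fxl <- smallFixture(nPairs = 40L, seed = 64L)
  sams <- lapply(c(1L, 2L, 4L), function(t)
    samAlignmentMultiset(
      runFixture(fxl, partitionCount = 3L,
                 threadsPerMapper = t)$result@mergedOutput))
  expect_identical(sams[[2L]], sams[[1L]])
  expect_identical(sams[[3L]], sams[[1L]])
})

test_that("pairing strategies drive identical merged multisets", {
  fxl <- smallFixture(nPairs = 50L, seed = 65L)
  byJoin <- runFixture(fxl, partitionCount = 3L, sortMode = 0L)
  bySort <- runFixture(fxl, partitionCount = 3L, sortMode = 1L)
  byInterleave <- runFixture(fxl, partitionCount = 3L, sortMode = 2L)
  m <- samAlignmentMultiset(byJoin$result@mergedOutput)
  expect_identical(samAlignmentMultiset(bySort$result@mergedOutput), m)
  expect_identical(samAlignmentMultiset(byInterleave$result@mergedOutput), m)
})

test_that("map phase respects the concurrency budget and passes threads", {
  fxl <- smallFixture(nPairs = 12L, seed = 66L)
  pairs <- pairJoin(readFastq(fxl$fx$fastq1),
                    readFastq(fxl$fx$fastq2))$pairs
  partitions <- makePartitions(pairs, 3L)
  dir <- tempfile("rec-"); dir.create(dir)
  backend <- new("RecordingBackend", dir = dir, sleep = 0.25)
  opts <- bwaOptions(indexPath = fxl$ref$path, inputPath = fxl$fx$fastq1,
                     inputPath2 = fxl$fx$fastq2, outputPath = tempfile(),
                     threadsPerMapper = 4L, maxConcurrentMappers = 2L)
  frags <- mapPhase(partitions, opts, backend)
  expect_length(frags, 3L)
  expect_identical(vapply(frags, partitionIndex, integer(1)), 0:2)
  expect_lte(peakConcurrency(dir), 2L)
  expect_identical(recordedThreads(dir), rep(4L, 3L))
})

test_that("a transiently failing partition is retried once and recovers", {
  fxl <- smallFixture(nPairs = 10L, seed = 67L)
  pairs <- pairJoin(readFastq(fxl$fx$fastq1),
                    readFastq(fxl$fx$fastq2))$pairs
  partitions <- makePartitions(pairs, 2L)
  failDir <- tempfile("flaky-"); dir.create(failDir)
  toy <- ToyBackend(fxl$ref$path)
  flaky <- new("FlakyBackend", reference = toy@reference,
               seedLen = toy@seedLen, mapq = toy@mapq,
               failDir = failDir, failOnce = 1L)
  opts <- bwaOptions(indexPath = fxl$ref$path, inputPath = fxl$fx$fastq1,
                     inputPath2 = fxl$fx$fastq2, outputPath = tempfile(),
                     maxConcurrentMappers = 1L)
  frags <- mapPhase(partitions, opts, flaky)
  expect_length(frags, 2L)
  steady <- mapPhase(partitions, opts, toy)
  expect_identical(lapply(frags, samAlignments),
                   lapply(steady, samAlignments))
  # a permanently failing partition aborts with a stage diagnostic
  expect_error(mapPhase(partitions, opts, new("FailingBackend")),
               "failed twice")
})

test_that("reduce of one fragment reproduces its body", {
  frag <- new("SamFragment", partitionIndex = 0L,
              header = c("@HD\tVN:1.6\tSO:unsorted",
                         "@SQ\tSN:chr1\tLN:100",
                         "@PG\tID:x\tPN:x"),
              alignments = "q\t0\tchr1\t5\t37\t4M\t*\t0\t0\tACGT\tIIII")
  out <- tempfile()
  reducePhase(list(frag), out)
  expect_identical(readLines(out), c(samHeader(frag), samAlignments(frag)))
})

test_that("reduce concatenates counts, dedupes @PG and keeps one @HD", {
  mk <- function(idx, n, pg = "@PG\tID:x\tPN:x") {
    new("SamFragment", partitionIndex = idx,
        header = c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:100", pg),
        alignments = replicate(n, paste(
          paste0("q", idx), 0L, "chr1", 5L, 37L, "4M", "*", 0L, 0L,
          "ACGT", "IIII", sep = "\t")))
  }
  out <- tempfile()
  reducePhase(list(mk(1L, 5L), mk(0L, 3L)), out)
  lines <- readLines(out)
  aln <- lines[!startsWith(lines, "@")]
  expect_length(aln, 8L)
  # partition-index order regardless of list order
  expect_identical(substr(aln, 1L, 2L), c(rep("q0", 3L), rep("q1", 5L)))
  expect_identical(sum(startsWith(lines, "@HD")), 1L)
  expect_identical(sum(startsWith(lines, "@PG")), 1L)
  # distinct @PG lines are concatenated
  out2 <- tempfile()
  reducePhase(list(mk(0L, 1L), mk(1L, 1L, pg = "@PG\tID:y\tPN:y")), out2)
  expect_identical(sum(startsWith(readLines(out2), "@PG")), 2L)
})

test_that("conflicting reference dictionaries refuse to merge", {
  a <- new("SamFragment", partitionIndex = 0L,
           header = c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100"),
           alignments = character(0))
  b <- new("SamFragment", partitionIndex = 1L,
           header = c("@HD\tVN:1.6", "@SQ\tSN:chr2\tLN:999"),
           alignments = character(0))
  expect_error(reducePhase(list(a, b), tempfile()),
               "conflicting reference.*chr2")
})

test_that("single-end runs work end to end", {
  fxl <- smallFixture(nPairs = 30L, seed = 68L)
  opts <- bwaOptions(indexPath = fxl$ref$path, inputPath = fxl$fx$fastq1,
                     outputPath = tempfile("se-"), paired = FALSE,
                     useReducer = TRUE, partitionCount = 3L)
  res <- runAlignment(opts, backend = ToyBackend(fxl$ref$path))
  expect_identical(res@pairsAligned, 30L)
  aln <- samAlignmentMultiset(res@mergedOutput)
  expect_length(aln, 30L)   # one line per read in single-end mode
  flags <- as.integer(vapply(strsplit(aln, "\t"), `[[`, "", 2L))
  expect_true(all(bitwAnd(flags, 0x1L) == 0L))  # not paired
})

test_that("stage errors are tagged with the failing stage", {
  ref <- generateReference(fixtureSpec(refLength = 400L, seed = 4L))
  opts <- bwaOptions(indexPath = ref$path,
                     inputPath = tempfile("missing-"),
                     inputPath2 = tempfile("missing-"),
                     outputPath = tempfile())
  expect_error(runAlignment(opts, backend = ToyBackend(ref$path)),
               "stage prepare:")
})

test_that("auto partitioning by block bytes is used when count is NA", {
  fxl <- smallFixture(nPairs = 40L, seed = 69L)
  run <- runFixture(fxl, blockBytes = 1500)
  expect_gt(run$result@fragmentsWritten, 1L)
  expect_length(samAlignmentMultiset(run$result@mergedOutput), 80L)
})
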