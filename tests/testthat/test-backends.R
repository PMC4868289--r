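# Toy aligner, SAM rendering, and the backend contract.

toyRef <- function(seed = 101L, len = 2000L) {
  generateReference(fixtureSpec(refLength = len, seed = seed))$sequences
}

test_that("a read equal to a reference prefix maps at position 1", {
  ref <- toyRef()
  read <- substr(ref[[1L]], 1L, 60L)
  hit <- toyAlign(read, ref, seedLen = 20L)
  expect_true(hit$mapped)
  expect_identical(hit$pos, 1L)
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$strand, "+")
})

test_that("an all-N read is unmapped; short reads are a value error", {
  ref <- toyRef()
  hit <- toyAlign(strrep("N", 50L), ref, seedLen = 20L)
  expect_false(hit$mapped)
  expect_error(toyAlign("ACGT", ref, seedLen = 20L), "shorter than")
})

test_that("reverse-complemented reads are found on the minus strand", {
  ref <- toyRef()
  frag <- substr(ref[[1L]], 501L, 600L)
  read <- oracleRevComp(frag)
  hit <- toyAlign(read, ref, seedLen = 20L)
  expect_true(hit$mapped)
  expect_identical(hit$pos, 501L)
  expect_identical(hit$strand, "-")
  expect_identical(hit$mismatches, 0L)
})

test_that("mismatch fraction above 0.25 leaves the read unmapped", {
  ref <- c(chrA = strrep("A", 200L))
  # seed matches (20 A's) but 40/60 mismatches beyond it
  read <- paste0(strrep("A", 20L), strrep("C", 40L))
  hit <- toyAlign(read, ref, seedLen = 20L)
  expect_false(hit$mapped)
})

test_that("ties break to the smallest (refName, pos)", {
  dup <- strrep("ACGTT", 8L)  # 40 bp, planted twice in one sequence
  ref <- c(chrB = paste0(strrep("G", 50L), dup, strrep("C", 30L), dup),
           chrA = paste0(strrep("T", 10L), dup))
  hit <- toyAlign(dup, ref, seedLen = 20L)
  expect_identical(hit$refName, "chrA")   # name order before position
  expect_identical(hit$pos, 11L)
  hit2 <- toyAlign(dup, ref["chrB"], seedLen = 20L)
  expect_identical(hit2$pos, 51L)         # first of the two placements
})

test_that("toy placements agree with the exhaustive minimal-Hamming scan", {
  set.seed(202L)
  ref <- toyRef(seed = 202L, len = 1500L)
  refseq <- ref[[1L]]
  L <- 80L
  seedLen <- 20L
  n <- 200L
  agree <- 0L
  for (i in seq_len(n)) {
    pos <- sample.int(nchar(refseq) - L + 1L, 1L)
    read <- substr(refseq, pos, pos + L - 1L)
    # up to 2 substitutions outside the seed region of either strand, so
    # the toy contract's intact-seed precondition holds by construction
    nmut <- sample(0:2, 1L)
    if (nmut) {
      at <- sample((seedLen + 1L):(L - seedLen), nmut)
      ch <- strsplit(read, "")[[1L]]
      for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
      read <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) read <- oracleRevComp(read)
    got <- toyAlign(read, ref, seedLen = seedLen)
    want <- bruteForceAlign(read, ref)
    agree <- agree + identical(got[c("refName", "pos", "mismatches")],
                               want[c("refName", "pos", "mismatches")])
  }
  expect_identical(agree, n)
})

test_that("SAM lines carry the documented FLAG/POS/CIGAR conventions", {
  unmapped <- list(refName = NA_character_, pos = NA_integer_,
                   mismatches = NA_integer_, strand = NA_character_,
                   mapped = FALSE)
  line <- toyHitToSam("r1/1", "ACGTN", "IIIII", unmapped,
                      paired = TRUE, mateNumber = 1L, mateHit = unmapped)
  f <- strsplit(line, "\t")[[1L]]
  expect_identical(f[1L], "r1")
  flag <- as.integer(f[2L])
  expect_true(bitwAnd(flag, 0x4L) > 0L)    # unmapped
  expect_true(bitwAnd(flag, 0x1L) > 0L)    # paired
  expect_true(bitwAnd(flag, 0x40L) > 0L)   # first mate
  expect_true(bitwAnd(flag, 0x8L) > 0L)    # mate unmapped
  expect_identical(f[4L], "0")
  expect_identical(f[6L], "*")
  expect_identical(f[5L], "0")
  expectValidSamLine(line)

  fwd <- list(refName = "chr1", pos = 11L, mismatches = 0L, strand = "+",
              mapped = TRUE)
  rev <- list(refName = "chr1", pos = 222L, mismatches = 1L, strand = "-",
              mapped = TRUE)
  l1 <- toyHitToSam("p/1", "ACGTA", "ABCDE", fwd, paired = TRUE,
                    mateNumber = 1L, mateHit = rev)
  f1 <- strsplit(l1, "\t")[[1L]]
  flag1 <- as.integer(f1[2L])
  expect_identical(bitwAnd(flag1, 0x1L + 0x40L), 0x1L + 0x40L)
  expect_true(bitwAnd(flag1, 0x20L) > 0L)  # mate on reverse strand
  expect_identical(f1[4L], "11")
  expect_identical(f1[6L], "5M")
  expect_identical(f1[7L], "=")
  expect_identical(f1[8L], "222")
  expectValidSamLine(l1)

  l2 <- toyHitToSam("p/2", "ACGTA", "ABCDE", rev, paired = TRUE,
                    mateNumber = 2L, mateHit = fwd)
  f2 <- strsplit(l2, "\t")[[1L]]
  flag2 <- as.integer(f2[2L])
  expect_true(bitwAnd(flag2, 0x10L) > 0L)  # reverse strand
  expect_true(bitwAnd(flag2, 0x80L) > 0L)  # second mate
  expect_identical(f2[10L], "TACGT")       # stored reverse-complemented
  expect_identical(f2[11L], "EDCBA")       # qualities reversed
  expectValidSamLine(l2)
})

test_that("the toy backend aligns a matching pair into two mapped lines", {
  spec <- fixtureSpec(nPairs = 1L, refLength = 2000L,
                      substitutionRate = 0, seed = 7L)
  ref <- generateReference(spec)
  fx <- generatePairs(spec, ref)
  pairs <- pairJoin(readFastq(fx$fastq1), readFastq(fx$fastq2))$pairs
  part <- makePartitions(pairs, 1L)[[1L]]
  backend <- ToyBackend(ref$path)
  frag <- runBackend(backend, backendRequest(part))
  expect_s4_class(frag, "SamFragment")
  expect_length(samAlignments(frag), 2L)
  fields <- strsplit(samAlignments(frag), "\t")
  expect_true(all(vapply(fields, function(x)
    bitwAnd(as.integer(x[2L]), 0x4L) == 0L, logical(1))))
  expect_identical(as.integer(fields[[1L]][4L]), fx$truth$pos1[1L])
  expect_identical(as.integer(fields[[2L]][4L]), fx$truth$pos2[1L])
  for (l in samAlignments(frag)) expectValidSamLine(l)
  expect_true(any(startsWith(samHeader(frag), "@SQ")))
})

test_that("an empty partition yields a header-only fragment", {
  ref <- generateReference(fixtureSpec(refLength = 500L, seed = 9L))
  backend <- ToyBackend(ref$path)
  part <- new("ReadPartition", index = 0L,
              records = partialign:::PairedReads())
  frag <- runBackend(backend, backendRequest(part))
  expect_length(samAlignments(frag), 0L)
  expect_gt(length(samHeader(frag)), 0L)
})

test_that("identical requests give byte-identical fragments and persist", {
  fxl <- smallFixture(nPairs = 15L, seed = 51L)
  pairs <- pairJoin(readFastq(fxl$fx$fastq1),
                    readFastq(fxl$fx$fastq2))$pairs
  part <- makePartitions(pairs, 2L)[[2L]]
  backend <- ToyBackend(fxl$ref$path)
  wd <- tempfile("wd-")
  f1 <- runBackend(backend, backendRequest(part, workdir = wd))
  f2 <- runBackend(backend, backendRequest(part, workdir = wd))
  expect_identical(samAlignments(f1), samAlignments(f2))
  expect_identical(samHeader(f1), samHeader(f2))
  persisted <- file.path(wd, "part-00001.sam")
  expect_true(file.exists(persisted))
  expect_identical(readLines(persisted),
                   c(samHeader(f1), samAlignments(f1)))
})

test_that("a failing external executable surfaces its exit status", {
  fake <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo boom >&2", "exit 3"), fake)
  Sys.chmod(fake, "0755")
  idx <- tempfile(); file.create(idx)
  fxl <- smallFixture(nPairs = 2L, seed = 52L)
  pairs <- pairJoin(readFastq(fxl$fx$fastq1),
                    readFastq(fxl$fx$fastq2))$pairs
  part <- makePartitions(pairs, 1L)[[1L]]
  backend <- ExternalBackend(executable = fake)
  expect_error(
    runBackend(backend, backendRequest(part, indexRef = idx)),
    "exit status 3.*boom")
})

test_that("a missing index is a configuration error", {
  fxl <- smallFixture(nPairs = 2L, seed = 53L)
  pairs <- pairJoin(readFastq(fxl$fx$fastq1),
                    readFastq(fxl$fx$fastq2))$pairs
  part <- makePartitions(pairs, 1L)[[1L]]
  expect_error(
    runBackend(ExternalBackend(), backendRequest(part,
      indexRef = file.path(tempdir(), "no-such-index"))),
    "index not found")
})

test_that("invalid backend requests are rejected", {
  part <- new("ReadPartition", index = 0L,
              records = partialign:::PairedReads())
  expect_error(backendRequest(part, algorithm = "SMITH"), "MEM")
  expect_error(backendRequest(part, threads = 0L), "threads")
})
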