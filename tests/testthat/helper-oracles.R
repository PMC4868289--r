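# Shared test helpers: independent oracles and fake backends.
# Oracles deliberately avoid the package's own code paths (own reverse
# complement, own scanning loops) so they can stand as cross-checks.

# -- independent reverse complement (character-by-character) ---------------
oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            a = "t", c = "g", g = "c", t = "a", n = "n")
  paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1L]]])),
        collapse = "")
}

# -- exhaustive minimal-Hamming alignment oracle ---------------------------
# Scans every offset of every reference sequence on both strands with a
# whole-read integer comparison; keeps the first-found minimum under the
# documented tie order (forward strand first, then refName, then pos).
bruteForceAlign <- function(seq, reference, maxMismatchFrac = 0.25) {
  best <- NULL
  for (strand in c("+", "-")) {
    query <- if (strand == "+") seq else oracleRevComp(seq)
    q <- utf8ToInt(query)
    L <- length(q)
    for (rn in sort(names(reference))) {
      r <- utf8ToInt(reference[[rn]])
      if (length(r) < L) next
      for (off in seq_len(length(r) - L + 1L)) {
        mm <- sum(r[off:(off + L - 1L)] != q)
        if (is.null(best) || mm < best$mismatches)
          best <- list(refName = rn, pos = off, mismatches = mm,
                       strand = strand, mapped = TRUE)
      }
    }
  }
  if (is.null(best) ||
      best$mismatches / nchar(seq) > maxMismatchFrac)
    return(list(refName = NA_character_, pos = NA_integer_,
                mismatches = NA_integer_, strand = NA_character_,
                mapped = FALSE))
  best
}

# -- brute-force dictionary pairing oracle ---------------------------------
# Hash-map of file 1 keyed by normalized id, probed with file 2; returns
# the multiset of "key|seq1|seq2" strings, sorted.
dictionaryPairing <- function(reads1, reads2) {
  k1 <- sub("/[12]$", "", sub("[ \t].*$", "", readIds(reads1)))
  k2 <- sub("/[12]$", "", sub("[ \t].*$", "", readIds(reads2)))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(k1)) assign(k1[i], readBases(reads1)[i], envir = env)
  out <- character(0)
  for (j in seq_along(k2)) {
    if (exists(k2[j], envir = env, inherits = FALSE))
      out <- c(out, paste(k2[j], get(k2[j], envir = env),
                          readBases(reads2)[j], sep = "|"))
  }
  sort(out)
}

pairMultiset <- function(pairs)
  sort(paste(pairs@key, pairs@seq1, pairs@seq2, sep = "|"))

# -- SAM syntax checks -----------------------------------------------------
expectValidSamLine <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  expect_gte(length(f), 11L)
  flag <- suppressWarnings(as.integer(f[2L]))
  expect_false(is.na(flag))
  pos <- suppressWarnings(as.integer(f[4L]))
  expect_false(is.na(pos))
  expect_gte(pos, 0L)
  expect_true(grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[6L]))
  if (f[10L] != "*" && f[11L] != "*")
    expect_identical(nchar(f[10L]), nchar(f[11L]))
}

samAlignmentMultiset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sort(lines[!startsWith(lines, "@")])
}

# -- fake backends for orchestration tests ---------------------------------
# A recording backend writes one start/end stamp file per invocation so
# peak concurrency can be measured after the fact (works across forks).
setClass("RecordingBackend", contains = "AlignerBackend",
         representation(dir = "character", sleep = "numeric"))

setMethod("runBackend", signature("RecordingBackend", "BackendRequest"),
  function(backend, request) {
    idx <- partitionIndex(request@partition)
    t0 <- as.numeric(Sys.time())
    Sys.sleep(backend@sleep)
    t1 <- as.numeric(Sys.time())
    writeLines(c(format(t0, digits = 17), format(t1, digits = 17),
                 as.character(request@threads)),
               file.path(backend@dir, sprintf("call-%05d", idx)))
    new("SamFragment", partitionIndex = idx,
        header = "@HD\tVN:1.6\tSO:unsorted", alignments = character(0))
  })

peakConcurrency <- function(dir) {
  files <- list.files(dir, pattern = "^call-", full.names = TRUE)
  iv <- t(vapply(files, function(f)
    as.numeric(readLines(f)[1:2]), numeric(2)))
  events <- rbind(cbind(iv[, 1L], 1), cbind(iv[, 2L], -1))
  events <- events[order(events[, 1L], events[, 2L]), , drop = FALSE]
  max(cumsum(events[, 2L]))
}

recordedThreads <- function(dir) {
  files <- list.files(dir, pattern = "^call-", full.names = TRUE)
  as.integer(vapply(files, function(f) readLines(f)[3L], character(1)))
}

# A backend that fails on the first attempt for chosen partitions, then
# succeeds (exercises the retry-once policy). Attempt counts are kept on
# disk so retries survive forks.
setClass("FlakyBackend", contains = "ToyBackend",
         representation(failDir = "character", failOnce = "integer"))

setMethod("runBackend", signature("FlakyBackend", "BackendRequest"),
  function(backend, request) {
    idx <- partitionIndex(request@partition)
    marker <- file.path(backend@failDir, sprintf("attempted-%05d", idx))
    if (idx %in% backend@failOnce && !file.exists(marker)) {
      file.create(marker)
      stop("injected transient failure for partition ", idx)
    }
    callNextMethod()
  })

# A backend that always errors (exercises the abort-after-retry path).
setClass("FailingBackend", contains = "AlignerBackend")
setMethod("runBackend", signature("FailingBackend", "BackendRequest"),
  function(backend, request) stop("backend permanently down"))

# -- small fixture conveniences --------------------------------------------
smallFixture <- function(nPairs = 40L, seed = 7L, substitutionRate = 0.01,
                         refLength = 4000L, ...) {
  spec <- fixtureSpec(nPairs = nPairs, seed = seed, refLength = refLength,
                      substitutionRate = substitutionRate, ...)
  ref <- generateReference(spec)
  fx <- generatePairs(spec, ref)
  list(spec = spec, ref = ref, fx = fx)
}
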