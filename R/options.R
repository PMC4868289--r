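# Programmatic option surface: a validating constructor plus Table-style
# setter methods, mirroring the classic BwaOptions builder of distributed
# BWA wrappers. Every setter re-validates, so no RunOptions with violated
# invariants can escape.

.SORT_MODES <- c(JOIN = 0L, JOIN_SORT = 1L, SORTHDFS = 2L)
.ALGORITHMS <- c(MEM = 0L, BACKTRACK = 1L, SW = 2L)

.defaultMappers <- function() {
  n <- tryCatch(parallel::detectCores(logical = TRUE), error = function(e) 1L)
  max(1L, as.integer(if (is.na(n)) 1L else n))
}

#' Construct a validated run-option set
#'
#' Defaults follow the conventional option table of distributed BWA
#' wrappers: no reducer, automatic partitioning by block size, plain join
#' pairing, one thread per mapper (regular mode), BWA-MEM, paired-end
#' reads. \code{indexPath}, \code{inputPath} and \code{outputPath} are
#' mandatory; \code{inputPath2} is mandatory for paired-end mode.
#'
#' @param indexPath reference index prefix (external backend) or FASTA
#'   path (toy backend); mandatory.
#' @param inputPath first (or only) FASTQ input; mandatory.
#' @param outputPath output directory for the per-partition SAM files, the
#'   optional merged SAM and the run manifest; mandatory.
#' @param inputPath2 second FASTQ input (mandatory when \code{paired}).
#' @param useReducer merge per-partition SAMs into one file.
#' @param partitionCount number of partitions; \code{NA} splits by
#'   \code{blockBytes} instead.
#' @param sortMode 0 = join, 1 = join + sort-by-key, 2 = streaming
#'   interleave.
#' @param threadsPerMapper threads handed to each backend invocation
#'   (> 1 enables hybrid parallelism).
#' @param algorithm 0 = MEM, 1 = backtrack, 2 = SW.
#' @param paired paired-end input.
#' @param maxConcurrentMappers local concurrency budget; defaults to the
#'   number of available processors.
#' @param blockBytes serialized-bytes bound per partition when
#'   \code{partitionCount} is \code{NA}.
#' @return a validated \linkS4class{RunOptions}.
#' @export
bwaOptions <- function(indexPath, inputPath, outputPath,
                       inputPath2 = NA_character_, useReducer = FALSE,
                       partitionCount = NA_integer_, sortMode = 0L,
                       threadsPerMapper = 1L, algorithm = 0L, paired = TRUE,
                       maxConcurrentMappers = .defaultMappers(),
                       blockBytes = 128 * 1024^2) {
  new("RunOptions", useReducer = useReducer,
      partitionCount = as.integer(partitionCount),
      sortMode = as.integer(sortMode),
      threadsPerMapper = as.integer(threadsPerMapper),
      algorithm = as.integer(algorithm), paired = paired,
      indexPath = indexPath, inputPath = inputPath,
      inputPath2 = as.character(inputPath2), outputPath = outputPath,
      maxConcurrentMappers = as.integer(maxConcurrentMappers),
      blockBytes = as.numeric(blockBytes))
}

.setOpt <- function(options, slotName, value) {
  slot(options, slotName) <- value
  validObject(options)
  options
}

#' Builder-style option setters
#'
#' Functional setters over \linkS4class{RunOptions}; each returns a
#' modified, re-validated copy. Enum-coded setters take the integer codes
#' of the option table: sort modes join (0), join+sortByKey (1),
#' interleave (2); algorithms MEM (0), backtrack (1), SW (2).
#'
#' @param options a \linkS4class{RunOptions}.
#' @param value the new value.
#' @return the modified \linkS4class{RunOptions}.
#' @name option-setters
NULL

#' @rdname option-setters
#' @export
setUseReducer <- function(options, value)
  .setOpt(options, "useReducer", as.logical(value))

#' @rdname option-setters
#' @export
setPartitionNumber <- function(options, value)
  .setOpt(options, "partitionCount", as.integer(value))

#' @rdname option-setters
#' @export
setSortFastqReads <- function(options, value) {
  value <- as.integer(value)
  if (!value %in% .SORT_MODES)
    stop("invalid sort mode code ", value, " (expected 0, 1 or 2)")
  .setOpt(options, "sortMode", value)
}

#' @rdname option-setters
#' @export
setNumThreads <- function(options, value)
  .setOpt(options, "threadsPerMapper", as.integer(value))

#' @rdname option-setters
#' @export
setAlgorithm <- function(options, value) {
  value <- as.integer(value)
  if (!value %in% .ALGORITHMS)
    stop("invalid algorithm code ", value, " (expected 0, 1 or 2)")
  .setOpt(options, "algorithm", value)
}

#' @rdname option-setters
#' @export
setPairedReads <- function(options, value)
  .setOpt(options, "paired", as.logical(value))

#' @rdname option-setters
#' @export
setIndexPath <- function(options, value)
  .setOpt(options, "indexPath", as.character(value))

#' @rdname option-setters
#' @export
setInputPath <- function(options, value)
  .setOpt(options, "inputPath", as.character(value))

#' @rdname option-setters
#' @export
setInputPath2 <- function(options, value)
  .setOpt(options, "inputPath2", as.character(value))

#' @rdname option-setters
#' @export
setOutputPath <- function(options, value)
  .setOpt(options, "outputPath", as.character(value))

#' @rdname option-setters
#' @export
setMaxConcurrentMappers <- function(options, value)
  .setOpt(options, "maxConcurrentMappers", as.integer(value))
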