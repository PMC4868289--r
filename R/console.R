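# Console argument surface. Flag vocabulary is bit-compatible with the
# classic option table of distributed BWA wrappers (-r, -partitions, -sort,
# -sorthdfs, -threads, -mem, -aln, -bwasw, -paired, -single, -index), with
# double-dash synonyms accepted. A YAML/JSON config layer sits beneath the
# flags; explicit flags win on conflict. Positional arguments are the input
# path(s) followed by the output path.

.usageError <- function(...) {
  stop(structure(class = c("usageError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Enumerate the option bindings of the console/builder surface
#'
#' One row per run option: the builder setter name, the console flag
#' spelling, the documented default and the RunOptions field it binds to.
#' Used by the interface-fidelity tests to assert the bijection between
#' the option table and \linkS4class{RunOptions}.
#'
#' @return a data.frame with columns \code{api_name}, \code{console_flag},
#'   \code{default}, \code{field}.
#' @export
optionBindings <- function() {
  data.frame(
    api_name = c("setUseReducer", "setPartitionNumber", "setSortFastqReads",
                 "setNumThreads", "setAlgorithm", "setPairedReads",
                 "setIndexPath", "setInputPath", "setInputPath2",
                 "setOutputPath", "setMaxConcurrentMappers"),
    console_flag = c("-r", "none |-partitions <num>",
                     "none |-sort |-sorthdfs", "-threads <num>",
                     "-mem |-aln |-bwasw", "-paired |-single",
                     "-index <prefix>", "positional", "positional",
                     "positional", "-mappers <num>"),
    default = c("FALSE", "auto (block size)", "0 (join)", "1",
                "0 (MEM)", "paired", "(mandatory)", "(mandatory)",
                "(mandatory when paired)", "(mandatory)",
                "available processors"),
    field = c("useReducer", "partitionCount", "sortMode",
              "threadsPerMapper", "algorithm", "paired", "indexPath",
              "inputPath", "inputPath2", "outputPath",
              "maxConcurrentMappers"),
    stringsAsFactors = FALSE)
}

.readConfigFile <- function(path) {
  if (!file.exists(path)) .usageError("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) .usageError("config file must hold a mapping: ", path)
  known <- optionBindings()$field
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    .usageError("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

.needValue <- function(argv, i, flag) {
  if (i + 1L > length(argv))
    .usageError("flag ", flag, " requires a value")
  argv[i + 1L]
}

#' Parse console arguments into a validated RunOptions
#'
#' Accepts the single-dash flag vocabulary (double-dash synonyms allowed):
#' \code{-r} (use reducer), \code{-partitions <num>}, \code{-sort} /
#' \code{-sorthdfs}, \code{-threads <num>} (hybrid mode when > 1),
#' \code{-mem} / \code{-aln} / \code{-bwasw}, \code{-paired} /
#' \code{-single}, \code{-index <prefix>} (mandatory),
#' \code{-mappers <num>}, \code{-config <yaml|json>}. Positional
#' arguments: \code{IN1 [IN2] OUT} (two inputs required in paired mode).
#' Precedence: explicit flag > config file > default. Usage violations
#' raise a condition of class \code{usageError}.
#'
#' @param argv character vector of command-line tokens.
#' @return a validated \linkS4class{RunOptions}.
#' @export
parseConsole <- function(argv) {
  flags <- list()
  positional <- character(0)
  configPath <- NULL
  exclusive <- list(algorithm = character(0), sortMode = character(0),
                    paired = character(0))
  i <- 1L
  while (i <= length(argv)) {
    tok <- sub("^--", "-", argv[i])
    consumed <- 1L
    switch(tok,
      "-r" = { flags$useReducer <- TRUE },
      "-partitions" = {
        flags$partitionCount <- .needValue(argv, i, tok); consumed <- 2L },
      "-sort" = {
        flags$sortMode <- 1L
        exclusive$sortMode <- c(exclusive$sortMode, tok) },
      "-sorthdfs" = {
        flags$sortMode <- 2L
        exclusive$sortMode <- c(exclusive$sortMode, tok) },
      "-threads" = {
        flags$threadsPerMapper <- .needValue(argv, i, tok); consumed <- 2L },
      "-mem" = {
        flags$algorithm <- 0L
        exclusive$algorithm <- c(exclusive$algorithm, tok) },
      "-aln" = {
        flags$algorithm <- 1L
        exclusive$algorithm <- c(exclusive$algorithm, tok) },
      "-bwasw" = {
        flags$algorithm <- 2L
        exclusive$algorithm <- c(exclusive$algorithm, tok) },
      "-paired" = {
        flags$paired <- TRUE
        exclusive$paired <- c(exclusive$paired, tok) },
      "-single" = {
        flags$paired <- FALSE
        exclusive$paired <- c(exclusive$paired, tok) },
      "-index" = {
        flags$indexPath <- .needValue(argv, i, tok); consumed <- 2L },
      "-mappers" = {
        flags$maxConcurrentMappers <- .needValue(argv, i, tok)
        consumed <- 2L },
      "-config" = {
        configPath <- .needValue(argv, i, tok); consumed <- 2L },
      {
        if (startsWith(tok, "-"))
          .usageError("unknown flag: ", argv[i])
        positional <- c(positional, argv[i])
      })
    i <- i + consumed
  }
  for (grp in names(exclusive)) {
    seen <- unique(exclusive[[grp]])
    if (length(seen) > 1L)
      .usageError("mutually exclusive flags given: ",
                  paste(seen, collapse = " with "))
  }
  cfg <- if (!is.null(configPath)) .readConfigFile(configPath) else list()
  getOpt <- function(name, default) {
    if (!is.null(flags[[name]])) flags[[name]]
    else if (!is.null(cfg[[name]])) cfg[[name]]
    else default
  }
  paired <- as.logical(getOpt("paired", TRUE))
  nPos <- length(positional)
  expected <- if (paired) 3L else 2L
  if (nPos != expected)
    .usageError("expected ", expected, " positional arguments (",
                if (paired) "IN1 IN2 OUT" else "IN OUT", "), got ", nPos)
  indexPath <- getOpt("indexPath", NA_character_)
  if (is.na(indexPath) || !nzchar(indexPath))
    .usageError("-index <prefix> is a mandatory option")
  asInt <- function(x, what) {
    v <- suppressWarnings(as.integer(x))
    if (is.na(v) && !is.na(x)) .usageError(what, " must be an integer, got ", x)
    v
  }
  tryCatch(
    bwaOptions(
      indexPath = indexPath,
      inputPath = positional[1L],
      inputPath2 = if (paired) positional[2L] else
        as.character(getOpt("inputPath2", NA_character_)),
      outputPath = positional[nPos],
      useReducer = as.logical(getOpt("useReducer", FALSE)),
      partitionCount = asInt(getOpt("partitionCount", NA_integer_),
                             "-partitions"),
      sortMode = asInt(getOpt("sortMode", 0L), "sort mode"),
      threadsPerMapper = asInt(getOpt("threadsPerMapper", 1L), "-threads"),
      algorithm = asInt(getOpt("algorithm", 0L), "algorithm"),
      paired = paired,
      maxConcurrentMappers = asInt(
        getOpt("maxConcurrentMappers", .defaultMappers()), "-mappers"),
      blockBytes = as.numeric(getOpt("blockBytes", 128 * 1024^2))),
    error = function(e) {
      if (inherits(e, "usageError")) stop(e)
      .usageError("invalid options: ", conditionMessage(e))
    })
}
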