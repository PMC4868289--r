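#' Execute one mapper invocation on a backend
#'
#' The single dispatch point of the backend contract: turn a
#' \linkS4class{BackendRequest} into a \linkS4class{SamFragment}, persisting
#' the fragment under the request's \code{workdir} as
#' \code{part-<index>.sam}. Implementations must be deterministic for the
#' toy backend and surface external-process diagnostics on failure.
#'
#' @param backend an \linkS4class{AlignerBackend}.
#' @param request a \linkS4class{BackendRequest}.
#' @return a \linkS4class{SamFragment}.
#' @export
setGeneric("runBackend", function(backend, request)
  standardGeneric("runBackend"))

#' @rdname accessors
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname accessors
#' @export
setGeneric("recordBytes", function(x) standardGeneric("recordBytes"))

#' @rdname accessors
#' @export
setGeneric("partitionIndex", function(x) standardGeneric("partitionIndex"))

#' @rdname accessors
#' @export
setGeneric("partitionRecords", function(x) standardGeneric("partitionRecords"))

#' @rdname accessors
#' @export
setGeneric("samHeader", function(x) standardGeneric("samHeader"))

#' @rdname accessors
#' @export
setGeneric("samAlignments", function(x) standardGeneric("samAlignments"))

#' @rdname accessors
#' @export
setGeneric("pairsEmitted", function(x) standardGeneric("pairsEmitted"))

#' @rdname accessors
#' @export
setGeneric("orphanCounts", function(x) standardGeneric("orphanCounts"))
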