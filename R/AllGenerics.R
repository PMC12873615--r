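#' @rdname OverviewDataset
#' @export
setGeneric("reviews", function(x) standardGeneric("reviews"))

#' @rdname OverviewDataset
#' @export
setGeneric("references", function(x) standardGeneric("references"))

#' @rdname OverviewDataset
#' @export
setGeneric("inclusions", function(x) standardGeneric("inclusions"))

#' @rdname OverviewDataset
#' @export
setGeneric("mainOutcome", function(x) standardGeneric("mainOutcome"))

#' @rdname OverviewDataset
#' @export
setGeneric("outcomeUniverse", function(x) standardGeneric("outcomeUniverse"))

#' @rdname evidenceMatrix-accessors
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' @rdname evidenceMatrix-accessors
#' @export
setGeneric("rowMode", function(x) standardGeneric("rowMode"))

#' @rdname evidenceMatrix-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname matrixAdjustments
#' @export
setGeneric("adjustScope", function(x) standardGeneric("adjustScope"))

#' @rdname matrixAdjustments
#' @export
setGeneric("collapseThreads", function(x) standardGeneric("collapseThreads"))

#' @rdname matrixAdjustments
#' @export
setGeneric("markStructuralMissingness",
           function(x) standardGeneric("markStructuralMissingness"))

#' @rdname cca
#' @export
setGeneric("overallCCA", function(x, ...) standardGeneric("overallCCA"))

#' @rdname cca
#' @export
setGeneric("pairwiseCCA", function(x, ...) standardGeneric("pairwiseCCA"))

#' @rdname CCAResult
#' @export
setGeneric("ccaValue", function(x) standardGeneric("ccaValue"))

#' @rdname CCAResult
#' @export
setGeneric("pairwiseValues", function(x) standardGeneric("pairwiseValues"))

#' @rdname CCAResult
#' @export
setGeneric("pairwiseSummary", function(x) standardGeneric("pairwiseSummary"))

#' @rdname SweepResult
#' @export
setGeneric("sweepRecords", function(x) standardGeneric("sweepRecords"))

#' @rdname SweepResult
#' @export
setGeneric("sweepResults", function(x) standardGeneric("sweepResults"))
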