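#' Infer per-block output shapes
#'
#' @param object a [ModelGraph-class].
#' @param ... unused.
#' @return data.frame with one record per block: `block`, `name`, `stage`,
#'   `height`, `width`, `channels`. The final record is the output block with
#'   the input spatial dims and 1 channel.
#' @export
setGeneric("inferShapes", function(object, ...) standardGeneric("inferShapes"))

#' Export the layer audit table
#'
#' @param object a [ModelGraph-class].
#' @param ... unused.
#' @return data.frame with columns `Block`, `Name`, `Filters`, `Dimensions`,
#'   `Params`, `Operation`, mirroring the reference layer table for diffing.
#' @export
setGeneric("auditTable", function(object, ...) standardGeneric("auditTable"))

#' Fold-plan accessors
#'
#' `foldSizes` returns the per-fold sizes; `foldIndices` the sample indices
#' assigned to one fold.
#'
#' @param object a [FoldPlan-class].
#' @param fold fold id in `1..k`.
#' @name foldPlan-accessors
NULL

#' @rdname foldPlan-accessors
#' @export
setGeneric("foldSizes", function(object) standardGeneric("foldSizes"))

#' @rdname foldPlan-accessors
#' @export
setGeneric("foldIndices", function(object, fold) standardGeneric("foldIndices"))

#' Metric-report accessors
#'
#' Fold-mean, fold-standard-deviation and per-fold metric values of a
#' [MetricReport-class].
#'
#' @param object a [MetricReport-class].
#' @name metricReport-accessors
NULL

#' @rdname metricReport-accessors
#' @export
setGeneric("meanMetrics", function(object) standardGeneric("meanMetrics"))

#' @rdname metricReport-accessors
#' @export
setGeneric("sdMetrics", function(object) standardGeneric("sdMetrics"))

#' @rdname metricReport-accessors
#' @export
setGeneric("perFoldMetrics", function(object) standardGeneric("perFoldMetrics"))

#' Training-history accessor
#'
#' @param object a [TrainHistory-class].
#' @name trainHistory-accessors
NULL

#' @rdname trainHistory-accessors
#' @export
setGeneric("historyTable", function(object) standardGeneric("historyTable"))

#' Dataset-index accessor
#'
#' @param object a [DatasetIndex-class].
#' @name datasetIndex-accessors
NULL

#' @rdname datasetIndex-accessors
#' @export
setGeneric("sampleRecords", function(object) standardGeneric("sampleRecords"))
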