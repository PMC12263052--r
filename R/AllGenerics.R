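#' @include AllClasses.R
NULL

#' Accessors for mrchain objects
#'
#' Small accessor family in the usual S4 style: prefer these over direct
#' slot access.
#'
#' @param x an mrchain object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("dropped", function(x) standardGeneric("dropped"))

#' @rdname accessors
#' @export
setGeneric("qcTally", function(x) standardGeneric("qcTally"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname accessors
#' @param method method label of the estimate to extract.
#' @export
setGeneric("estimate", function(x, method) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("qTest", function(x) standardGeneric("qTest"))

#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

setMethod("traitId", "SummaryDataset", function(x) x@traitId)
setMethod("traitType", "SummaryDataset", function(x) x@traitType)
setMethod("records", "SummaryDataset", function(x) x@records)
setMethod("nVariants", "SummaryDataset", function(x) nrow(x@records))
setMethod("variantIds", "SummaryDataset", function(x) x@records$variant_id)
setMethod("qcTally", "SummaryDataset", function(x) x@tally)

setMethod("nVariants", "HarmonizedSet", function(x) length(x@variantIds))
setMethod("variantIds", "HarmonizedSet", function(x) x@variantIds)
setMethod("dropped", "HarmonizedSet", function(x) x@dropped)

setMethod("estimates", "MRSuiteResult", function(x) x@estimates)
setMethod("estimate", "MRSuiteResult", function(x, method) {
  if (!method %in% names(x@estimates)) {
    reason <- if (method %in% names(x@skipped)) x@skipped[[method]]
              else "not computed"
    .mrError(sprintf("method '%s' unavailable (%s)", method, reason),
             "mrMissingEstimateError")
  }
  x@estimates[[method]]
})
setMethod("qTest", "MRSuiteResult", function(x) x@q)
setMethod("eggerIntercept", "MRSuiteResult", function(x) x@eggerIntercept)
setMethod("qcTally", "MRSuiteResult", function(x) x@tally)
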