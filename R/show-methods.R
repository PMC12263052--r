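#' @include AllClasses.R
NULL

setMethod("show", "SummaryDataset", function(object) {
  cat(sprintf("SummaryDataset '%s' (%s): %d variant(s)\n",
              object@traitId, object@traitType, nrow(object@records)))
  if (length(object@tally) && sum(object@tally) > 0) {
    t <- object@tally[object@tally > 0]
    cat("  dropped on read:",
        paste(sprintf("%s=%d", names(t), t), collapse = ", "), "\n")
  }
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet %s ~ %s: k = %d, %d dropped\n",
              object@exposureId, object@outcomeId,
              length(object@variantIds), nrow(object@dropped)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s (k=%d): beta %.4f (se %.4f), OR %.3f (%.3f–%.3f), p %.3g\n",
              object@method, object@k, object@beta, object@se,
              object@or, object@ciLow, object@ciHigh, object@pval))
})

setMethod("show", "QTest", function(object) {
  cat(sprintf("Cochran Q = %.3f on %d df, p = %s\n", object@Q, object@df,
              if (is.na(object@pval)) "NA" else sprintf("%.3g", object@pval)))
})

setMethod("show", "EggerIntercept", function(object) {
  cat(sprintf("Egger intercept %.4f (se %.4f), p = %.3g\n",
              object@intercept, object@se, object@pval))
})

setMethod("show", "MRSuiteResult", function(object) {
  cat(sprintf("MRSuiteResult [%s] %s -> %s, k = %d\n", object@direction,
              object@exposureId, object@outcomeId, object@k))
  for (e in object@estimates) { cat("  "); show(e) }
  if (length(object@skipped))
    cat("  skipped:", paste(sprintf("%s (%s)", names(object@skipped),
                                    object@skipped), collapse = ", "), "\n")
  cat("  "); show(object@q)
  if (!is.null(object@eggerIntercept)) { cat("  "); show(object@eggerIntercept) }
})

setMethod("show", "DirectionClassification", function(object) {
  cat(sprintf("%s: %s (forward %s, reverse %s)%s\n", object@pairId,
              object@label,
              ifelse(object@forwardSig, "sig", "ns"),
              ifelse(object@reverseSig, "sig", "ns"),
              if (!object@mediationEligible) " [mediation ineligible]" else ""))
})

setMethod("show", "MediationEstimate", function(object) {
  prop <- if (object@propUndefined) "undefined"
          else sprintf("%.2f%% (se %.2f%%)", 100 * object@propMediated,
                       100 * object@propSe)
  cat(sprintf("Mediation [%s] %s -> %s -> %s\n", object@method,
              object@exposureId, object@mediatorId, object@outcomeId))
  cat(sprintf("  total %.4f, indirect %.4f (se %.4f, p %.3g), direct %.4f\n",
              object@betaTotal, object@indirect, object@indirectSe,
              object@pvalIndirect, object@direct))
  cat(sprintf("  proportion mediated: %s%s\n", prop,
              if (!object@signConsistent) " [sign-inconsistent]" else ""))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d SNPs/block, n = (%g, %g, %g), theta = (xm %.2f, my %.2f,",
    " direct %.2f), pleiotropy %s, reverse %.2f, seed %d\n"),
    object@nSnps, object@nX, object@nM, object@nY, object@thetaXm,
    object@thetaMy, object@thetaDirect, object@pleiotropy,
    object@reverseTheta, object@seed))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix over %d variant(s)\n", length(object@variantIds)))
})
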