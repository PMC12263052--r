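#' @import methods
NULL

.DROP_REASONS <- c("allele_mismatch", "palindromic_ambiguous",
                   "missing_in_outcome", "duplicate")

.CANONICAL_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")

.MR_METHODS <- c("wald_ratio", "ivw_fixed", "ivw_random", "egger",
                 "weighted_median", "weighted_mode", "mvmr_ivw")

#' SummaryDataset: one trait's GWAS summary statistics
#'
#' Container for validated per-variant association records of a single GWAS:
#' one row per variant with identifier, coordinates, allele coding, effect
#' allele frequency, effect size, standard error, p-value and sample size.
#' Effect sizes are per effect-allele copy, on the log-odds scale for binary
#' traits and in SD units for continuous traits.
#'
#' @slot traitId character(1) trait identifier.
#' @slot traitType `"binary"` or `"continuous"`; fixes the scale of `beta`.
#' @slot records data.frame with the canonical columns (`variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`), unique by `variant_id`.
#' @slot tally named numeric; QC counts of rows dropped on read.
#' @export
setClass("SummaryDataset",
  representation(traitId = "character", traitType = "character",
                 records = "data.frame", tally = "numeric"),
  prototype(traitType = "continuous", tally = numeric(0)))

setValidity("SummaryDataset", function(object) {
  msg <- character(0)
  if (length(object@traitId) != 1L || is.na(object@traitId))
    msg <- c(msg, "traitId must be a single string")
  if (!object@traitType %in% c("binary", "continuous"))
    msg <- c(msg, "traitType must be 'binary' or 'continuous'")
  r <- object@records
  missing_cols <- setdiff(.CANONICAL_COLS, names(r))
  if (length(missing_cols))
    return(paste("records lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$variant_id))
      msg <- c(msg, "duplicate variant_id in records")
    if (any(is.na(r$se) | r$se <= 0))
      msg <- c(msg, "all se must be > 0")
    if (any(is.na(r$pval) | r$pval <= 0 | r$pval > 1))
      msg <- c(msg, "all pval must be in (0, 1]")
    if (any(r$effect_allele == r$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    bad_eaf <- !is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1)
    if (any(bad_eaf))
      msg <- c(msg, "eaf must be missing or in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: allele-aligned exposure/outcome effect pairs
#'
#' Result of harmonizing an exposure and an outcome GWAS to the exposure's
#' effect-allele convention: parallel vectors of exposure and outcome effects
#' and standard errors over the shared, aligned variants, plus a record of
#' which overlapping variants were dropped and why.
#'
#' @slot exposureId,outcomeId character(1) trait identifiers.
#' @slot variantIds character; aligned variant identifiers (exposure order).
#' @slot bx,seX exposure effects and standard errors.
#' @slot by,seY outcome effects (re-oriented to the exposure effect allele)
#'   and standard errors.
#' @slot dropped data.frame(variant_id, reason); reasons are one of
#'   `allele_mismatch`, `palindromic_ambiguous`, `missing_in_outcome`,
#'   `duplicate`.
#' @export
setClass("HarmonizedSet",
  representation(exposureId = "character", outcomeId = "character",
                 variantIds = "character", bx = "numeric", seX = "numeric",
                 by = "numeric", seY = "numeric", dropped = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  k <- length(object@variantIds)
  msg <- character(0)
  if (k < 1L) msg <- c(msg, "at least one harmonized variant required")
  lens <- c(length(object@bx), length(object@seX),
            length(object@by), length(object@seY))
  if (any(lens != k)) msg <- c(msg, "all effect/SE vectors must have length k")
  if (any(object@seX <= 0) || any(object@seY <= 0))
    msg <- c(msg, "standard errors must be > 0")
  if (nrow(object@dropped) &&
      !all(object@dropped$reason %in% .DROP_REASONS))
    msg <- c(msg, "invalid drop reason")
  if (length(msg)) msg else TRUE
})

#' MREstimate: one causal-effect estimate
#'
#' A single Mendelian-randomization estimate: method label, number of
#' instruments, the causal effect on the log-odds (binary outcome) or SD
#' scale with its standard error and two-sided normal p-value, and the
#' odds-ratio transform `exp(beta)` with 95% Wald confidence limits.
#'
#' @export
setClass("MREstimate",
  representation(method = "character", k = "integer", beta = "numeric",
                 se = "numeric", pval = "numeric", or = "numeric",
                 ciLow = "numeric", ciHigh = "numeric"))

setValidity("MREstimate", function(object) {
  msg <- character(0)
  if (!object@method %in% .MR_METHODS)
    msg <- c(msg, "unknown method label")
  if (object@se < 0) msg <- c(msg, "se must be >= 0")
  if (object@se > 0 &&
      !(object@ciLow < object@or && object@or < object@ciHigh))
    msg <- c(msg, "CI must bracket the OR when se > 0")
  if (abs(object@or - exp(object@beta)) > 1e-12 * max(1, object@or))
    msg <- c(msg, "or must equal exp(beta)")
  if (is.na(object@pval) || object@pval <= 0 || object@pval > 1)
    msg <- c(msg, "pval must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' QTest: Cochran heterogeneity test
#'
#' Cochran's Q over per-variant ratio estimates with k - 1 degrees of
#' freedom and an upper-tail chi-square p-value (NA when df = 0).
#' @export
setClass("QTest",
  representation(Q = "numeric", df = "integer", pval = "numeric"))

setValidity("QTest", function(object) {
  if (object@Q < -1e-12) return("Q must be >= 0")
  if (object@df < 0L) return("df must be >= 0")
  TRUE
})

#' EggerIntercept: directional-pleiotropy test
#'
#' The intercept of the MR-Egger regression with its standard error and
#' two-sided p-value; an intercept away from zero indicates directional
#' horizontal pleiotropy of the instruments.
#' @export
setClass("EggerIntercept",
  representation(intercept = "numeric", se = "numeric", pval = "numeric"))

setValidity("EggerIntercept", function(object) {
  if (object@se <= 0) return("se must be > 0") else TRUE
})

#' MRSuiteResult: the full estimator battery for one pair
#'
#' All estimators and sensitivity statistics computed on one harmonized
#' exposure-outcome pair, together with instrument-QC bookkeeping.
#'
#' @slot estimates named list of [MREstimate-class] (one per method run).
#' @slot skipped named character; methods not run and the reason.
#' @slot q [QTest-class] heterogeneity test.
#' @slot eggerIntercept [EggerIntercept-class] or NULL if MR-Egger skipped.
#' @slot fStats named numeric; per-instrument F statistics of the retained
#'   instruments.
#' @slot tally named numeric; variant counts through the selection pipeline.
#' @slot harmonized the underlying [HarmonizedSet-class].
#' @slot direction `"forward"` or `"reverse"`.
#' @export
setClass("MRSuiteResult",
  representation(exposureId = "character", outcomeId = "character",
                 direction = "character", k = "integer",
                 estimates = "list", skipped = "character",
                 q = "QTest", eggerIntercept = "ANY",
                 fStats = "numeric", tally = "numeric",
                 harmonized = "HarmonizedSet"))

setValidity("MRSuiteResult", function(object) {
  msg <- character(0)
  if (!object@direction %in% c("forward", "reverse"))
    msg <- c(msg, "direction must be 'forward' or 'reverse'")
  ks <- vapply(object@estimates, function(e) e@k, integer(1))
  if (length(ks) && any(ks != object@k))
    msg <- c(msg, "all estimates must share the suite's k")
  if (length(msg)) msg else TRUE
})

#' DirectionClassification: forward/reverse significance truth table
#'
#' Classification of one exposure-outcome pair from its forward and reverse
#' MR results: `forward_only`, `reverse_only`, `bidirectional` or `null`.
#' Bidirectional pairs are flagged ineligible for mediation analysis.
#' @export
setClass("DirectionClassification",
  representation(pairId = "character", forwardSig = "logical",
                 reverseSig = "logical", label = "character",
                 mediationEligible = "logical"))

setValidity("DirectionClassification", function(object) {
  want <- if (object@forwardSig && object@reverseSig) "bidirectional"
          else if (object@forwardSig) "forward_only"
          else if (object@reverseSig) "reverse_only"
          else "null"
  if (object@label != want) return("label inconsistent with significance flags")
  TRUE
})

#' MediationEstimate: decomposition of a total effect through one mediator
#'
#' Total, direct and indirect (mediated) effects for one exposure ->
#' mediator -> outcome triplet, with the proportion mediated and
#' delta-method standard errors. Proportions outside [0, 1] and
#' sign-inconsistent indirect effects are flagged, never truncated.
#'
#' @slot method `"product"` (product of coefficients) or `"difference"`
#'   (total minus the multivariable-MR direct effect).
#' @export
setClass("MediationEstimate",
  representation(exposureId = "character", mediatorId = "character",
                 outcomeId = "character", method = "character",
                 betaTotal = "numeric", betaXm = "numeric", betaMy = "numeric",
                 indirect = "numeric", indirectSe = "numeric",
                 direct = "numeric", propMediated = "numeric",
                 propSe = "numeric", pvalIndirect = "numeric",
                 signConsistent = "logical", propUndefined = "logical"))

setValidity("MediationEstimate", function(object) {
  msg <- character(0)
  if (!object@method %in% c("product", "difference"))
    msg <- c(msg, "method must be 'product' or 'difference'")
  if (!is.na(object@indirectSe) && object@indirectSe < 0)
    msg <- c(msg, "indirectSe must be >= 0")
  if (object@method == "product" && !object@propUndefined) {
    if (abs(object@indirect - object@betaXm * object@betaMy) > 1e-12)
      msg <- c(msg, "product indirect must equal betaXm * betaMy")
  }
  if (length(msg)) msg else TRUE
})

#' LDMatrix: pairwise squared correlations between variants
#'
#' Symmetric matrix of LD r-squared values with unit diagonal, used by
#' [ldClump()]. The package never computes LD from genotypes; the matrix is
#' supplied by the caller (e.g. from a reference panel tool).
#' @export
setClass("LDMatrix",
  representation(variantIds = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  n <- length(object@variantIds)
  if (!all(dim(m) == c(n, n))) return("r2 must be n x n")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("r2 values must be in [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) return("r2 must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) return("r2 diagonal must be 1")
  TRUE
})

#' SimConfig: structural model and GWAS design for the synthetic generator
#'
#' Parameters of the simulated X -> M -> Y structural model and of the
#' three GWAS that measure it. See the methods vignette for the rationale
#' behind the defaults.
#'
#' @slot nSnps candidate instruments per trait-specific block (the exposure,
#'   the mediator and the outcome each get a disjoint block of this size).
#' @slot nX,nM,nY GWAS sample sizes for exposure, mediator and outcome.
#' @slot thetaXm,thetaMy,thetaDirect structural effects X->M, M->Y and the
#'   direct X->Y path; the implied total effect is
#'   `thetaDirect + thetaXm * thetaMy`.
#' @slot pleiotropy `"none"`, `"balanced"` or `"directional"` direct
#'   variant-to-outcome effects on the exposure instruments.
#' @slot pleiotropyScale SD (and, for directional, mean) of the pleiotropic
#'   effects.
#' @slot mafRange uniform sampling range of minor-allele frequencies.
#' @slot exposureH2 variance of each trait explained by its own instrument
#'   block.
#' @slot reverseTheta propagation of the outcome's instrument block into the
#'   exposure (0 = no reverse causation).
#' @slot seed mandatory integer seed; all randomness derives from it.
#' @export
setClass("SimConfig",
  representation(nSnps = "integer", nX = "numeric", nM = "numeric",
                 nY = "numeric", thetaXm = "numeric", thetaMy = "numeric",
                 thetaDirect = "numeric", pleiotropy = "character",
                 pleiotropyScale = "numeric", mafRange = "numeric",
                 exposureH2 = "numeric", reverseTheta = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (any(c(object@nX, object@nM, object@nY) <= 0))
    msg <- c(msg, "sample sizes must be > 0")
  if (!object@pleiotropy %in% c("none", "balanced", "directional"))
    msg <- c(msg, "pleiotropy must be none/balanced/directional")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must lie within (0, 0.5]")
  if (object@exposureH2 <= 0 || object@exposureH2 >= 1)
    msg <- c(msg, "exposureH2 must be in (0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' InstrumentCriteria: instrument selection and QC thresholds
#'
#' Thresholds applied, in order, by the selection pipeline: genome-wide
#' p-value cut (strict `<`), confounder exclusion list, greedy LD clumping
#' (prune when r-squared exceeds `clumpR2` AND distance is within
#' `clumpWindowKb` on the same chromosome) and the weak-instrument F filter
#' (retain strictly `F > fMin`, with `F = (beta/se)^2`).
#' @export
setClass("InstrumentCriteria",
  representation(pThreshold = "numeric", clumpR2 = "numeric",
                 clumpWindowKb = "numeric", fMin = "numeric",
                 exclusionIds = "character"))

setValidity("InstrumentCriteria", function(object) {
  msg <- character(0)
  if (object@pThreshold <= 0 || object@pThreshold > 1)
    msg <- c(msg, "pThreshold must be in (0, 1]")
  if (object@clumpR2 < 0 || object@clumpR2 > 1)
    msg <- c(msg, "clumpR2 must be in [0, 1]")
  if (object@clumpWindowKb <= 0) msg <- c(msg, "clumpWindowKb must be > 0")
  if (object@fMin < 0) msg <- c(msg, "fMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn InstrumentCriteria-class Constructor with the pipeline's
#'   default thresholds (p < 5e-5, r2 0.001, 10,000 kb window, F > 10).
#' @param pThreshold,clumpR2,clumpWindowKb,fMin,exclusionIds see slots.
#' @export
instrumentCriteria <- function(pThreshold = 5e-5, clumpR2 = 0.001,
                               clumpWindowKb = 10000, fMin = 10,
                               exclusionIds = character(0)) {
  new("InstrumentCriteria", pThreshold = pThreshold, clumpR2 = clumpR2,
      clumpWindowKb = clumpWindowKb, fMin = fMin,
      exclusionIds = as.character(exclusionIds))
}
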