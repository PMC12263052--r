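#' @include AllClasses.R conditions.R gwas-io.R instruments.R estimators.R
NULL

.HEADLINE <- "ivw_random"   # significance calls use random-effects IVW

#' Run the full MR estimator battery for one exposure-outcome pair
#'
#' Applies the instrument-selection pipeline in the fixed order
#' p-value threshold -> confounder exclusion -> LD clumping -> F filter,
#' harmonizes the survivors against the outcome, then runs every requested
#' estimator whose instrument-count precondition is met (IVW needs k >= 1;
#' MR-Egger, weighted median and weighted mode need k >= 3). Methods
#' skipped for insufficient instruments are recorded with the reason.
#'
#' @param exposure,outcome [SummaryDataset-class] objects.
#' @param criteria an [InstrumentCriteria-class].
#' @param ld optional [LDMatrix-class] for clumping; when absent, variants
#'   are treated as independent.
#' @param nBoot bootstrap draws for the median/mode SEs.
#' @param seed seed for the bootstrap resampling.
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode")` to run; IVW is always reported in both fixed and
#'   random flavors.
#' @param direction `"forward"` or `"reverse"` (bookkeeping).
#' @param palindromeEafWindow passed to [harmonize()].
#' @return An [MRSuiteResult-class].
#' @export
runMrSuite <- function(exposure, outcome, criteria = instrumentCriteria(),
                       ld = NULL, nBoot = 1000, seed = 1,
                       methods = c("ivw", "egger", "weighted_median",
                                   "weighted_mode"),
                       direction = "forward",
                       palindromeEafWindow = c(0.42, 0.58)) {
  methods <- match.arg(methods, several.ok = TRUE)
  tally <- c(input = nVariants(exposure))
  d <- selectByPvalue(exposure, criteria@pThreshold)
  tally["after_pvalue"] <- nVariants(d)
  d <- excludeSnps(d, criteria@exclusionIds)
  tally["after_exclusion"] <- nVariants(d)
  d <- ldClump(d, ld, criteria)
  tally["after_clump"] <- nVariants(d)
  ff <- fFilter(d, criteria@fMin)
  d <- ff$dataset
  tally["after_f_filter"] <- nVariants(d)
  if (nVariants(d) < 1L)
    .mrError(sprintf("no instruments survived QC for %s", traitId(exposure)),
             "mrNoInstrumentsError", data = list(tally = tally))
  h <- tryCatch(harmonize(d, outcome, palindromeEafWindow),
                mrchainError = function(e) {
                  .mrError(sprintf(
                    "no instruments after harmonization for %s vs %s (%s)",
                    traitId(exposure), traitId(outcome), conditionMessage(e)),
                    "mrNoInstrumentsError", data = list(tally = tally))
                })
  tally["harmonized"] <- nVariants(h)
  k <- nVariants(h)

  ests <- list()
  skipped <- character(0)
  ivw <- mrIvw(h, "random")
  if ("ivw" %in% methods) {
    ests$ivw_fixed <- mrIvw(h, "fixed")$estimate
    ests$ivw_random <- ivw$estimate
  }
  eggerInt <- NULL
  for (m in setdiff(methods, "ivw")) {
    if (k < 3L) {
      skipped[m] <- "insufficient_instruments"
      next
    }
    if (m == "egger") {
      eg <- mrEgger(h)
      ests$egger <- eg$estimate
      eggerInt <- eg$intercept
    } else if (m == "weighted_median") {
      ests$weighted_median <- weightedMedian(h, nBoot, seed)
    } else if (m == "weighted_mode") {
      ests$weighted_mode <- weightedMode(h, nBoot = nBoot, seed = seed + 1L)
    }
  }

  new("MRSuiteResult",
      exposureId = traitId(exposure), outcomeId = traitId(outcome),
      direction = direction, k = as.integer(k), estimates = ests,
      skipped = skipped, q = ivw$q, eggerIntercept = eggerInt,
      fStats = ff$f[variantIds(h)], tally = tally, harmonized = h)
}

#' Screen a panel of exposures against one outcome
#'
#' Runs [runMrSuite()] independently for every exposure; per-exposure
#' failures (e.g. too few instruments) are recorded, never fatal.
#' "Significant" means the random-effects IVW p-value is below `alpha`
#' (nominal, no multiple-testing correction, matching common screening
#' practice); [panelTable()] additionally reports Benjamini-Hochberg FDR.
#'
#' @param exposures list of [SummaryDataset-class] objects.
#' @param outcome a [SummaryDataset-class].
#' @param criteria,ld,nBoot,seed,methods,direction,palindromeEafWindow
#'   passed to [runMrSuite()].
#' @param alpha screening significance level in (0, 1).
#' @return list with `results` (suites sorted by IVW p ascending),
#'   `significant` (exposure ids flagged), and `errors` (named character of
#'   per-exposure failure messages).
#' @export
runPanel <- function(exposures, outcome, criteria = instrumentCriteria(),
                     ld = NULL, alpha = 0.05, nBoot = 1000, seed = 1,
                     methods = c("ivw", "egger", "weighted_median",
                                 "weighted_mode"),
                     direction = "forward",
                     palindromeEafWindow = c(0.42, 0.58)) {
  if (alpha <= 0 || alpha > 1)
    .mrError("alpha must be in (0, 1]", "mrConfigError")
  results <- list()
  errors <- character(0)
  for (x in exposures) {
    res <- tryCatch(
      runMrSuite(x, outcome, criteria, ld, nBoot, seed, methods,
                 direction, palindromeEafWindow),
      mrchainError = function(e) e)
    if (is(res, "MRSuiteResult")) results[[traitId(x)]] <- res
    else errors[traitId(x)] <- conditionMessage(res)
  }
  if (length(results)) {
    pv <- vapply(results, function(r) estimate(r, .HEADLINE)@pval, numeric(1))
    results <- results[order(pv, names(results))]
    pv <- pv[order(pv, names(pv))]
  } else pv <- numeric(0)
  list(results = results,
       significant = names(results)[pv < alpha],
       errors = errors)
}

#' Flat table of a panel screen with FDR column
#'
#' @param panel result of [runPanel()].
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame, one row per (exposure, method), with `fdr`
#'   (Benjamini-Hochberg over the headline IVW p-values) and
#'   `significant` columns.
#' @export
panelTable <- function(panel, alpha = 0.05) {
  if (!length(panel$results)) return(data.frame())
  tabs <- do.call(rbind, lapply(panel$results, suiteTable))
  pv <- vapply(panel$results, function(r) estimate(r, .HEADLINE)@pval,
               numeric(1))
  fdr <- stats::p.adjust(pv, "BH")
  tabs$fdr <- fdr[match(tabs$exposure_id, names(pv))]
  tabs$significant <- tabs$exposure_id %in% panel$significant
  rownames(tabs) <- NULL
  tabs
}

#' Reverse-direction MR
#'
#' Identical machinery to [runMrSuite()] with the disease used as the
#' exposure, marked `direction = "reverse"`.
#'
#' @param outcomeAsExposure the original outcome dataset, now the exposure.
#' @param exposureAsOutcome the original exposure dataset, now the outcome.
#' @param ... passed to [runMrSuite()].
#' @return An [MRSuiteResult-class] with `direction = "reverse"`.
#' @export
reverseMr <- function(outcomeAsExposure, exposureAsOutcome, ...) {
  runMrSuite(outcomeAsExposure, exposureAsOutcome, ...,
             direction = "reverse")
}

#' Classify the causal direction of a pair
#'
#' Truth table over the forward and reverse headline IVW p-values at level
#' `alpha`: `forward_only`, `reverse_only`, `bidirectional` or `null`.
#' Bidirectional pairs are flagged ineligible for mediation analysis (the
#' exclusion applied to exposures with reverse causation, e.g. a lipid
#' species that the disease itself alters).
#'
#' @param forward,reverse [MRSuiteResult-class] objects for the same pair
#'   with roles swapped.
#' @param alpha significance level.
#' @return A [DirectionClassification-class].
#' @export
classifyDirection <- function(forward, reverse, alpha = 0.05) {
  if (forward@exposureId != reverse@outcomeId ||
      forward@outcomeId != reverse@exposureId)
    .mrError(sprintf("pair mismatch: forward %s->%s vs reverse %s->%s",
                     forward@exposureId, forward@outcomeId,
                     reverse@exposureId, reverse@outcomeId),
             "mrPairingError")
  fs <- estimate(forward, .HEADLINE)@pval < alpha
  rs <- estimate(reverse, .HEADLINE)@pval < alpha
  label <- if (fs && rs) "bidirectional"
           else if (fs) "forward_only"
           else if (rs) "reverse_only"
           else "null"
  new("DirectionClassification",
      pairId = paste(forward@exposureId, forward@outcomeId, sep = "~"),
      forwardSig = fs, reverseSig = rs, label = label,
      mediationEligible = fs && !rs)
}
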