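#' @include AllClasses.R conditions.R gwas-io.R estimators.R screening.R
NULL

.propDelta <- function(indirect, indirectSe, total, totalSe,
                       covTerm = 0) {
  # delta-method variance of indirect/total; covTerm = cov(indirect, total)
  sqrt(indirectSe^2 / total^2 +
         indirect^2 * totalSe^2 / total^4 -
         2 * indirect * covTerm / total^3)
}

.mkMediation <- function(exposureId, mediatorId, outcomeId, method,
                         betaTotal, betaXm, betaMy, indirect, indirectSe,
                         totalSe, covTerm = 0) {
  undefined <- betaTotal == 0
  if (undefined) {
    .mrWarning(sprintf(
      "total effect of %s on %s is zero: proportion mediated undefined",
      exposureId, outcomeId), "mrUndefinedProportionWarning")
    prop <- NA_real_
    propSe <- NA_real_
  } else {
    prop <- indirect / betaTotal
    propSe <- .propDelta(indirect, indirectSe, betaTotal, totalSe, covTerm)
  }
  pv <- if (indirectSe > 0)
    pmax(2 * stats::pnorm(-abs(indirect / indirectSe)),
         .Machine$double.xmin) else NA_real_
  new("MediationEstimate",
      exposureId = exposureId, mediatorId = mediatorId,
      outcomeId = outcomeId, method = method,
      betaTotal = betaTotal, betaXm = betaXm, betaMy = betaMy,
      indirect = indirect, indirectSe = indirectSe,
      direct = betaTotal - indirect,
      propMediated = prop, propSe = propSe, pvalIndirect = pv,
      signConsistent = !undefined && sign(indirect) == sign(betaTotal),
      propUndefined = undefined)
}

#' Product-of-coefficients mediation estimate
#'
#' Two-step decomposition: `indirect = beta_xm * beta_my` with the
#' delta-method SE `sqrt(beta_my^2 se_xm^2 + beta_xm^2 se_my^2)`
#' (independent samples assumed); `direct = total - indirect`;
#' `proportion mediated = indirect / total`. Proportions outside [0, 1]
#' or with an indirect effect of opposite sign to the total are flagged,
#' never truncated.
#'
#' @param total [MREstimate-class] for the exposure -> outcome total effect.
#' @param xm [MREstimate-class] for exposure -> mediator.
#' @param my [MREstimate-class] for mediator -> outcome (univariable).
#' @param ids character(3): exposure, mediator and outcome identifiers.
#' @return A [MediationEstimate-class] (`method = "product"`).
#' @export
mediationProduct <- function(total, xm, my,
                             ids = c("exposure", "mediator", "outcome")) {
  indirect <- xm@beta * my@beta
  indirectSe <- sqrt(my@beta^2 * xm@se^2 + xm@beta^2 * my@se^2)
  .mkMediation(ids[1], ids[2], ids[3], "product",
               betaTotal = total@beta, betaXm = xm@beta, betaMy = my@beta,
               indirect = indirect, indirectSe = indirectSe,
               totalSe = total@se)
}

#' Difference-method mediation estimate
#'
#' `indirect = total - direct`, where the direct effect is the exposure's
#' coefficient from multivariable IVW with exposure and mediator jointly
#' modeled; `se = sqrt(se_total^2 + se_direct^2)` (conservative,
#' cross-sample covariance taken as zero). The proportion-mediated SE
#' accounts for the shared total-effect term.
#'
#' @param total [MREstimate-class] total effect.
#' @param directMvmr [MREstimate-class]; the exposure coefficient from
#'   [mvmrIvw()].
#' @param ids character(3): exposure, mediator and outcome identifiers.
#' @return A [MediationEstimate-class] (`method = "difference"`).
#' @export
mediationDifference <- function(total, directMvmr,
                                ids = c("exposure", "mediator", "outcome")) {
  indirect <- total@beta - directMvmr@beta
  indirectSe <- sqrt(total@se^2 + directMvmr@se^2)
  # indirect = total - direct shares the total term: cov(ind, total) = var(total)
  .mkMediation(ids[1], ids[2], ids[3], "difference",
               betaTotal = total@beta, betaXm = NA_real_, betaMy = NA_real_,
               indirect = indirect, indirectSe = indirectSe,
               totalSe = total@se, covTerm = total@se^2)
}

# align a dataset's betas to reference (outcome) effect alleles over snps;
# returns list(beta, se) with NA where absent/mismatched/ambiguous
.alignedEffects <- function(dataset, snps, ref, window = c(0.42, 0.58)) {
  r <- records(dataset)
  i <- match(snps, r$variant_id)
  beta <- se <- rep(NA_real_, length(snps))
  ok <- !is.na(i)
  if (any(ok)) {
    j <- match(snps[ok], ref$variant_id)
    orient <- .orient(r$effect_allele[i[ok]], r$other_allele[i[ok]],
                      ref$effect_allele[j], ref$other_allele[j],
                      r$eaf[i[ok]], ref$eaf[j], window)
    good <- !is.na(orient) & orient != 0L
    beta[ok][good] <- orient[good] * r$beta[i[ok]][good]
    se[ok][good] <- r$se[i[ok]][good]
  }
  list(beta = beta, se = se)
}

#' Mediation analysis for one exposure-mediator-outcome triplet
#'
#' Computes the total (X -> Y), exposure-mediator (X -> M) and
#' mediator-outcome (M -> Y) univariable IVW fits, the product-method
#' decomposition, and the difference-method decomposition from a
#' multivariable IVW fit over the union of the X and M instrument sets
#' (effects aligned to the outcome's allele coding).
#'
#' @param exposure,mediator,outcome [SummaryDataset-class] objects.
#' @param criteria an [InstrumentCriteria-class].
#' @param ld optional [LDMatrix-class].
#' @param nBoot,seed,methods passed to [runMrSuite()] (IVW alone suffices
#'   for the decomposition).
#' @return list with `product` and `difference`
#'   ([MediationEstimate-class]), and the three underlying suites
#'   (`total`, `xm`, `my`).
#' @export
estimateMediation <- function(exposure, mediator, outcome,
                              criteria = instrumentCriteria(), ld = NULL,
                              nBoot = 1000, seed = 1, methods = "ivw") {
  totalS <- runMrSuite(exposure, outcome, criteria, ld, nBoot, seed, methods)
  xmS <- runMrSuite(exposure, mediator, criteria, ld, nBoot, seed, methods)
  myS <- runMrSuite(mediator, outcome, criteria, ld, nBoot, seed, methods)
  .mediationFromSuites(totalS, xmS, myS, exposure, mediator, outcome)
}

.mediationFromSuites <- function(totalS, xmS, myS,
                                 exposure, mediator, outcome) {
  ids <- c(traitId(exposure), traitId(mediator), traitId(outcome))
  total <- estimate(totalS, .HEADLINE)
  prod <- mediationProduct(total, estimate(xmS, .HEADLINE),
                           estimate(myS, .HEADLINE), ids = ids)

  snps <- union(variantIds(totalS@harmonized), variantIds(myS@harmonized))
  ref <- records(outcome)
  ex <- .alignedEffects(exposure, snps, ref)
  em <- .alignedEffects(mediator, snps, ref)
  io <- match(snps, ref$variant_id)
  ok <- !is.na(ex$beta) & !is.na(em$beta) & !is.na(io)
  diffEst <- tryCatch({
    bxMat <- cbind(exposure = ex$beta[ok], mediator = em$beta[ok])
    fit <- mvmrIvw(bxMat,
                   seXMatrix = cbind(ex$se[ok], em$se[ok]),
                   by = ref$beta[io[ok]], seY = ref$se[io[ok]])
    mediationDifference(total, fit$exposure, ids = ids)
  }, mrchainError = function(e) e)

  list(product = prod, difference = diffEst,
       total = totalS, xm = xmS, my = myS)
}

#' Screen mediator candidates for eligible exposures
#'
#' For every (exposure, mediator) pair, a mediation estimate is produced
#' only when both steps of the chain are supported: the X -> M and M -> Y
#' headline IVW p-values must each fall below `alpha`. Ineligible triplets
#' are recorded with the failing step (`step1_null`, `step2_null`) or the
#' error that prevented a fit; nothing is fatal.
#'
#' @param exposures list of [SummaryDataset-class] (already classified
#'   forward-only; bidirectional exposures are excluded upstream).
#' @param mediators list of [SummaryDataset-class] candidate mediators.
#' @param outcome a [SummaryDataset-class].
#' @param criteria,ld,nBoot,seed passed through.
#' @param alpha gating significance level.
#' @return list with `estimates` (flat list of [MediationEstimate-class],
#'   product and difference per gated triplet) and `skipped` (data.frame
#'   exposure_id, mediator_id, reason).
#' @export
screenMediators <- function(exposures, mediators, outcome,
                            criteria = instrumentCriteria(), ld = NULL,
                            alpha = 0.05, nBoot = 1000, seed = 1) {
  estimatesOut <- list()
  skipped <- data.frame(exposure_id = character(0),
                        mediator_id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  note <- function(x, m, why)
    rbind(skipped, data.frame(exposure_id = x, mediator_id = m,
                              reason = why, stringsAsFactors = FALSE))
  mySuites <- list()
  for (m in mediators) {
    mySuites[[traitId(m)]] <- tryCatch(
      runMrSuite(m, outcome, criteria, ld, nBoot, seed, methods = "ivw"),
      mrchainError = function(e) e)
  }
  for (x in exposures) {
    totalS <- tryCatch(
      runMrSuite(x, outcome, criteria, ld, nBoot, seed, methods = "ivw"),
      mrchainError = function(e) e)
    for (m in mediators) {
      xid <- traitId(x); mid <- traitId(m)
      if (!is(totalS, "MRSuiteResult")) {
        skipped <- note(xid, mid, "total_fit_failed"); next
      }
      myS <- mySuites[[mid]]
      if (!is(myS, "MRSuiteResult")) {
        skipped <- note(xid, mid, "my_fit_failed"); next
      }
      xmS <- tryCatch(
        runMrSuite(x, m, criteria, ld, nBoot, seed, methods = "ivw"),
        mrchainError = function(e) e)
      if (!is(xmS, "MRSuiteResult")) {
        skipped <- note(xid, mid, "xm_fit_failed"); next
      }
      if (estimate(xmS, .HEADLINE)@pval >= alpha) {
        skipped <- note(xid, mid, "step1_null"); next
      }
      if (estimate(myS, .HEADLINE)@pval >= alpha) {
        skipped <- note(xid, mid, "step2_null"); next
      }
      med <- .mediationFromSuites(totalS, xmS, myS, x, m, outcome)
      estimatesOut[[paste(xid, mid, "product", sep = "~")]] <- med$product
      if (is(med$difference, "MediationEstimate"))
        estimatesOut[[paste(xid, mid, "difference", sep = "~")]] <-
          med$difference
      else skipped <- note(xid, mid, "difference_fit_failed")
    }
  }
  list(estimates = estimatesOut, skipped = skipped)
}
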