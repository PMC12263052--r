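#' @include AllClasses.R conditions.R gwas-io.R
NULL

#' Construct a SimConfig
#'
#' Defaults describe a well-powered molecular-exposure study: a large
#' exposure GWAS (n = 500,000) so that instruments selected at the relaxed
#' p < 5e-5 threshold are strong (with `exposureH2 = 0.05` spread over 100
#' SNPs the median instrument F is far above 10), a 100,000-sample
#' mediator GWAS, a disease outcome GWAS at the 15,088-case scale of a
#' biobank phenotype (large enough to carry its own instruments, small
#' enough that exposure instruments rarely leak into the outcome's
#' selection), and the canonical structural scenario `thetaXm = 0.4`,
#' `thetaMy = 0.5`,
#' `thetaDirect = 0.3` (total effect 0.5, proportion mediated 0.4). See the
#' methods vignette for the full rationale.
#'
#' @param nSnps candidate instruments per trait block.
#' @param nX,nM,nY GWAS sample sizes.
#' @param thetaXm,thetaMy,thetaDirect structural effects.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropyScale scale of pleiotropic effects.
#' @param mafRange minor-allele-frequency sampling range.
#' @param exposureH2 per-trait instrument heritability.
#' @param reverseTheta outcome -> exposure effect (0 = none).
#' @param seed mandatory integer seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nSnps = 100, nX = 500000, nM = 100000, nY = 15088,
                      thetaXm = 0.4, thetaMy = 0.5, thetaDirect = 0.3,
                      pleiotropy = c("none", "balanced", "directional"),
                      pleiotropyScale = 0.02, mafRange = c(0.05, 0.5),
                      exposureH2 = 0.05, reverseTheta = 0, seed) {
  if (missing(seed)) .mrError("seed is mandatory", "mrConfigError")
  new("SimConfig", nSnps = as.integer(nSnps), nX = nX, nM = nM, nY = nY,
      thetaXm = thetaXm, thetaMy = thetaMy, thetaDirect = thetaDirect,
      pleiotropy = match.arg(pleiotropy),
      pleiotropyScale = pleiotropyScale, mafRange = mafRange,
      exposureH2 = exposureH2, reverseTheta = reverseTheta,
      seed = as.integer(seed))
}

# scale raw normal draws so the block explains exactly h2 of trait variance
# (with h2 < 1 every per-variant share is automatically < 1)
.scaleToH2 <- function(z, v, h2) {
  z * sqrt(h2 / sum(v * z^2))
}

#' Simulate a GWAS summary-statistics triplet with known causal structure
#'
#' Generates exposure (X), mediator (M) and outcome (Y) summary datasets
#' from a linear structural model. Each trait carries its own disjoint
#' block of `nSnps` instruments (disjointness keeps the two-sample
#' assumptions clean); the exposure block propagates to M with `thetaXm`
#' and to Y with `thetaDirect + thetaXm * thetaMy` (plus optional
#' per-variant pleiotropic effects), the mediator block to Y with
#' `thetaMy`, and the outcome block back to X with `reverseTheta` (and on
#' to M through X). Observed effects add sampling noise with the standard
#' standardized-trait approximation `se = 1/sqrt(2 maf (1-maf) n)`;
#' p-values are Wald. Deterministic given the seed; sub-streams for MAFs,
#' true effects and each dataset's noise are derived from it so components
#' are independently reproducible.
#'
#' @param config a [SimConfig-class].
#' @param ids character(3) trait identifiers for X, M and Y.
#' @return Named list of three [SummaryDataset-class]: `exposure`,
#'   `mediator`, `outcome`.
#' @export
simulateTriplet <- function(config, ids = c("X", "M", "Y")) {
  validObject(config)
  sub <- withSeed(config@seed,
                  sample.int(.Machine$integer.max - 1L, 6L))
  n <- config@nSnps
  total <- 3L * n
  iX <- seq_len(n)
  iM <- n + seq_len(n)
  iY <- 2L * n + seq_len(n)

  snpIds <- sprintf("rs%07d", seq_len(total))
  chrom <- as.character(rep_len(1:22, total))
  occ <- stats::ave(seq_len(total), chrom, FUN = seq_along)
  pos <- as.integer(1e6 + occ * 2e7)  # >= 20 Mb apart within a chromosome

  pairs <- matrix(c("A","G", "A","C", "T","G", "T","C",
                    "G","A", "C","A", "G","T", "C","T"),
                  ncol = 2, byrow = TRUE)
  mafPair <- withSeed(sub[1], list(
    maf = stats::runif(total, config@mafRange[1], config@mafRange[2]),
    pair = sample.int(8L, total, replace = TRUE)))
  maf <- mafPair$maf
  ea <- pairs[mafPair$pair, 1]
  oa <- pairs[mafPair$pair, 2]
  v <- 2 * maf * (1 - maf)

  eff <- withSeed(sub[2], {
    list(zx = stats::rnorm(n), zm = stats::rnorm(n), zy = stats::rnorm(n),
         alpha = switch(config@pleiotropy,
                        none = numeric(n),
                        balanced = stats::rnorm(n, 0, config@pleiotropyScale),
                        directional = stats::rnorm(n, config@pleiotropyScale,
                                                   config@pleiotropyScale)))
  })
  h2 <- config@exposureH2
  b <- .scaleToH2(eff$zx, v[iX], h2)   # exposure block on X
  g <- .scaleToH2(eff$zm, v[iM], h2)   # mediator block on M
  hh <- .scaleToH2(eff$zy, v[iY], h2)  # outcome block on Y

  thetaTotal <- config@thetaDirect + config@thetaXm * config@thetaMy
  tX <- numeric(total)
  tX[iX] <- b
  tX[iY] <- config@reverseTheta * hh
  tM <- numeric(total)
  tM[iX] <- config@thetaXm * b
  tM[iM] <- g
  tM[iY] <- config@thetaXm * config@reverseTheta * hh
  # pleiotropic effects act relative to the exposure-increasing allele
  # (directional pleiotropy is only meaningful in that orientation)
  tY <- numeric(total)
  tY[iX] <- thetaTotal * b + sign(b) * eff$alpha
  tY[iM] <- config@thetaMy * g
  tY[iY] <- hh

  mk <- function(id, true, nSamp, type, subseed) {
    se <- 1 / sqrt(v * nSamp)
    beta <- withSeed(subseed, true + stats::rnorm(total) * se)
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    summaryDataset(id, data.frame(
      variant_id = snpIds, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta, se = se, pval = pval, n = nSamp,
      stringsAsFactors = FALSE), traitType = type)
  }
  list(exposure = mk(ids[1], tX, config@nX, "continuous", sub[3]),
       mediator = mk(ids[2], tM, config@nM, "continuous", sub[4]),
       outcome = mk(ids[3], tY, config@nY, "binary", sub[5]))
}

#' Simulate a triplet with genuine reverse causation
#'
#' Requires `reverseTheta != 0`; the outcome block's effects then propagate
#' into the exposure, producing a truly bidirectional pair. With
#' `reverseTheta = 0` the generator is exactly [simulateTriplet()].
#'
#' @param config a [SimConfig-class] with nonzero `reverseTheta`.
#' @param ids trait identifiers.
#' @return As [simulateTriplet()].
#' @export
simulateReverse <- function(config, ids = c("X", "M", "Y")) {
  if (config@reverseTheta == 0)
    .mrError("simulateReverse requires reverseTheta != 0 (use simulateTriplet for the purely forward model)",
             "mrConfigError")
  simulateTriplet(config, ids)
}

#' Closed-form expected effects of a SimConfig
#'
#' @param config a [SimConfig-class].
#' @return list with `thetaTotal`, `thetaDirect`, `indirect`
#'   (`thetaXm * thetaMy`), `proportion` (`indirect/thetaTotal`, NA when
#'   the total effect is zero) and `proportionDefined`.
#' @export
truthTable <- function(config) {
  indirect <- config@thetaXm * config@thetaMy
  thetaTotal <- config@thetaDirect + indirect
  defined <- thetaTotal != 0
  list(thetaTotal = thetaTotal, thetaDirect = config@thetaDirect,
       indirect = indirect,
       proportion = if (defined) indirect / thetaTotal else NA_real_,
       proportionDefined = defined)
}
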