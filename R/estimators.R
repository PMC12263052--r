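#' @include AllClasses.R conditions.R
NULL

.Z95 <- 1.959964

#' Log-scale effect to odds ratio with Wald interval
#'
#' @param beta effect on the log-odds (or SD) scale.
#' @param se positive standard error.
#' @return list with `or = exp(beta)`, `ciLow`/`ciHigh`
#'   (`exp(beta -/+ 1.959964 * se)`) and the two-sided normal `pval`.
#' @export
betaToOr <- function(beta, se) {
  if (any(se <= 0)) .mrError("se must be > 0", "mrConfigError")
  p <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  list(or = exp(beta), ciLow = exp(beta - .Z95 * se),
       ciHigh = exp(beta + .Z95 * se), pval = p)
}

.mkEstimate <- function(method, k, beta, se) {
  t <- betaToOr(beta, se)
  new("MREstimate", method = method, k = as.integer(k), beta = beta,
      se = se, pval = t$pval, or = t$or, ciLow = t$ciLow, ciHigh = t$ciHigh)
}

.requireK <- function(h, kmin, what) {
  k <- length(h@bx)
  if (k < kmin)
    .mrError(sprintf("%s requires at least %d instruments (have %d)",
                     what, kmin, k), "mrInsufficientInstrumentsError")
  k
}

#' Per-variant Wald ratio estimates
#'
#' `ratio_j = by_j / bx_j` with the first-order delta standard error
#' `se_j = seY_j / |bx_j|` (the exposure-side uncertainty is ignored, the
#' usual summary-data approximation).
#'
#' @param h a [HarmonizedSet-class].
#' @param secondOrder if TRUE use the second-order delta SE, which adds the
#'   exposure-side term `by^2 * seX^2 / bx^4`.
#' @return list with `ratio` and `se` vectors (named by variant).
#' @export
waldRatios <- function(h, secondOrder = FALSE) {
  zero <- h@bx == 0
  if (any(zero))
    .mrError(sprintf("zero exposure effect for variant %s",
                     h@variantIds[which(zero)[1]]),
             "mrDegenerateInstrumentError")
  ratio <- h@by / h@bx
  se <- if (secondOrder)
    sqrt(h@seY^2 / h@bx^2 + h@by^2 * h@seX^2 / h@bx^4)
  else h@seY / abs(h@bx)
  names(ratio) <- names(se) <- h@variantIds
  list(ratio = ratio, se = se)
}

#' Inverse-variance weighted estimate with Cochran's Q
#'
#' Precision-weighted combination of Wald ratios, equivalent to weighted
#' least squares of the outcome effects on the exposure effects through the
#' origin with weights `1/seY^2`:
#' `beta = sum(bx*by/seY^2) / sum(bx^2/seY^2)`. The fixed-effect SE is
#' `1/sqrt(sum(bx^2/seY^2))`; under multiplicative random effects the SE is
#' inflated by `sqrt(Q/(k-1))` when heterogeneity exceeds its expectation
#' (`Q/(k-1) > 1`). Cochran's Q is reported against chi-square on k - 1 df.
#'
#' @param h a [HarmonizedSet-class] with k >= 1 (k >= 2 for Q and random
#'   effects to be meaningful).
#' @param mode `"random"` (the pipeline's headline flavor) or `"fixed"`.
#' @return list with `estimate` ([MREstimate-class]) and `q`
#'   ([QTest-class]).
#' @export
mrIvw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  k <- .requireK(h, 1L, "IVW")
  wsum <- sum(h@bx^2 / h@seY^2)
  beta <- sum(h@bx * h@by / h@seY^2) / wsum
  seFixed <- 1 / sqrt(wsum)
  Q <- sum((h@by - beta * h@bx)^2 / h@seY^2)
  df <- max(0L, k - 1L)
  qp <- if (df >= 1L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  se <- seFixed
  if (mode == "random" && df >= 1L && Q / df > 1)
    se <- seFixed * sqrt(Q / df)
  list(estimate = .mkEstimate(paste0("ivw_", mode), k, beta, se),
       q = new("QTest", Q = Q, df = df, pval = qp))
}

# weighted least squares with multiplicative random-effect SE scaling
.wls <- function(X, y, w, dfResid) {
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * y)
  coefs <- drop(solve(XtWX, XtWy))
  resid <- y - drop(X %*% coefs)
  rssW <- sum(w * resid^2)
  scale <- if (dfResid > 0) max(1, sqrt(rssW / dfResid)) else 1
  se <- sqrt(diag(solve(XtWX))) * scale
  list(coef = coefs, se = se, rssW = rssW, scale = scale)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept,
#' weights `1/seY^2`, after orienting every variant so its exposure effect
#' is non-negative. The slope is the pleiotropy-adjusted causal estimate;
#' an intercept away from zero indicates directional horizontal pleiotropy.
#' Standard errors carry the multiplicative random-effects scale
#' `max(1, sqrt(RSS_w/(k-2)))`; p-values are two-sided normal.
#'
#' @param h a [HarmonizedSet-class] with k >= 3.
#' @return list with `estimate` (slope, [MREstimate-class]) and
#'   `intercept` ([EggerIntercept-class]).
#' @export
mrEgger <- function(h) {
  k <- .requireK(h, 3L, "MR-Egger")
  s <- ifelse(h@bx < 0, -1, 1)
  bx <- s * h@bx
  by <- s * h@by
  fit <- .wls(cbind(intercept = 1, slope = bx), by, 1 / h@seY^2, k - 2L)
  int <- fit$coef[["intercept"]]
  intSe <- fit$se[["intercept"]]
  list(estimate = .mkEstimate("egger", k, fit$coef[["slope"]],
                              fit$se[["slope"]]),
       intercept = new("EggerIntercept", intercept = int, se = intSe,
                       pval = pmax(2 * stats::pnorm(-abs(int / intSe)),
                                   .Machine$double.xmin)))
}

# interpolated weighted median of ratios (weights need not be normalized)
.weightedMedianPoint <- function(ratio, w) {
  o <- order(ratio)
  r <- unname(ratio[o])
  wn <- w[o] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

.parametricBootSe <- function(h, nBoot, seed, pointFun) {
  k <- length(h@bx)
  withSeed(seed, {
    ests <- vapply(seq_len(nBoot), function(i) {
      bx <- stats::rnorm(k, h@bx, h@seX)
      by <- stats::rnorm(k, h@by, h@seY)
      bx[bx == 0] <- .Machine$double.eps
      pointFun(by / bx, (abs(bx) / h@seY)^2)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median MR estimate
#'
#' Orders the Wald ratios and takes the weight-interpolated median: with
#' normalized inverse-variance weights `w_j` (from the ratio SEs) and
#' cumulative midpoints `p_j = S_{j-1} + w_j/2`, the estimate is the linear
#' interpolation of the ordered ratios at p = 0.5. Consistent when at least
#' half the weight comes from valid instruments. The SE comes from a
#' parametric bootstrap: per-variant effects are redrawn from normals with
#' the observed SEs and the estimator recomputed.
#'
#' @param h a [HarmonizedSet-class] with k >= 3.
#' @param nBoot bootstrap draws for the SE.
#' @param seed seed for the bootstrap (mandatory for reproducibility).
#' @return An [MREstimate-class].
#' @export
weightedMedian <- function(h, nBoot = 1000, seed) {
  .requireK(h, 3L, "weighted median")
  wr <- waldRatios(h)
  est <- .weightedMedianPoint(wr$ratio, 1 / wr$se^2)
  se <- .parametricBootSe(h, nBoot, seed,
                          function(r, w) .weightedMedianPoint(r, w))
  .mkEstimate("weighted_median", length(h@bx), est, se)
}

# mode of the weighted kernel density of the ratios
.weightedModePoint <- function(ratio, w, phi = 1) {
  if (diff(range(ratio)) == 0) return(unname(ratio[1]))
  k <- length(ratio)
  s <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  if (s <= 0) s <- stats::sd(ratio)
  bw <- phi * 0.9 * s * k^(-1 / 5)
  d <- stats::density(ratio, weights = w / sum(w), bw = bw,
                      kernel = "gaussian", n = 512,
                      from = min(ratio), to = max(ratio))
  d$x[which.max(d$y)]
}

#' Weighted-mode MR estimate
#'
#' The mode of a Gaussian kernel density over the Wald ratios with
#' inverse-variance weights, evaluated on a 512-point grid spanning the
#' ratio range. Bandwidth is `phi` times a modified Silverman rule,
#' `0.9 * min(sd, IQR/1.349) * k^(-1/5)`. Consistent when the largest
#' group of instruments sharing a ratio value is valid (the ZEMPA
#' assumption). SE by the same parametric bootstrap as [weightedMedian()].
#'
#' @param h a [HarmonizedSet-class] with k >= 3.
#' @param bandwidthPhi bandwidth multiplier.
#' @param nBoot bootstrap draws for the SE.
#' @param seed seed for the bootstrap.
#' @return An [MREstimate-class].
#' @export
weightedMode <- function(h, bandwidthPhi = 1, nBoot = 1000, seed) {
  .requireK(h, 3L, "weighted mode")
  wr <- waldRatios(h)
  est <- .weightedModePoint(wr$ratio, 1 / wr$se^2, bandwidthPhi)
  se <- .parametricBootSe(h, nBoot, seed,
                          function(r, w) .weightedModePoint(r, w, bandwidthPhi))
  .mkEstimate("weighted_mode", length(h@bx), est, se)
}

#' Multivariable IVW (weighted least squares without intercept)
#'
#' Regresses the outcome effects on several exposures' effects jointly,
#' weights `1/seY^2`, no intercept. Each exposure's coefficient is its
#' direct effect adjusting for the others — the ingredient of the
#' difference method of mediation analysis. SEs carry the multiplicative
#' random-effects scale `max(1, sqrt(RSS_w/(k-m)))`. With m = 1 this
#' reduces exactly to [mrIvw()] in random mode.
#'
#' @param bxMatrix k x m matrix of exposure effects (one column per
#'   exposure; column names label the estimates).
#' @param seXMatrix k x m matrix of exposure SEs (interface completeness;
#'   not used by the first-order estimator).
#' @param by,seY outcome effects and SEs (length k).
#' @return Named list of [MREstimate-class], one per exposure column.
#' @export
mvmrIvw <- function(bxMatrix, seXMatrix = NULL, by, seY) {
  bxMatrix <- as.matrix(bxMatrix)
  k <- nrow(bxMatrix)
  m <- ncol(bxMatrix)
  if (m < 1L || k <= m)
    .mrError(sprintf("need k > m >= 1 (k = %d, m = %d)", k, m),
             "mrInsufficientInstrumentsError")
  if (qr(bxMatrix)$rank < m)
    .mrError("exposure-effect matrix is rank deficient", "mrCollinearityError")
  fit <- .wls(bxMatrix, by, 1 / seY^2, k - m)
  nms <- colnames(bxMatrix)
  if (is.null(nms)) nms <- paste0("exposure", seq_len(m))
  out <- lapply(seq_len(m), function(j)
    .mkEstimate("mvmr_ivw", k, unname(fit$coef[j]), unname(fit$se[j])))
  names(out) <- nms
  out
}
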