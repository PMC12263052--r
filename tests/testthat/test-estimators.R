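test_that("Wald ratios follow the delta formula and catch null instruments", {
  h <- makeHarmonized(bx = c(0.1, -0.1, 0.2), by = c(0.05, 0.05, 0),
                      seY = c(0.02, 0.02, 0.02))
  wr <- waldRatios(h)
  expect_equal(unname(wr$ratio), c(0.5, -0.5, 0))
  expect_equal(unname(wr$se), c(0.2, 0.2, 0.1))
  h0 <- makeHarmonized(bx = c(0.1, 0), by = c(0.05, 0.01),
                       seY = c(0.02, 0.02))
  expect_error(waldRatios(h0), "rs002",
               class = "mrDegenerateInstrumentError")
})

test_that("IVW matches the closed form and the WLS-through-origin oracle", {
  h <- makeHarmonized(bx = c(0.2, 0.4), by = c(0.1, 0.1), seY = c(0.1, 0.1))
  res <- mrIvw(h, "fixed")
  expect_equal(res$estimate@beta, 0.3)
  expect_equal(res$estimate@se, sqrt(1 / 20), tolerance = 1e-6)

  # k = 1 reduces to the single Wald ratio; Q degenerates
  h1 <- makeHarmonized(bx = 0.2, by = 0.1, seY = 0.05)
  r1 <- mrIvw(h1)
  expect_equal(r1$estimate@beta, 0.5)
  expect_equal(r1$q@Q, 0)
  expect_equal(r1$q@df, 0L)
  expect_true(is.na(r1$q@pval))

  # generic oracle on random instances
  set.seed(7)
  for (i in 1:10) {
    k <- sample(3:10, 1)
    h <- makeHarmonized(bx = runif(k, -0.3, 0.3) + 0.05,
                        by = rnorm(k, 0, 0.1), seY = runif(k, 0.01, 0.2))
    fit <- lm(h@by ~ 0 + h@bx, weights = 1 / h@seY^2)
    expect_equal(mrIvw(h)$estimate@beta, unname(coef(fit)),
                 tolerance = 1e-10)
  }

  # homogeneous ratios: Q = 0 and random SE equals fixed SE
  hh <- makeHarmonized(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.1, 0.2),
                       seY = c(0.1, 0.1, 0.1))
  expect_equal(mrIvw(hh)$q@Q, 0, tolerance = 1e-20)
  expect_equal(mrIvw(hh, "random")$estimate@se,
               mrIvw(hh, "fixed")$estimate@se)
})

test_that("random-effects IVW never narrows the fixed-effect SE", {
  set.seed(99)
  for (i in 1:20) {
    k <- sample(2:15, 1)
    h <- makeHarmonized(bx = runif(k, 0.05, 0.3),
                        by = rnorm(k, 0.1, 0.1), seY = runif(k, 0.02, 0.2))
    fx <- mrIvw(h, "fixed")
    rd <- mrIvw(h, "random")
    expect_gte(rd$estimate@se, fx$estimate@se)
    if (fx$q@Q <= fx$q@df)
      expect_equal(rd$estimate@se, fx$estimate@se)
  }
})

test_that("MR-Egger recovers exact linear data and matches a WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- makeHarmonized(bx = bx, by = 0.01 + 0.3 * bx, seY = rep(0.1, 4))
  eg <- mrEgger(h)
  expect_equal(eg$estimate@beta, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept@intercept, 0.01, tolerance = 1e-12)

  h2 <- makeHarmonized(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.07, 0.13),
                       seY = c(0.1, 0.1, 0.1))
  eg2 <- mrEgger(h2)
  fit <- lm(h2@by ~ h2@bx, weights = 1 / h2@seY^2)
  expect_equal(eg2$estimate@beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg2$intercept@intercept, unname(coef(fit)[1]),
               tolerance = 1e-10)
  # SE oracle: unscaled (X'WX)^-1 diagonal times max(1, sqrt(RSS_w/(k-2)))
  X <- cbind(1, h2@bx)
  W <- diag(1 / h2@seY^2)
  unscaled <- sqrt(diag(solve(t(X) %*% W %*% X)))
  rssW <- sum((h2@by - X %*% coef(fit))^2 / h2@seY^2)
  expect_equal(c(eg2$intercept@se, eg2$estimate@se),
               unscaled * max(1, sqrt(rssW / 1)), tolerance = 1e-10)

  # orientation invariance: negating one variant's (bx, by) changes nothing
  h3 <- makeHarmonized(bx = c(-0.1, 0.2, 0.4), by = c(-0.05, 0.07, 0.13),
                       seY = c(0.1, 0.1, 0.1))
  eg3 <- mrEgger(h3)
  expect_equal(eg3$estimate@beta, eg2$estimate@beta)
  expect_equal(eg3$intercept@intercept, eg2$intercept@intercept)

  expect_error(mrEgger(makeHarmonized(bx = c(0.1, 0.2), by = c(0, 0),
                                      seY = c(0.1, 0.1))),
               class = "mrInsufficientInstrumentsError")
})

test_that("the weighted median interpolates the cumulative-weight midpoints", {
  h <- makeHarmonized(bx = rep(1, 3), by = c(0.2, 0.5, 0.8),
                      seY = rep(0.1, 3))
  expect_equal(weightedMedian(h, nBoot = 50, seed = 1)@beta, 0.5)

  # hand interpolation: ratios (0.1, 0.2, 0.3), weights (0.6, 0.2, 0.2)
  # midpoints (0.3, 0.7, 0.9) -> value at 0.5 is 0.15
  h2 <- makeHarmonized(bx = rep(1, 3), by = c(0.1, 0.2, 0.3),
                       seY = 1 / sqrt(c(0.6, 0.2, 0.2)))
  expect_equal(weightedMedian(h2, nBoot = 50, seed = 1)@beta, 0.15)

  # estimate always lies inside the ratio range; order invariance
  set.seed(3)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    bx <- runif(k, 0.05, 0.4)
    by <- rnorm(k, 0.2 * bx, 0.05)
    h3 <- makeHarmonized(bx = bx, by = by, seY = runif(k, 0.02, 0.2))
    est <- weightedMedian(h3, nBoot = 10, seed = 2)@beta
    r <- by / bx
    expect_gte(est, min(r)); expect_lte(est, max(r))
    perm <- sample(k)
    h3p <- makeHarmonized(bx = bx[perm], by = by[perm],
                          seY = h3@seY[perm])
    expect_equal(weightedMedian(h3p, nBoot = 10, seed = 2)@beta, est)
  }

  # degenerate: identical ratios, shrinking SEs -> bootstrap SE shrinks
  hc <- makeHarmonized(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15),
                       seY = rep(1e-4, 3), seX = rep(1e-5, 3))
  est <- weightedMedian(hc, nBoot = 100, seed = 4)
  expect_equal(est@beta, 0.5)
  expect_lt(est@se, 0.01)
})

test_that("the weighted mode tracks the majority cluster of ratios", {
  hc <- makeHarmonized(bx = rep(1, 3), by = c(0.7, 0.7, 0.7),
                       seY = rep(0.1, 3))
  expect_equal(weightedMode(hc, nBoot = 10, seed = 1)@beta, 0.7)

  h <- makeHarmonized(bx = rep(1, 4), by = c(0.5, 0.5, 0.5, 1.0),
                      seY = rep(0.1, 4))
  est <- weightedMode(h, nBoot = 10, seed = 1)@beta
  # kernel-density oracle on the same 4 ratios, same bandwidth rule
  r <- c(0.5, 0.5, 0.5, 1.0)
  bw <- 0.9 * min(sd(r), IQR(r) / 1.349) * 4^(-1 / 5)
  grid <- seq(min(r), max(r), length.out = 512)
  dens <- vapply(grid, function(g)
    sum(dnorm((g - r) / bw)), numeric(1))
  # density() bins onto the same grid via FFT; allow one grid cell
  expect_equal(est, grid[which.max(dens)], tolerance = 2 * diff(grid[1:2]))
  expect_lt(abs(est - 0.5), 0.05)

  # affine equivariance: doubling the outcome effects doubles the mode
  h2 <- makeHarmonized(bx = rep(1, 4), by = 2 * c(0.5, 0.5, 0.5, 1.0),
                       seY = rep(0.2, 4))
  expect_equal(weightedMode(h2, nBoot = 10, seed = 1)@beta, 2 * est,
               tolerance = 2 * diff(grid[1:2]))
})

test_that("multivariable IVW reduces to IVW and recovers joint effects", {
  h <- makeHarmonized(bx = c(0.1, 0.25, 0.4, 0.15),
                      by = c(0.04, 0.1, 0.11, 0.06),
                      seY = c(0.05, 0.08, 0.05, 0.1))
  mv <- mvmrIvw(matrix(h@bx, ncol = 1), by = h@by, seY = h@seY)[[1]]
  ivw <- mrIvw(h, "random")$estimate
  expect_equal(mv@beta, ivw@beta, tolerance = 1e-12)
  expect_equal(mv@se, ivw@se, tolerance = 1e-12)

  # near-orthogonal design with tiny noise recovers (0.2, -0.1)
  set.seed(5)
  k <- 40
  B <- cbind(a = rnorm(k), b = rnorm(k))
  by <- drop(B %*% c(0.2, -0.1)) + rnorm(k, 0, 1e-7)
  out <- mvmrIvw(B, by = by, seY = rep(0.05, k))
  expect_equal(out$a@beta, 0.2, tolerance = 1e-6)
  expect_equal(out$b@beta, -0.1, tolerance = 1e-6)

  expect_error(mvmrIvw(cbind(B[, 1], B[, 1]), by = by, seY = rep(0.05, k)),
               class = "mrCollinearityError")
})

test_that("log-OR transforms are internally consistent", {
  t0 <- betaToOr(0, 0.1)
  expect_equal(t0$or, 1)
  expect_equal(t0$ciLow * t0$ciHigh, 1, tolerance = 1e-12)

  # IL-17A forest row: CI (1.042, 1.234) implies the printed p = .004
  se <- (log(1.234) - log(1.042)) / (2 * 1.959964)
  t1 <- betaToOr(log(1.134), se)
  expect_equal(round(t1$pval, 3), 0.004)
  expect_equal(t1$ciLow, 1.042, tolerance = 1e-3)
  expect_equal(t1$ciHigh, 1.234, tolerance = 1e-3)

  # geometric mean of the CI equals the OR for arbitrary inputs
  set.seed(8)
  for (i in 1:10) {
    b <- rnorm(1); s <- runif(1, 0.01, 1)
    t <- betaToOr(b, s)
    expect_equal(sqrt(t$ciLow * t$ciHigh), t$or, tolerance = 1e-12)
  }
})

test_that("estimators share scale equivariance and orientation invariance", {
  set.seed(21)
  k <- 12
  bx <- runif(k, 0.05, 0.3)
  by <- 0.25 * bx + rnorm(k, 0, 0.02)
  seY <- runif(k, 0.02, 0.1)
  h <- makeHarmonized(bx = bx, by = by, seY = seY)

  # scaling outcome effects and SEs by c scales beta by c, p unchanged
  c0 <- 3.7
  hs <- makeHarmonized(bx = bx, by = c0 * by, seY = c0 * seY)
  for (fn in list(function(x) mrIvw(x)$estimate,
                  function(x) mrEgger(x)$estimate)) {
    e1 <- fn(h); e2 <- fn(hs)
    expect_equal(e2@beta, c0 * e1@beta, tolerance = 1e-10)
    expect_equal(e2@pval, e1@pval, tolerance = 1e-10)
  }

  # joint re-orientation of a subset leaves every estimator unchanged
  flip <- c(2, 5, 9)
  sgn <- rep(1, k); sgn[flip] <- -1
  hf <- makeHarmonized(bx = sgn * bx, by = sgn * by, seY = seY,
                       seX = h@seX)
  expect_equal(mrIvw(hf)$estimate@beta, mrIvw(h)$estimate@beta)
  expect_equal(mrEgger(hf)$estimate@beta, mrEgger(h)$estimate@beta)
  expect_equal(weightedMedian(hf, nBoot = 10, seed = 6)@beta,
               weightedMedian(h, nBoot = 10, seed = 6)@beta)
  expect_equal(weightedMode(hf, nBoot = 10, seed = 6)@beta,
               weightedMode(h, nBoot = 10, seed = 6)@beta)
})

test_that("with strong clean instruments all four estimators agree", {
  trip <- simulateTriplet(simConfig(seed = 77))
  s <- runMrSuite(trip$exposure, trip$outcome, nBoot = 300, seed = 9)
  ivw <- estimate(s, "ivw_random")
  for (m in c("egger", "weighted_median", "weighted_mode")) {
    e <- estimate(s, m)
    expect_lt(abs(e@beta - ivw@beta),
              2 * sqrt(e@se^2 + ivw@se^2))
  }
})
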