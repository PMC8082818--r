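test_that("the spline basis is centered and reproduces cubics exactly", {
  tt <- seq(0, 1, length.out = 100)
  b <- buildSplineBasis(tt, K = 6)
  expect_lt(max(abs(colMeans(b@design))), 1e-10)
  expect_true(isTRUE(all.equal(b@penalty, t(b@penalty))))
  expect_true(all(eigen(b@penalty, only.values = TRUE)$values > -1e-8))

  # cubic reproduction by least squares on [intercept | basis]
  y <- tt^3
  fit <- lm.fit(cbind(1, b@design), y)
  expect_lt(max(abs(fit$residuals)), 1e-6)

  # a constant function projects to ~zero spline coefficients
  cf <- lm.fit(cbind(1, b@design), rep(2.5, 100))
  expect_lt(max(abs(cf$coefficients[-1])), 1e-8)

  # degenerate inputs
  expect_error(buildSplineBasis(rep(0.5, 10)), "degenerate")
  expect_warning(buildSplineBasis(rep(c(0, 0.3, 0.6, 1, 0.8), 4), K = 6),
                 "reducing K")
})

test_that("NB-GAM fits recover a linear trend and match an independent
           GAM implementation", {
  set.seed(31)
  n <- 1000
  tt <- normalizePseudotime(runif(n))
  y <- rnbinom(n, mu = exp(1 + 2 * tt), size = 5)
  f <- fitNBGAM(y, tt)
  target <- 2 * tt - 2 * mean(tt)
  expect_lt(max(abs(f@fhat - target)), 0.15)
  expect_gt(f@phi, 0)
  expect_lt(abs(mean(f@fhat)), 1e-8)

  # cross-check against mgcv on the same basis (independent route)
  dat <- data.frame(y = y, t = tt)
  g <- mgcv::gam(y ~ s(t, k = 6, bs = "bs", m = c(3, 2)), data = dat,
                 family = mgcv::nb(), method = "REML")
  expect_gt(cor(f@fhat, predict(g, type = "terms")[, 1]), 0.999)
  expect_lt(abs(f@loglik - as.numeric(stats::logLik(g))), 1)
  expect_lt(abs(log(f@phi / g$family$getTheta(TRUE))), 0.15)

  expect_error(fitNBGAM(rep(0, 50), seq(0, 1, length.out = 50)), "all-zero")
  expect_error(fitNBGAM(c(-1, 2, 3), c(0, 0.5, 1)), "non-negative")
})

test_that("equidispersed counts drive the NB fit to its Poisson limit", {
  set.seed(5)
  n <- 500
  tt <- normalizePseudotime(runif(n))
  y <- rpois(n, lambda = exp(2 + tt))
  f <- fitNBGAM(y, tt)
  expect_gt(f@phi, 100)  # 1/phi -> 0
})

test_that("asymptotic p-values are approximately uniform for null genes", {
  set.seed(17)
  ps <- replicate(200, {
    tt <- normalizePseudotime(runif(400))
    y <- rnbinom(400, mu = 5, size = 2)
    asymptoticPvalue(fitNBGAM(y, tt))
  })
  expect_gt(mean(ps <= 0.05), 0.015)
  expect_lt(mean(ps <= 0.05), 0.105)
  expect_gt(mean(ps <= 0.5), 0.40)
  expect_lt(mean(ps <= 0.5), 0.68)
  # the asymptotic approximation carries a small liberal bias (documented
  # in the vignette); distance from uniformity stays modest
  expect_lt(max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps))), 0.2)

  # power + monotonicity: strong DE gene versus null gene
  set.seed(18)
  tt <- normalizePseudotime(runif(500))
  yDE <- rnbinom(500, mu = exp(1 + 3 * sin(2 * pi * tt)), size = 5)
  expect_lt(asymptoticPvalue(fitNBGAM(yDE, tt)), 1e-4)
})

test_that("zero-inflated fits recover dropout parameters by EM", {
  set.seed(42)
  n <- 500
  tt <- normalizePseudotime(runif(n))
  basis <- buildSplineBasis(tt)
  mu <- exp(1.5 + 1.2 * sin(2 * pi * tt))
  rec <- t(vapply(1:30, function(r) {
    y <- rnbinom(n, mu = mu, size = 3)
    p <- plogis(1 + 0.5 * log(mu))
    y <- y * rbinom(n, 1, p)
    f <- suppressWarnings(fitZINBGAM(y, tt, basis = basis))
    c(f@alpha0, f@alpha1, all(diff(f@emTrace) > -1e-5 * abs(f@emTrace[-1])))
  }, numeric(3)))
  # recovered alphas within 3 Monte-Carlo s.e. of the truth
  expect_lt(abs(mean(rec[, 1]) - 1), 3 * sd(rec[, 1]) / sqrt(nrow(rec)))
  expect_lt(abs(mean(rec[, 2]) - 0.5), 3 * sd(rec[, 2]) / sqrt(nrow(rec)))
  # EM ascends its penalized observed-data likelihood
  expect_true(all(rec[, 3] == 1))
})

test_that("without excess zeros the ZINB model degenerates to NB", {
  set.seed(6)
  n <- 400
  tt <- normalizePseudotime(runif(n))
  y <- rnbinom(n, mu = exp(0.5 + tt), size = 2)  # natural NB zeros only
  basis <- buildSplineBasis(tt)
  nb <- fitNBGAM(y, tt, basis = basis)
  zinb <- suppressWarnings(fitZINBGAM(y, tt, basis = basis))
  expect_gt(mean(zinb@pzero), 0.9)      # observation probability near 1
  expect_gte(zinb@loglik, nb@loglik - 1e-6)  # nesting
  expect_lt(zinb@loglik - nb@loglik, 2)      # no spurious improvement
  sel <- selectModel(nb, zinb, mode = "auto", delta = 10)
  expect_equal(sel@flavor, "NB")

  # a gene without zeros short-circuits to the NB fit with a note
  ypos <- y + 1L
  f <- fitZINBGAM(ypos, tt, basis = basis)
  expect_equal(f@flavor, "NB")
  expect_match(f@notes, "no zeros")
})

test_that("model selection applies the AIC-improvement rule", {
  x <- tinyLineage()
  basis <- buildSplineBasis(x$tt)
  y <- x$counts[, which(x$isDE)[1]]
  nb <- fitNBGAM(y, x$tt, basis = basis)
  zinb <- suppressWarnings(fitZINBGAM(y, x$tt, basis = basis))

  fake <- function(fit, aic) { fit@aic <- aic; fit }
  # improvement 5 < 10: keep NB; improvement 11 >= 10: switch to ZINB
  expect_equal(selectModel(fake(nb, 100), fake(zinb, 95), "auto")@aic, 100)
  expect_equal(selectModel(fake(nb, 100), fake(zinb, 89), "auto")@aic, 89)
  # forced modes bypass the comparison
  expect_equal(selectModel(fake(nb, 100), fake(zinb, 1), "nb")@flavor, "NB")
  # unconverged ZINB always falls back
  zbad <- fake(zinb, 1); zbad@converged <- FALSE
  expect_warning(sel <- selectModel(nb, zbad, "auto"), "unconverged")
  expect_equal(sel@flavor, "NB")
})

test_that("the quadratic-form statistic matches an eigendecomposition
           oracle", {
  # identity covariance: s = |fhat|^2
  expect_equal(as.numeric(computeStatistic(c(3, 4), Vf = diag(2))), 25)
  # zero smooth: s = 0
  expect_equal(as.numeric(computeStatistic(c(0, 0), Vf = diag(2))), 0)

  set.seed(12)
  for (r in 1:100) {
    V <- randomPSD(6, 3)
    f <- V %*% rnorm(6)  # fhat in the column space
    s <- computeStatistic(as.numeric(f), Vf = V)
    expect_lt(abs(s - bruteStat(as.numeric(f), V)), 1e-8)
  }

  # the GAMFit method agrees with the dense-covariance route
  x <- tinyLineage()
  fit <- fitNBGAM(x$counts[, 3], x$tt)
  sLow <- computeStatistic(fit)
  sDense <- computeStatistic(fit@fhat, Vf = smoothCovariance(fit),
                             edf = fit@edf)
  expect_lt(abs(sLow - sDense) / (abs(sLow) + 1e-8), 1e-6)
  # and with the value stored at fit time
  expect_lt(abs(sLow - fit@statistic) / (abs(sLow) + 1e-8), 1e-8)

  expect_error(computeStatistic(c(1, 2), Vf = matrix(0, 2, 2)), "undefined")
})

test_that("the statistic is invariant to reversing pseudotime direction", {
  x <- tinyLineage()
  for (j in c(2, 11, 25)) {
    f1 <- fitNBGAM(x$counts[, j], x$tt)
    f2 <- fitNBGAM(x$counts[, j], 1 - x$tt)
    expect_lt(abs(f1@statistic - f2@statistic) / (abs(f1@statistic) + 1e-8),
              1e-4)
  }
})
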