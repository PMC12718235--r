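test_that("uniform and degenerate-mixture densities are flat at 1/vMax", {
  u <- asFitResult(distSpec("uniform"))
  expect_equal(speedPdf(u, 50), 0.01)
  expect_equal(speedPdf(u, c(-1, 0, 101)), c(0, 0, 0))
  m0 <- asFitResult(distSpec("lognormal", mixture = TRUE),
                    c(meanlog = 0.5, sdlog = 0.5, w = 0))
  x <- c(0.5, 10, 99.5)
  expect_equal(speedPdf(m0, x), rep(0.01, 3))
})

test_that("every candidate density integrates to 1 over its support", {
  pool <- defaultSpecPool(100)
  params <- list(
    lognormal = c(meanlog = 0.7, sdlog = 0.6),
    cauchy = c(location = 2, scale = 1),
    normal = c(mean = 5, sd = 10),
    gamma = c(shape = 1.5, rate = 0.4),
    weibull = c(shape = 1.2, scale = 8),
    exponential = c(rate = 0.2),
    uniform = numeric())
  for (spec in pool) {
    p <- params[[spec@family]]
    if (spec@mixture) p <- c(p, w = 0.6)
    fit <- asFitResult(spec, p)
    z <- integrate(function(x) speedPdf(fit, x), 0, 100,
                   rel.tol = 1e-9, subdivisions = 500L)$value
    expect_lt(abs(z - 1), 1e-6)
  }
})

test_that("truncated Cauchy(2,1) on (0,100] is a proper density", {
  fit <- asFitResult(distSpec("cauchy"), c(location = 2, scale = 1))
  z <- integrate(function(x) speedPdf(fit, x), 0, 100, rel.tol = 1e-10)$value
  expect_lt(abs(z - 1), 1e-6)
  expect_equal(speedPdf(fit, 150), 0)
})

test_that("lognormal MLE recovers generating parameters", {
  set.seed(11)
  x <- rTruncLnorm(5000, 0.7, 0.6)
  fit <- fitMLE(x, distSpec("lognormal"), nRestarts = 5, seed = 11)
  expect_true(fit@converged)
  expect_lt(abs(fit@params[["meanlog"]] - 0.7), 0.03)
  expect_lt(abs(fit@params[["sdlog"]] - 0.6), 0.02)
})

test_that("mixture MLE recovers the weight and flat data gives the exact uniform logL", {
  set.seed(12)
  x <- rLnormUnifMix(5000, 0.7, 0.7, 0.6)
  fit <- fitMLE(x, distSpec("lognormal", mixture = TRUE),
                nRestarts = 6, seed = 12)
  expect_lt(abs(fit@params[["w"]] - 0.7), 0.05)

  xc <- rep(42, 100)
  fu <- fitMLE(xc, distSpec("uniform"))
  expect_equal(fu@logLik, 100 * log(0.01))
})

test_that("samples outside the support or too few samples are input errors", {
  expect_error(fitMLE(c(-1, seq_len(20)), distSpec("lognormal")), "support")
  expect_error(fitMLE(1:5, distSpec("lognormal")), "at least 10")
})

test_that("a mixture never scores below its nested single family", {
  set.seed(21)
  for (fam in c("lognormal", "cauchy", "gamma")) {
    x <- rTruncLnorm(800, 0.8, 0.7)
    single <- fitMLE(x, distSpec(fam), nRestarts = 4, seed = 1)
    mix <- fitMLE(x, distSpec(fam, mixture = TRUE), nRestarts = 4, seed = 1)
    expect_gte(mix@logLik, single@logLik - 1e-6)
  }
})

test_that("MLE logL is at least the logL at the generating parameters", {
  set.seed(31)
  x <- rTruncLnorm(2000, 0.6, 0.7)
  fit <- fitMLE(x, distSpec("lognormal"), nRestarts = 5, seed = 2)
  atTruth <- asFitResult(distSpec("lognormal"),
                         c(meanlog = 0.6, sdlog = 0.7), samples = x)
  expect_gte(fit@logLik, atTruth@logLik - 1e-6)
})

test_that("fitMLE matches a dense grid-search oracle within 0.1 log-units", {
  set.seed(41)
  x <- rTruncLnorm(200, 0.7, 0.6)
  fit <- fitMLE(x, distSpec("lognormal"), nRestarts = 5, seed = 3)
  grid <- expand.grid(m = seq(0.4, 1.0, length.out = 120),
                      s = seq(0.4, 0.9, length.out = 120))
  gl <- mapply(function(m, s) {
    sum(dlnorm(x, m, s, log = TRUE)) - length(x) * log(plnorm(100, m, s))
  }, grid$m, grid$s)
  expect_lt(max(gl) - fit@logLik, 0.1)
  expect_gte(fit@logLik, max(gl) - 0.1)
})

test_that("information criteria follow their definitions", {
  fit <- new("FitResult", spec = distSpec("lognormal"),
             params = c(meanlog = 0, sdlog = 1), logLik = -100,
             n = 100L, converged = TRUE, nRestartsUsed = 1L)
  ic <- informationCriteria(fit)
  expect_equal(ic[["AIC"]], 204)
  expect_equal(ic[["BIC"]], 2 * log(100) + 200)
  expect_equal(ic[["HQC"]], 4 * log(log(100)) + 200)

  u <- asFitResult(distSpec("uniform"))
  u@logLik <- -50; u@n <- 10L
  expect_equal(informationCriteria(u)[["AIC"]], 100)  # k = 0

  tiny <- fit; tiny@n <- 2L
  expect_error(informationCriteria(tiny), "too small")

  # nested pair identity: AIC difference is 2*dk - 2*dlogL
  set.seed(5)
  x <- rTruncLnorm(500, 0.7, 0.6)
  f1 <- fitMLE(x, distSpec("lognormal"), nRestarts = 3, seed = 1)
  f2 <- fitMLE(x, distSpec("lognormal", mixture = TRUE), nRestarts = 3,
               seed = 1)
  dAIC <- informationCriteria(f2)[["AIC"]] - informationCriteria(f1)[["AIC"]]
  expect_equal(dAIC, 2 * 1 - 2 * (f2@logLik - f1@logLik), tolerance = 1e-8)
})

test_that("rankModels recovers generators and is order-invariant", {
  set.seed(51)
  x <- rLnormUnifMix(3000, 0.65, 0.6, 0.7)
  rk <- rankModels(x, seed = 7, nRestarts = 4)
  tb <- rankingTable(rk)
  expect_equal(tb$family[1], "lognormal")
  expect_true(tb$mixture[1])
  expect_lte(nrow(tb), 10)
  expect_true(all(diff(tb$BIC) >= 0))

  xu <- runif(3000, 0, 100)
  rku <- rankModels(xu, seed = 7, nRestarts = 4)
  expect_equal(rankingTable(rku)$family[1], "uniform")

  # order invariance
  rk2 <- rankModels(sample(x), seed = 7, nRestarts = 4)
  expect_equal(rankingTable(rk2)$BIC, tb$BIC, tolerance = 1e-8)
  expect_equal(rankingTable(rk2)$family, tb$family)

  # single-spec pool
  rk1 <- rankModels(x, pool = list(distSpec("lognormal")), seed = 1,
                    nRestarts = 3)
  expect_equal(nrow(rankingTable(rk1)), 1)
})

test_that("sampleSpeeds draws agree with the model CDF", {
  fit <- asFitResult(distSpec("lognormal", mixture = TRUE),
                     c(meanlog = 0.6, sdlog = 0.7, w = 0.65))
  x <- sampleSpeeds(fit, 20000, seed = 99)
  expect_true(all(x > 0 & x <= 100))
  for (q in c(2, 5, 20, 60))
    expect_lt(abs(mean(x <= q) - speedCdf(fit, q)), 0.015)
})
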