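test_that("closed-form lognormal pair intersects at exp(1/2)", {
  a <- asFitResult(distSpec("lognormal", support = c(0, Inf)),
                   c(meanlog = 0, sdlog = 1))
  b <- asFitResult(distSpec("lognormal", support = c(0, Inf)),
                   c(meanlog = 1, sdlog = 1))
  rts <- roots(pdfIntersections(a, b, c(0.1, 10)))
  expect_length(rts, 1)
  expect_lt(abs(rts - exp(0.5)), 1e-6)
  expect_lt(abs(speedPdf(a, rts) - speedPdf(b, rts)), 1e-9)
})

test_that("identical fits give an empty intersection set, not an error", {
  a <- asFitResult(distSpec("lognormal"), c(meanlog = 0.5, sdlog = 0.6))
  expect_length(roots(pdfIntersections(a, a, c(0.5, 20))), 0)
})

test_that("intersections match a brute-force dense sign scan", {
  set.seed(13)
  bruteRoots <- function(fa, fb, lo, hi, n = 1e6) {
    g <- seq(lo, hi, length.out = n)
    d <- speedPdf(fa, g) - speedPdf(fb, g)
    i <- which(sign(d[-n]) * sign(d[-1]) < 0)
    (g[i] + g[i + 1]) / 2
  }
  # uniform vs half-weight mixture (one analytic-style case)
  u <- asFitResult(distSpec("uniform"))
  m <- asFitResult(distSpec("lognormal", mixture = TRUE),
                   c(meanlog = 0.8, sdlog = 0.7, w = 0.5))
  r1 <- roots(pdfIntersections(u, m, c(0.1, 50)))
  b1 <- bruteRoots(u, m, 0.1, 50)
  expect_equal(length(r1), length(b1))
  expect_true(all(abs(r1 - b1) < 1e-4))

  # 20 random fitted-model pairs
  for (k in 1:20) {
    fa <- asFitResult(distSpec("lognormal", mixture = TRUE),
                      c(meanlog = runif(1, 0, 1.2), sdlog = runif(1, 0.4, 1),
                        w = runif(1, 0.4, 0.95)))
    fb <- asFitResult(distSpec("cauchy", mixture = TRUE),
                      c(location = runif(1, 0.5, 4), scale = runif(1, 0.5, 3),
                        w = runif(1, 0.4, 0.95)))
    r <- roots(pdfIntersections(fa, fb, c(0.2, 80)))
    b <- bruteRoots(fa, fb, 0.2, 80)
    expect_equal(length(r), length(b))
    if (length(r)) expect_true(all(abs(sort(r) - sort(b)) < 1e-4))
  }
})

test_that("splitAt partitions, summarises and reports fractions", {
  sp <- splitAt(list(p = c(1, 2, 3, 10, 20)), threshold = 5)
  tb <- regimeSummary(sp)
  slow <- tb[tb$regime == "slow", ]
  fast <- tb[tb$regime == "fast", ]
  expect_equal(slow$n, 3); expect_equal(slow$mean, 2)
  expect_equal(fast$n, 2); expect_equal(fast$mean, 15)
  expect_equal(unname(slowFraction(sp)["p"]), 60)

  below <- splitAt(list(p = c(5, 6, 7)), threshold = 1)
  expect_equal(unname(slowFraction(below)["p"]), 0)

  empty <- splitAt(list(p = numeric()), threshold = 5)
  expect_equal(regimeSummary(empty)$n, c(0, 0))
})

test_that("split conserves counts/sums, is order-invariant and monotone", {
  set.seed(31)
  v <- rLnormUnifMix(4000, 0.7, 0.7, 0.6)
  sp <- splitAt(list(a = v), 5.44)
  expect_equal(length(sp@slow$a) + length(sp@fast$a), length(v))
  expect_equal(sum(sp@slow$a) + sum(sp@fast$a), sum(v))
  expect_true(all(sp@slow$a < 5.44) && all(sp@fast$a >= 5.44))
  sp2 <- splitAt(list(a = sample(v)), 5.44)
  expect_equal(slowFraction(sp2), slowFraction(sp))
  fr <- sapply(c(2, 5, 10, 30), function(thr)
    slowFraction(splitAt(list(a = v), thr))["a"])
  expect_true(all(diff(fr) >= 0))
})

test_that("a planted 70/30 slow/fast composition is recovered at the boundary", {
  set.seed(31)
  n <- 6000
  slow <- rTruncLnorm(round(0.7 * n), 0.6, 0.5, hi = 5)       # all < 5
  fast <- 5 + 95 * rbeta(n - length(slow), 1, 3)              # all >= 5
  sp <- splitAt(list(pop = c(slow, fast)), threshold = 5)
  expect_equal(unname(slowFraction(sp)["pop"]), 70, tolerance = 0.001)
})

test_that("subrange refits run on both sides and flag empty subsets", {
  set.seed(42)
  x <- rLnormUnifMix(3000, 0.7, 0.7, 0.6)
  sr <- subrangeRefit(x, cut = 60, seed = 1, nRestarts = 3)
  expect_false(sr$slowFlagged)
  expect_false(sr$fastFlagged)
  expect_s4_class(sr$slow, "ModelRanking")
  expect_s4_class(sr$fast, "ModelRanking")
  expect_true(all(rankingTable(sr$slow)$logL > -Inf))
  expect_type(sr$mixtureDominated, "logical")

  # single-family data: fast subset nearly empty -> flagged
  set.seed(41)
  y <- rTruncLnorm(2000, 0.5, 0.5)   # essentially no mass near 60
  sr2 <- subrangeRefit(y, cut = 60, seed = 1, nRestarts = 3)
  expect_true(sr2$fastFlagged)
  expect_false(isTRUE(sr2$mixtureDominated))

  sr3 <- subrangeRefit(c(rep(1, 50), 2, 3), cut = 60, seed = 1,
                       nRestarts = 3)
  expect_true(sr3$fastFlagged)   # cut above max(samples)
})
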