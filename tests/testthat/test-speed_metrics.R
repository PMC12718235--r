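test_that("speed is consecutive-frame displacement over time (3-4-5 triangle)", {
  ts <- TrackSet(data.frame(track_id = "A", frame = 0:1,
                            x = c(0, 3), y = c(0, 4)), frameInterval = 0.024)
  s <- instantaneousSpeeds(ts)
  expect_equal(nrow(s), 1)
  expect_equal(s$speed, 5 / 0.024)
  expect_equal(s$dt, 0.024)
})

test_that("frame gaps yield no speed sample", {
  ts <- TrackSet(data.frame(track_id = "A", frame = c(0L, 2L),
                            x = c(0, 3), y = c(0, 4)))
  expect_equal(nrow(instantaneousSpeeds(ts)), 0)
})

test_that("a non-positive time step is a data error naming the track", {
  ts <- TrackSet(data.frame(track_id = "bad", frame = 0:1, x = 0:1, y = 0,
                            t = c(0.5, 0.5)))
  expect_error(instantaneousSpeeds(ts), "bad")
})

test_that("a noise-free constant-speed runner gives exactly constant speeds", {
  net <- new("HyphalNetwork",
             segments = list(cbind(seq(0, 2000, by = 500), 50)),
             adjacency = data.frame(segment = 1L, parent = 0L,
                                    parentVertex = 1L),
             box = c(2000, 100))
  cfg <- agentConfig(30, proportions = c(microcolony = 0, slow = 0, fast = 1),
                     fastLaw = list(family = "constant", value = 20),
                     switchRate = 0)
  paths <- simulateAgents(net, cfg, durationS = 0.5, seed = 4)
  obs <- observeTracks(paths, observationModel(noiseSd = 0, dropoutProb = 0),
                       seed = 4)
  v <- instantaneousSpeeds(obs)$speed
  # straight rail: every step is exactly 20 µm/s except the rare
  # reflection step at a rail end, which can only shorten the chord
  expect_true(mean(abs(v - 20) < 1e-9) > 0.95)
  expect_true(all(v <= 20 + 1e-9))
})

test_that("path length sums consecutive displacements, including across gaps", {
  tr <- data.frame(track_id = "p", frame = c(0L, 1L, 3L),
                   x = c(0, 3, 3), y = c(0, 4, 10))
  expect_equal(trajectoryPathLength(TrackSet(tr)), 11)
  one <- data.frame(track_id = "s", frame = 0L, x = 1, y = 1)
  expect_equal(trajectoryPathLength(TrackSet(one)), 0)
  sq <- data.frame(track_id = "q", frame = 0:4,
                   x = c(0, 2, 2, 0, 0), y = c(0, 0, 2, 2, 0))
  expect_equal(trajectoryPathLength(TrackSet(sq)), 8)  # path, not displacement
})

test_that("the 4-track fixture filters exactly as specified, boundaries retained", {
  fl <- applyFilters(filterFixture())
  r <- fl$report
  expect_equal(r@nTracksIn, 4L)
  expect_equal(r@nTracksRemovedDuration, 1L)
  expect_equal(r@nTracksRemovedLength, 1L)
  expect_equal(r@nSamplesRemovedByCutoff, 1L)
  expect_false("shortT" %in% fl$samples$track_id)
  expect_false("shortP" %in% fl$samples$track_id)
  expect_equal(r@cutoffExcludedPercent,
               100 * 1 / r@nSpeedSamplesBeforeCutoff)

  # boundary values are retained: exactly 0.25 s, exactly 5 µm, exactly 100 µm/s
  dt <- 0.025
  bnd <- TrackSet(data.frame(track_id = "b", frame = 0:10,
                             x = seq(0, 5, length.out = 11), y = 0),
                  frameInterval = dt)  # duration 0.25 s, path 5 µm
  fb <- applyFilters(bnd)
  expect_equal(fb$report@nTracksRemovedDuration, 0L)
  expect_equal(fb$report@nTracksRemovedLength, 0L)
  # dt and step chosen binary-exact so the speed is exactly 100
  v100 <- TrackSet(data.frame(track_id = "c", frame = 0:19,
                              x = (0:19) * 25, y = 0),
                   frameInterval = 0.25)
  expect_equal(unique(instantaneousSpeeds(v100)$speed), 100)
  expect_equal(applyFilters(v100)$report@nSamplesRemovedByCutoff, 0L)
})

test_that("cutoff percent is 0 when all speeds are within range", {
  fl <- applyFilters(TrackSet(runnerTrack(n = 40)))
  expect_equal(fl$report@cutoffExcludedPercent, 0)
})

test_that("planted exceedances are excluded at close to the planted rate", {
  # 50 valid runner tracks; 2% of steps doubled to exceed 100 µm/s
  set.seed(7)
  dt <- 0.024
  rows <- lapply(1:50, function(i) {
    n <- 41
    dx <- rep(30 * dt, n - 1)
    fastIdx <- which(runif(n - 1) < 0.02)
    dx[fastIdx] <- 150 * dt
    data.frame(track_id = sprintf("t%02d", i), frame = 0:(n - 1),
               x = cumsum(c(0, dx)), y = 0)
  })
  ts <- TrackSet(do.call(rbind, rows), frameInterval = dt)
  r <- applyFilters(ts)$report
  p <- r@cutoffExcludedPercent / 100
  se <- sqrt(0.02 * 0.98 / r@nSpeedSamplesBeforeCutoff)
  expect_lt(abs(p - 0.02), 3 * se + 1e-12)
})

test_that("filtering is idempotent and conserves counts", {
  fl1 <- applyFilters(filterFixture())
  kept <- TrackSet(detections(filterFixture())[
    detections(filterFixture())$track_id %in% unique(fl1$samples$track_id), ],
    frameInterval = 0.03)
  # second pass on surviving tracks removes no tracks
  fl2 <- applyFilters(kept)
  expect_equal(fl2$report@nTracksRemovedDuration, 0L)
  expect_equal(fl2$report@nTracksRemovedLength, 0L)
  # conservation at the sample stage
  r <- fl1$report
  expect_equal(nrow(fl1$samples) + r@nSamplesRemovedByCutoff,
               r@nSpeedSamplesBeforeCutoff)
  expect_true(all(fl1$samples$speed >= 0 & fl1$samples$speed <= 100))
})

test_that("speeds scale homogeneously with coordinates", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    d <- data.frame(track_id = "h", frame = 0:(n - 1),
                    x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    c0 <- runif(1, 0.1, 10)
    s1 <- instantaneousSpeeds(TrackSet(d))$speed
    d2 <- d; d2$x <- d2$x * c0; d2$y <- d2$y * c0
    s2 <- instantaneousSpeeds(TrackSet(d2))$speed
    expect_equal(s2, c0 * s1, tolerance = 1e-12)
  }
})

test_that("summarizeSpeeds: mean, sample sd, formatting, degenerate inputs", {
  s <- summarizeSpeeds(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$label, "2.00 ± 1.00")
  s1 <- summarizeSpeeds(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  s0 <- summarizeSpeeds(numeric())
  expect_equal(s0$n, 0)
  expect_true(is.na(s0$mean))

  # closed-form lognormal mean on a large sample
  set.seed(3)
  x <- rlnorm(10000, 0.6, 0.62)
  expect_lt(abs(summarizeSpeeds(x)$mean - exp(0.6 + 0.62^2 / 2)), 0.05)
})
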