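# Fixtures and independent reference samplers used across the test files.
# The samplers here deliberately avoid the package's own sampling code so
# that parameter-recovery tests check the fitters against an independent
# generative route.

# inverse-CDF draw from a lognormal truncated to (0, hi]
rTruncLnorm <- function(n, meanlog, sdlog, hi = 100) {
  qlnorm(runif(n) * plnorm(hi, meanlog, sdlog), meanlog, sdlog)
}

# inverse-CDF draw from a Cauchy truncated to (lo, hi]
rTruncCauchy <- function(n, location, scale, lo = 0, hi = 100) {
  a <- pcauchy(lo, location, scale)
  b <- pcauchy(hi, location, scale)
  qcauchy(a + runif(n) * (b - a), location, scale)
}

# w * truncated-lognormal + (1 - w) * uniform(0, hi]
rLnormUnifMix <- function(n, w, meanlog, sdlog, hi = 100) {
  comp <- runif(n) < w
  out <- numeric(n)
  out[comp] <- rTruncLnorm(sum(comp), meanlog, sdlog, hi)
  out[!comp] <- runif(sum(!comp), 0, hi)
  out
}

# a small TrackSet built by hand: one straight mover and one L-shaped path
twoTrackSet <- function(frameInterval = 0.024) {
  d <- rbind(
    data.frame(track_id = "m1", frame = 0:10,
               x = seq(0, 10, by = 1), y = 0),
    data.frame(track_id = "m2", frame = 0:5,
               x = c(0, 3, 3, 3, 3, 3), y = c(0, 0, 2, 4, 6, 8)))
  TrackSet(d, frameInterval = frameInterval)
}

# constant-speed runner along x at `speed` µm/s for n frames
runnerTrack <- function(id = "r", speed = 20, n = 50, dt = 0.024) {
  data.frame(track_id = id, frame = seq_len(n) - 1L,
             x = (seq_len(n) - 1L) * speed * dt, y = 0)
}

# the 4-track filter fixture: one too short in time, one too short in path,
# one valid but with a single 150 µm/s jump among 9 ordinary steps, one
# fully valid
filterFixture <- function(dt = 0.03) {
  tooShortTime <- data.frame(track_id = "shortT", frame = 0:8,
                             x = seq(0, 8) * 2, y = 0)       # 0.24 s < 0.25
  tooShortPath <- data.frame(track_id = "shortP", frame = 0:20,
                             x = seq(0, 20) * 0.19, y = 0)   # 3.8 µm < 5
  jump <- runnerTrack("jump", speed = 20, n = 11, dt = dt)   # 0.30 s
  jump$x[11] <- jump$x[10] + 150 * dt                        # one 150 µm/s step
  good <- runnerTrack("good", speed = 20, n = 30, dt = dt)
  TrackSet(rbind(tooShortTime, tooShortPath, jump, good), frameInterval = dt)
}
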