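test_that("network generation is seeded, seed-sensitive, and box-checked", {
  n1 <- generateNetwork(1, nBranches = 1)
  n1b <- generateNetwork(1, nBranches = 1)
  expect_length(n1@segments, 1)
  expect_identical(n1@segments, n1b@segments)
  n2 <- generateNetwork(2, nBranches = 1)
  expect_false(identical(n1@segments, n2@segments))
  expect_error(generateNetwork(1, stepUm = 50, boxUm = c(100, 100)),
               "too small")
})

test_that("an 8-branch network has 8 leaf tips, all reachable from the origin", {
  net <- generateNetwork(3, nBranches = 8)
  expect_equal(nrow(leafTips(net)), 8)
  # reachability: walk each segment's parent chain back to the trunk
  adj <- net@adjacency
  for (i in seq_len(nrow(adj))) {
    j <- i
    while (adj$parent[j] != 0L) j <- adj$parent[j]
    expect_equal(j, 1L)
  }
  # every route is a connected polyline: consecutive points at most a step apart
  for (r in hyphalTracks:::networkRoutes(net)) {
    steps <- sqrt(rowSums(diff(r)^2))
    expect_true(all(steps <= 5 + 1e-9))
  }
})

test_that("pure microcolony agents jitter in place and are filtered out downstream", {
  net <- generateNetwork(5, nBranches = 4)
  cfg <- agentConfig(40, proportions = c(microcolony = 1, slow = 0, fast = 0),
                     jitterSd = 0.005, switchRate = 0)
  paths <- simulateAgents(net, cfg, durationS = 10, seed = 5)
  plen <- vapply(paths$positions, function(p) sum(sqrt(rowSums(diff(p)^2))), 0)
  expect_true(mean(plen < 5) > 0.95)
  obs <- observeTracks(paths, observationModel(noiseSd = 0, dropoutProb = 0),
                       seed = 5)
  fl <- applyFilters(obs)
  expect_equal(nrow(fl$samples), 0)
  expect_equal(fl$report@nTracksIn,
               fl$report@nTracksRemovedDuration +
                 fl$report@nTracksRemovedLength)
})

test_that("state occupancy approaches the configured stationary proportions", {
  net <- generateNetwork(6, nBranches = 4)
  cfg <- agentConfig(150, proportions = c(microcolony = 0.3, slow = 0.4,
                                          fast = 0.3),
                     switchRate = 2)
  paths <- simulateAgents(net, cfg, durationS = 10, seed = 5)
  occ <- table(factor(unlist(paths$states), levels = 1:3))
  occ <- occ / sum(occ)
  expect_lt(abs(occ[[1]] - 0.3), 0.03)
  expect_lt(abs(occ[[2]] - 0.4), 0.03)
  expect_lt(abs(occ[[3]] - 0.3), 0.03)
})

test_that("dropout fragments tracks; relabeling creates more tracks than agents", {
  net <- generateNetwork(7, nBranches = 4)
  cfg <- agentConfig(30, proportions = c(microcolony = 0, slow = 1, fast = 0))
  paths <- simulateAgents(net, cfg, durationS = 5, seed = 7)
  obs <- observeTracks(paths, observationModel(dropoutProb = 0.1,
                                               meanOffTime = 0.5), seed = 7)
  expect_gt(nTracks(obs), 30)
  # ground-truth linkage maps every track to exactly one agent
  link <- obs@metadata$linkage
  expect_true(all(table(link$track_id) == 1))
  expect_setequal(unique(detections(obs)$track_id), link$track_id)
})

test_that("localisation noise on a static agent produces the Rayleigh step law", {
  net <- generateNetwork(8, nBranches = 1)
  cfg <- agentConfig(25, proportions = c(microcolony = 1, slow = 0, fast = 0),
                     jitterSd = 0, switchRate = 0)
  paths <- simulateAgents(net, cfg, durationS = 10, seed = 8)
  sd0 <- 0.1
  obs <- observeTracks(paths, observationModel(noiseSd = sd0, dropoutProb = 0),
                       seed = 8)
  v <- instantaneousSpeeds(obs)$speed
  # Monte-Carlo oracle: || N(0, sd^2 I) - N(0, sd^2 I) || / dt
  set.seed(80)
  mc <- sqrt((rnorm(1e5, 0, sd0 * sqrt(2)))^2 +
             (rnorm(1e5, 0, sd0 * sqrt(2)))^2) / 0.024
  expect_lt(abs(mean(v) - mean(mc)) / mean(mc), 0.02)
})

test_that("simulation and observation are bit-deterministic given seeds", {
  net <- generateNetwork(9, nBranches = 4)
  cfg <- agentConfig(15)
  a <- observeTracks(simulateAgents(net, cfg, 2, seed = 3),
                     observationModel(), seed = 4)
  b <- observeTracks(simulateAgents(net, cfg, 2, seed = 3),
                     observationModel(), seed = 4)
  expect_identical(detections(a), detections(b))
})

test_that("paper-like datasets are deterministic, sized and majority-slow", {
  ds <- paperLikeDataset("UWC1", 1000, seed = 3)
  ds2 <- paperLikeDataset("UWC1", 1000, seed = 3)
  expect_identical(detections(ds$tracks), detections(ds2$tracks))
  fl <- applyFilters(ds$tracks)
  expect_gte(nrow(fl$samples), 1000)
  expect_lt(nrow(fl$samples), 1100)
  # the design target: roughly two thirds of measurements at low speeds
  expect_gt(mean(fl$samples$speed < 5.44), 0.5)
  expect_lt(mean(fl$samples$speed < 5.44), 0.85)
  expect_gt(max(fl$samples$speed), 50)  # heavy tail present
})

test_that("UWC1-like data hit the slow-fraction design window at 5.44 µm/s", {
  ds <- paperLikeDataset("UWC1", 7000, seed = 9)
  v <- applyFilters(ds$tracks)$samples$speed
  sf <- 100 * mean(v < 5.44)
  expect_gte(sf, 60); expect_lte(sf, 72)
})

test_that("KT2440-like data select lognormal+uniform as top model in most seeds", {
  hits <- 0L
  nSeeds <- 6
  for (s in seq_len(nSeeds)) {
    ds <- paperLikeDataset("KT2440", 3000, seed = 300 + s)
    v <- applyFilters(ds$tracks)$samples$speed
    v <- v[v > 0]
    rk <- rankModels(v, seed = s, nRestarts = 3)
    tb <- rankingTable(rk)
    if (tb$family[1] == "lognormal" && tb$mixture[1]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(nSeeds / 2) + 1L)
})
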