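# Perturbation protocols on fixtures (fast deterministic micro-networks);
# the full-network SND/SNS contrast lives in the acceptance suite.

test_that("baseline variability summarises PB counts over seeds", {
  net <- makeFixture("chain6")
  base <- baselineVariability(net, nRuns = 5, windowS = 4, seed = 100,
                              burnIn = 2000)
  expect_length(base$counts, 5)
  expect_equal(base$mean, mean(base$counts))
  expect_equal(base$band, base$mean + c(-3, 3) * base$sd)
  expect_true(base$usable)
  # repeated identical seed gives identical counts
  b2 <- baselineVariability(net, nRuns = 5, windowS = 4, seed = 100,
                            burnIn = 2000)
  expect_identical(base$counts, b2$counts)
})

test_that("deleting the chain leader silences the collective events", {
  net <- makeFixture("chain6")
  ctrl <- baselineVariability(net, nRuns = 3, windowS = 4, seed = 1,
                              burnIn = 2000)
  expect_gt(ctrl$mean, 20)                       # one PB per cycle
  snd <- sndExperiment(net, 1, windowS = 4, seed = 1, burnIn = 2000)
  expect_equal(snd$nPB, 0)                       # leader is necessary
  # deleting the tail neuron only shrinks participation, not the count
  snd6 <- sndExperiment(net, 6, windowS = 4, seed = 1, burnIn = 2000)
  expect_gt(snd6$nPB, 0.5 * ctrl$mean)
})

test_that("stimulation protocols sweep currents and report rates", {
  iso <- isolatedNet(14.0)
  r <- snsExperiment(iso, 1, 18, windowS = 2, seed = 1, burnIn = 500)
  expect_equal(r$rate, 1000 / naturalPeriod(18), tolerance = 0.05)

  sw <- sweepSNS(iso, 1, iRange = c(15.2, 16.0), step = 0.2, windowS = 2,
                 seed = 1, burnIn = 500)
  expect_equal(nrow(sw), 5)
  expect_true(all(diff(sw$rate) > 0))            # monotone in the current
  sw2 <- sweepSNS(iso, 1, iRange = c(15.2, 16.0), step = 0.2, windowS = 2,
                  seed = 1, burnIn = 500)
  expect_identical(sw, sw2)                      # reproducible per seed
})

test_that("the silent probe suppresses bursting only under stimulation", {
  net <- makeFixture("lc_probe")
  ctrl <- baselineVariability(net, nRuns = 3, windowS = 4, seed = 7,
                              burnIn = 2000)
  expect_gt(ctrl$mean, 20)
  # SND of the silent probe: no effect beyond baseline variability
  snd <- sndExperiment(net, 8, windowS = 4, seed = 7, burnIn = 2000)
  expect_lt(abs(snd$nPB - ctrl$mean), max(3 * ctrl$sd, 3))
  # SNS of the probe: inhibitory gate engages, bursts collapse >= 50%
  sns <- snsExperiment(net, 8, 16, windowS = 4, seed = 7, burnIn = 2000)
  expect_gte((ctrl$mean - sns$nPB) / ctrl$mean, 0.5)
})

test_that("driver classification applies the 50% and 3-SD gates jointly", {
  base <- list(mean = 60, sd = 2)
  snd <- c(10, 58, 55, 50, 61)                  # neuron 1: hub
  sns <- list(numeric(0),
              c(95, 60),                        # neuron 2: LC2 (increase)
              c(20, 100),                       # neuron 3: LC1 (both ways)
              c(62, 58),                        # neuron 4: within band
              c(64, 57))                        # neuron 5: small changes
  rep <- classifyDrivers(snd, sns, base)
  expect_equal(driverTable(rep)$driverClass,
               c("hub", "LC2", "LC1", "none", "none"))
  # a 50% change that stays inside a wide 3-SD band is not significant
  wide <- classifyDrivers(c(10, 58), list(numeric(0), c(95)),
                          list(mean = 60, sd = 20))
  expect_equal(driverTable(wide)$driverClass, c("none", "none"))
  # all outcomes within 3 SD -> everyone none
  quiet <- classifyDrivers(c(59, 61), list(c(60), c(62)),
                           list(mean = 60, sd = 2))
  expect_true(all(driverTable(quiet)$driverClass == "none"))
})

test_that("clique extraction recovers order, leader, routes and delays", {
  # hand-built spike table: 30 PBs, hubs 1-3 fire 10, 5, 2 ms before
  # each ignition volley with hub 1 leading
  pbTimes <- seq(1000, 30000, by = 1000)
  sp <- do.call(rbind, lapply(pbTimes, function(tp) rbind(
    data.frame(time = tp - 10, neuron = 1L),
    data.frame(time = tp - 5, neuron = 2L),
    data.frame(time = tp - 2, neuron = 3L),
    volley(tp, 30, start = 4L))))
  sd <- spikeTable(sp$time, sp$neuron, 31000, 40)
  ct <- detectBursts(sd)
  expect_equal(nrow(populationBursts(ct)), 30)
  cl <- extractClique(sd, ct, hubs = 1:3, windowMs = 70, maxLag = 50)
  expect_equal(cl$order, 1:3)
  expect_equal(cl$leader, 1L)
  expect_equal(cl$dominantRoute, "1 > 2 > 3")
  expect_equal(unname(cl$routes[1] / sum(cl$routes)), 1)  # single route
  expect_equal(cl$delays$mean, c(5, 3))
  expect_equal(cl$delays$sd, c(0, 0))

  # randomly ordered hubs: many routes, no dominant one
  set.seed(11)
  sp2 <- do.call(rbind, lapply(pbTimes, function(tp) rbind(
    data.frame(time = tp - sample(c(2, 5, 10)), neuron = 1:3),
    volley(tp, 30, start = 4L))))
  sd2 <- spikeTable(sp2$time, sp2$neuron, 31000, 40)
  cl2 <- extractClique(sd2, detectBursts(sd2), hubs = 1:3)
  expect_lt(cl2$routes[1] / sum(cl2$routes), 0.5)
})

test_that("resource monitoring reports pre-PB maxima and flags degenerates", {
  net <- makeFixture("chain6")
  sd <- simulateNetwork(net, 5000, seed = 2, burnIn = 2000, traceDt = 5,
                        traceNeurons = c(1, 6))
  ct <- detectBursts(sd)
  rm <- resourceMonitor(sd, ct, c(1, 6))
  # neuron 1 drives the chain: its efferent X is depleted and bounded
  expect_true(all(rm[["1"]]$prePB$xmax > 0 & rm[["1"]]$prePB$xmax <= 1))
  expect_equal(rm[["1"]]$xstar, min(rm[["1"]]$prePB$xmax))
  # neuron 6 has no efferent synapses: flagged, no trace
  expect_true(rm[["6"]]$flagged)
  expect_error(resourceMonitor(simulateNetwork(net, 200, burnIn = 0),
                               ct, 1), "no traces")
})
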