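test_that("PB detection uses the strict distinct-neuron threshold", {
  # 26 of 100 distinct neurons in one 10 ms bin -> one PB
  v <- volley(5, 26)
  ct <- detectBursts(spikeTable(v$time, v$neuron, 100, 100))
  expect_equal(nrow(populationBursts(ct)), 1)
  expect_equal(populationBursts(ct)$width, 10)
  expect_equal(populationBursts(ct)$nParticipants, 26)

  # exactly 25 -> no PB (strict inequality)
  v25 <- volley(5, 25)
  expect_equal(nrow(populationBursts(
    detectBursts(spikeTable(v25$time, v25$neuron, 100, 100)))), 0)

  # 26 spikes from 13 neurons -> not a PB under the distinct convention
  rep2 <- data.frame(time = rep(5, 26), neuron = rep(1:13, 2))
  expect_equal(nrow(populationBursts(
    detectBursts(spikeTable(rep2$time, rep2$neuron, 100, 100)))), 0)

  # empty data -> empty catalog
  expect_equal(nrow(populationBursts(detectBursts(
    spikeTable(numeric(0), integer(0), 100, 100)))), 0)

  # consecutive active bins merge into one PB
  v2 <- rbind(volley(12, 30), volley(22, 40))
  ct2 <- detectBursts(spikeTable(v2$time, v2$neuron, 100, 100))
  expect_equal(nrow(populationBursts(ct2)), 1)
  expect_equal(populationBursts(ct2)$width, 20)
  expect_equal(populationBursts(ct2)$peak, 25)   # maximal-count bin centre
})

test_that("aborted bursts sit between baseline and the PB threshold", {
  # two PBs with a 15-neuron local maximum in between, quiet elsewhere
  sp <- rbind(volley(105, 40), volley(1005, 40), volley(505, 15),
              data.frame(time = seq(5, 1995, by = 40), neuron = 1L))
  sd <- spikeTable(sp$time, sp$neuron, 2000, 100)
  ct <- detectAbortedBursts(sd, detectBursts(sd))
  expect_equal(nrow(abortedBursts(ct)), 1)
  expect_equal(abortedBursts(ct)$peak, 505)
  expect_equal(abortedBursts(ct)$count, 15)
  # PB bins are never ABs; all AB counts below the PB threshold
  expect_true(all(abortedBursts(ct)$count <= 25))

  # flat asynchronous activity -> no ABs
  set.seed(2)
  flat <- data.frame(time = sort(runif(400, 0, 2000)),
                     neuron = sample(1:100, 400, TRUE))
  sdF <- spikeTable(flat$time, flat$neuron, 2000, 100)
  expect_equal(nrow(abortedBursts(
    detectAbortedBursts(sdF, detectBursts(sdF)))), 0)

  # an event too close to a PB peak is suppressed
  near <- rbind(volley(105, 40), volley(125, 15), volley(1005, 40))
  sdN <- spikeTable(near$time, near$neuron, 2000, 100)
  expect_equal(nrow(abortedBursts(
    detectAbortedBursts(sdN, detectBursts(sdN)))), 0)
})

test_that("build-up refinement locates peaks and interpolates crossings", {
  # 6/100 neurons within one 1 ms bin qualifies as the fine peak
  sp <- rbind(volley(500.2, 6), volley(505, 30))
  sd <- spikeTable(sp$time, sp$neuron, 1000, 100)
  ct <- detectBursts(sd)
  bu <- refineBuildup(sd, ct)
  expect_length(bu, 1)
  expect_equal(bu[[1]]$peak, 500.5, tolerance = 0.5)
  # build-up window is the 70 ms preceding the peak
  expect_true(all(bu[[1]]$firstSpikes$time >= bu[[1]]$peak - 70))
  expect_true(all(bu[[1]]$firstSpikes$time < bu[[1]]$peak))

  # staircase counts 3, 4, 6 with threshold 5: crossing between the
  # last two bins by linear interpolation
  counts <- c(3, 4, 6)
  sp2 <- do.call(rbind, lapply(seq_along(counts), function(k)
    volley(500 + k - 0.5, counts[k])))
  sp2 <- rbind(sp2, volley(505, 30))
  sd2 <- spikeTable(sp2$time, sp2$neuron, 1000, 100)
  bu2 <- refineBuildup(sd2, detectBursts(sd2), peakFrac = 0.05)
  # threshold 5 crossed halfway between bin centres 501.5 and 502.5
  expect_equal(bu2[[1]]$crossing, 502, tolerance = 1e-9)
})

test_that("the phase indicator tracks deviations from the control rate", {
  expect_equal(phaseIndicator(c(2, 4, 6), 2)$phi, c(0, 0, 0))
  expect_equal(phaseIndicator(c(2.5, 5.0), 2)$phi, c(0.25, 0.5))
  # faster-than-control train drifts negative
  fast <- phaseIndicator(cumsum(rep(1.5, 10)), 2)$phi
  expect_true(all(diff(fast) < 0))
  # scaling times and the control interval together leaves phi unchanged
  tg <- cumsum(runif(20, 1, 3))
  expect_equal(phaseIndicator(tg, 1.7)$phi, phaseIndicator(3 * tg, 5.1)$phi)
  expect_error(phaseIndicator(1:3, 0))
})

test_that("IGI epoch comparison and the rolling mean behave", {
  x <- rexp(200, 1)
  expect_equal(compareIGIEpochs(x, x)$p, 1)
  expect_false(compareIGIEpochs(x, x)$significant)

  set.seed(8)
  reject <- compareIGIEpochs(rexp(200, 1), rexp(200, 5))
  expect_true(reject$significant)

  und <- compareIGIEpochs(1, rexp(50, 1))
  expect_true(und$undefined)
  expect_true(is.na(und$p))

  # rolling 60 s window mean of a uniform 2 s train is 2 s
  tg <- seq(0, 300, by = 2)
  rm <- rollingMeanIGI(tg, 60)
  expect_equal(rm[1], 2)
})

test_that("participation similarity recovers a planted two-cluster split", {
  set.seed(13)
  n <- 100
  # two prototype participant sets (80% vs 40% of the population) with
  # 10% membership flip noise per PB
  protoA <- 1:80
  protoB <- 11:50
  flip <- function(proto) {
    f <- runif(n) < 0.1
    sort(union(setdiff(proto, which(f)), setdiff(which(f), proto)))
  }
  parts <- c(lapply(1:20, function(i) flip(protoA)),
             lapply(1:20, function(i) flip(protoB)))
  truth <- rep(1:2, each = 20)
  pb <- data.frame(peak = seq_along(parts) * 1000,
                   onset = seq_along(parts) * 1000 - 5,
                   offset = seq_along(parts) * 1000 + 5,
                   width = 10, nParticipants = lengths(parts),
                   peakCount = lengths(parts))
  ct <- new("BurstCatalog", pb = pb, participants = parts,
            ab = data.frame(peak = numeric(0), count = integer(0)),
            binMs = 10, frac = 0.25, nNeurons = 100L, duration = 41000)
  ps <- participationSimilarity(ct)
  acc <- max(mean(ps$cluster == truth), mean(ps$cluster == 3 - truth))
  expect_gt(acc, 0.9)
  expect_equal(ps$nHigh + ps$nLow, 40)
  # identical participant sets: similarity 1 throughout
  ct2 <- ct
  ct2@participants <- rep(list(1:50), 40)
  ps2 <- participationSimilarity(ct2)
  expect_true(all(abs(ps2$similarity - 1) < 1e-12))
})

test_that("catalog invariants hold on simulated data", {
  net <- buildNetwork(networkConfig(), seed = 4)
  sd <- simulateNetwork(net, 30000, seed = 4, burnIn = 10000)
  ct <- detectAbortedBursts(sd, detectBursts(sd))
  pb <- populationBursts(ct)
  expect_true(all(diff(pb$peak) > 0))
  expect_true(all(pb$width > 0))
  expect_equal(sum(igi(ct)) * 1000, max(pb$peak) - min(pb$peak))
  # AB and PB sets disjoint in time, AB counts below the PB threshold
  ab <- abortedBursts(ct)
  if (nrow(ab)) {
    expect_true(all(ab$count <= 0.25 * 100))
    expect_true(min(outer(ab$peak, pb$peak, function(a, b)
      abs(a - b))) >= 50)
  }
})
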