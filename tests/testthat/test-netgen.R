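test_that("Erdos-Renyi digraph hits the target degree statistics", {
  a <- buildERDigraph(100, 10, seed = 11)
  expect_true(all(diag(a) == 0))
  expect_true(all(a %in% c(0L, 1L)))
  # realized mean in-degree within 3 binomial SDs of the target
  sdDeg <- sqrt(100 * 99 * (10 / 99) * (1 - 10 / 99)) / 100
  expect_lt(abs(mean(rowSums(a)) - 10), 3 * sdDeg)
  expect_equal(mean(rowSums(a)), mean(colSums(a)))  # same edge total

  # n = 2, mean degree 1 -> p = 1 -> complete digraph without self-loops
  a2 <- buildERDigraph(2, 1, seed = 1)
  expect_equal(a2, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  expect_error(buildERDigraph(10, 10), "between 0 and n")
})

test_that("edge density converges to the binomial law over replicates", {
  dens <- vapply(1:300, function(s) {
    a <- buildERDigraph(100, 10, seed = s)
    sum(a) / (100 * 99)
  }, numeric(1))
  p <- 10 / 99
  mcSE <- sqrt(p * (1 - p) / (100 * 99 * 300))
  expect_lt(abs(mean(dens) - p), 4 * mcSE)
})

test_that("excitability sampling enforces the exact suprathreshold count", {
  x <- sampleExcitabilities(100, seed = 3)
  expect_equal(sum(x > 15), 10)
  expect_true(all(x >= 14.55 & x <= 15.45))  # half-width 0.45 around 15

  expect_equal(sum(sampleExcitabilities(100, fracSupra = 0, seed = 1) > 15), 0)
  expect_equal(sum(sampleExcitabilities(50, fracSupra = 1, seed = 1) > 15), 50)
  expect_error(sampleExcitabilities(10, width = 0), "positive")
})

test_that("anti-correlated assignment reverses ranks and preserves values", {
  out <- assignAnticorrelated(c(14.8, 15.0, 15.2), c(5, 20, 10))
  expect_equal(out, c(15.2, 14.8, 15.0))

  set.seed(9)
  ex <- runif(60, 14.55, 15.45)
  kt <- rpois(60, 20)
  out <- assignAnticorrelated(ex, kt)
  expect_equal(sort(out), sort(ex))                 # permutation
  expect_lt(cor(out, kt, method = "spearman"), -0.99)

  # ties broken by neuron index: equal degrees keep ascending order
  tied <- assignAnticorrelated(c(3, 1, 2), c(7, 7, 7))
  expect_equal(tied, c(1, 2, 3))
  expect_error(assignAnticorrelated(1:3, 1:4), "equal length")
})

test_that("synaptic parameters follow the class-wise laws", {
  a <- buildERDigraph(100, 10, seed = 21)
  cls <- rep(c("exc", "inh"), c(90, 10))
  par <- sampleSynapticParams(a, cls, seed = 21)
  e <- a == 1L
  postInh <- matrix(cls == "inh", 100, 100)
  preInh <- matrix(cls == "inh", 100, 100, byrow = TRUE)

  expect_true(all(par$TI[e] > 0))
  expect_true(all(par$TR[e] > 0))
  expect_true(all(par$U[e] > 0 & par$U[e] < 1))
  expect_true(all(par$G[e & preInh] < 0))
  expect_true(all(par$G[e & !preInh] > 0))
  # facilitation defined exactly on edges onto inhibitory neurons
  expect_true(all(!is.na(par$TF[e & postInh])))
  expect_true(all(is.na(par$TF[e & !postInh])))
  # class means within sampling error (SD = mean/2, ~100-900 draws/class)
  expect_lt(abs(mean(par$G[e & !postInh & !preInh]) - 45), 5)
  expect_lt(abs(mean(abs(par$G[e & !postInh & preInh])) - 135), 25)
  expect_lt(abs(mean(par$TR[e & !postInh]) - 800), 80)
  expect_lt(abs(mean(par$TR[e & postInh]) - 100), 25)
  expect_lt(abs(mean(par$U[e & postInh]) - 0.04), 0.02)
})

test_that("full builds satisfy the realization invariants", {
  net <- buildNetwork(networkConfig(), seed = 5)
  expect_true(validObject(net))
  expect_equal(nNeurons(net), 100L)
  expect_equal(sum(excitability(net) > 15), 10)
  expect_lt(cor(excitability(net), totalDegree(net), method = "spearman"),
            -0.99)
  expect_equal(inDegree(net) + outDegree(net), totalDegree(net))

  # uncorrelated control: |Spearman| consistent with 0 over seeds
  rhos <- vapply(1:20, function(s) {
    n <- buildNetwork(networkConfig(correlated = FALSE), seed = s)
    cor(excitability(n), totalDegree(n), method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
  expect_gt(max(rhos), -0.3)
})

test_that("degenerate configs are caught by validity checks", {
  expect_error(networkConfig(nTotal = 100, nExc = 80, nInh = 10),
               "must equal nTotal")
  expect_error(networkConfig(meanInDegree = 200), "strictly between")
  expect_error(networkConfig(excitabilityWidth = -1), "positive")
})
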