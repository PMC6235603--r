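## End-to-end pipeline: build a realization, simulate control, detect
## bursts, functional connectivity, SND over all neurons and SNS at a
## representative current, classify drivers and extract the clique.

#' Run the full analysis pipeline
#'
#' Chains every stage of the workflow on one network realization. All
#' randomness derives from one root seed; with \code{noiseDelta = 0} a
#' rerun with the same arguments is bit-identical. The stimulation stage
#' uses a single representative current by default (the protocol's full
#' sweep is available through [sweepSNS()]).
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed root integer seed.
#' @param windowS recording window per experiment (s).
#' @param burnIn settling period (ms).
#' @param baselineRuns initial conditions for the baseline variability.
#' @param iStim representative SNS current(s) (mV) applied to every
#'   neuron.
#' @param sndNeurons,snsNeurons neuron subsets (defaults: all).
#' @param verbose print stage progress.
#' @return A list with the realization, control \linkS4class{SpikeData}
#'   and \linkS4class{BurstCatalog}, the functional graph and degrees,
#'   the baseline, the SND/SNS outcomes, the \linkS4class{DriverReport}
#'   and the clique description (NULL when fewer than two hubs emerge).
#' @export
runPipeline <- function(config = networkConfig(), seed = 1, windowS = 84,
                        burnIn = 10000, baselineRuns = 20,
                        iStim = 15.90, sndNeurons = NULL,
                        snsNeurons = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("building network realization")
  net <- buildNetwork(config, seed = seed)
  n <- nNeurons(net)
  if (is.null(sndNeurons)) sndNeurons <- seq_len(n)
  if (is.null(snsNeurons)) snsNeurons <- seq_len(n)

  say("control simulation")
  ctrl <- simulateNetwork(net, windowS * 1000, seed = seed,
                          burnIn = burnIn)
  catalog <- detectBursts(ctrl)
  catalog <- detectAbortedBursts(ctrl, catalog)

  say("baseline variability (", baselineRuns, " initial conditions )")
  base <- baselineVariability(net, nRuns = baselineRuns,
                              windowS = windowS, seed = seed * 1000L,
                              burnIn = burnIn)

  say("functional connectivity")
  fc <- if (nrow(catalog@pb) >= 3) {
    surro <- makeSurrogate(ctrl, "degree")
    buildFunctionalGraph(surro, nNeurons = n)
  } else NULL

  say("single-neuron deletion over ", length(sndNeurons), " neurons")
  sndCounts <- rep(NA_real_, n)
  for (i in sndNeurons)
    sndCounts[i] <- sndExperiment(net, i, windowS = windowS,
                                  seed = seed, burnIn = burnIn)$nPB
  say("single-neuron stimulation over ", length(snsNeurons), " neurons")
  snsCounts <- rep(list(numeric(0)), n)
  for (i in snsNeurons)
    snsCounts[[i]] <- vapply(iStim, function(I)
      as.numeric(snsExperiment(net, i, I, windowS = windowS, seed = seed,
                               burnIn = burnIn)$nPB), numeric(1))

  report <- classifyDrivers(sndCounts, snsCounts, base,
                            neuronClass = neuronClass(net))
  hubs <- report@table$neuron[report@table$driverClass == "hub"]
  clique <- if (length(hubs) >= 2 && nrow(catalog@pb) >= 2) {
    say("clique extraction over ", length(hubs), " hubs")
    extractClique(ctrl, catalog, hubs)
  } else NULL
  report@clique <- if (is.null(clique)) list() else clique

  list(network = net, control = ctrl, catalog = catalog,
       functionalGraph = fc, baseline = base,
       sndCounts = sndCounts, snsCounts = snsCounts,
       report = report, clique = clique)
}
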