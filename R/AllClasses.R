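## Central S4 containers. Subscript convention is (postsynaptic, presynaptic)
## throughout: adjacency[i, j] == 1 means presynaptic neuron j projects onto
## postsynaptic neuron i.

#' NetworkConfig: parameters of a network realization
#'
#' Holds every parameter needed to draw one random network realization:
#' size and composition, the Erdos-Renyi mean in-degree, the flat
#' excitability distribution (centre, width, suprathreshold fraction) and
#' the class-wise Gaussian means of the synaptic parameters. Standard
#' deviations of all synaptic parameters equal \code{sdFactor} times the
#' mean (default one half).
#'
#' @slot nTotal total number of neurons N.
#' @slot nExc,nInh numbers of excitatory / inhibitory neurons.
#' @slot meanInDegree mean in-degree of the directed Erdos-Renyi graph.
#' @slot excitabilityCenter,excitabilityWidth centre and full width (mV) of
#'   the flat distribution of intrinsic excitabilities.
#' @slot fracSuprathreshold fraction of neurons forced above threshold.
#' @slot synMeans named numeric vector of synaptic parameter means: decay
#'   \code{TI} (ms, all synapses); recovery \code{TR_excPost},
#'   \code{TR_inhPost} (ms); facilitation \code{TF_inhPost} (ms, synapses
#'   onto inhibitory neurons only); baseline release \code{U_excPost},
#'   \code{U_inhPost}; coupling magnitudes \code{G_ee}, \code{G_ei},
#'   \code{G_ie}, \code{G_ii} (mV, first index postsynaptic).
#' @slot sdFactor SD of each synaptic parameter as a fraction of its mean.
#' @slot correlated logical; embed the excitability-connectivity
#'   anti-correlation (TRUE) or assign excitabilities at random (FALSE).
#'
#' @seealso [networkConfig()], [buildNetwork()]
#' @export
setClass("NetworkConfig",
  representation(
    nTotal = "integer", nExc = "integer", nInh = "integer",
    meanInDegree = "numeric",
    excitabilityCenter = "numeric", excitabilityWidth = "numeric",
    fracSuprathreshold = "numeric",
    synMeans = "numeric", sdFactor = "numeric",
    correlated = "logical"))

.defaultSynMeans <- c(
  TI = 3, TR_excPost = 800, TR_inhPost = 100, TF_inhPost = 1000,
  U_excPost = 0.5, U_inhPost = 0.04,
  G_ee = 45, G_ei = 135, G_ie = 180, G_ii = 180)

setValidity("NetworkConfig", function(object) {
  msg <- character(0)
  if (object@nExc + object@nInh != object@nTotal)
    msg <- c(msg, "nExc + nInh must equal nTotal")
  if (object@meanInDegree <= 0 || object@meanInDegree >= object@nTotal)
    msg <- c(msg, "meanInDegree must lie strictly between 0 and nTotal")
  if (object@excitabilityWidth <= 0)
    msg <- c(msg, "excitabilityWidth must be positive")
  if (object@fracSuprathreshold < 0 || object@fracSuprathreshold > 1)
    msg <- c(msg, "fracSuprathreshold must lie in [0, 1]")
  if (!all(names(.defaultSynMeans) %in% names(object@synMeans)))
    msg <- c(msg, paste("synMeans must contain:",
                        paste(names(.defaultSynMeans), collapse = ", ")))
  if (any(object@synMeans <= 0))
    msg <- c(msg, "all synaptic parameter means must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a network configuration
#'
#' Defaults are the developing-circuit study conditions: N = 100 neurons
#' (90 excitatory, 10 inhibitory), mean in-degree 10, flat excitability
#' distribution spanning 0.45 mV on either side of the 15 mV firing
#' threshold with exactly 10\% of neurons above threshold, and class-wise Gaussian
#' synaptic parameters with SD equal to half the mean.
#'
#' @param nTotal,nExc,nInh network size and composition.
#' @param meanInDegree target mean in-degree of the Erdos-Renyi digraph.
#' @param excitabilityCenter,excitabilityWidth centre and width (mV) of the
#'   flat excitability distribution.
#' @param fracSuprathreshold fraction of neurons forced above threshold.
#' @param synMeans named numeric vector of synaptic means (see
#'   \linkS4class{NetworkConfig}); partial vectors override the defaults.
#' @param sdFactor SD/mean ratio for all synaptic parameters.
#' @param correlated embed the excitability-connectivity anti-correlation?
#' @return A \linkS4class{NetworkConfig}.
#' @examples
#' cfg <- networkConfig()
#' cfg
#' @export
networkConfig <- function(nTotal = 100L, nExc = 90L, nInh = 10L,
                          meanInDegree = 10,
                          excitabilityCenter = 15, excitabilityWidth = 0.9,
                          fracSuprathreshold = 0.10,
                          synMeans = NULL, sdFactor = 0.5,
                          correlated = TRUE) {
  sm <- .defaultSynMeans
  if (!is.null(synMeans)) sm[names(synMeans)] <- synMeans
  new("NetworkConfig",
      nTotal = as.integer(nTotal), nExc = as.integer(nExc),
      nInh = as.integer(nInh), meanInDegree = meanInDegree,
      excitabilityCenter = excitabilityCenter,
      excitabilityWidth = excitabilityWidth,
      fracSuprathreshold = fracSuprathreshold,
      synMeans = sm, sdFactor = sdFactor, correlated = correlated)
}

#' NetworkRealization: one static network instance
#'
#' The full description of a single random network draw: the binary
#' directed adjacency matrix, per-neuron class and intrinsic excitability,
#' and the per-edge synaptic parameter matrices. Matrices are indexed
#' (postsynaptic, presynaptic); entries of the parameter matrices are
#' \code{NA} where no edge exists.
#'
#' @slot adjacency integer 0/1 matrix, zero diagonal.
#' @slot neuronClass character, "exc" or "inh" per neuron.
#' @slot excitability numeric, intrinsic excitability I^b (mV) per neuron.
#' @slot G coupling matrix (mV); negative iff the presynaptic neuron is
#'   inhibitory.
#' @slot TI,TR,TF,U synaptic decay, recovery, facilitation time constants
#'   (ms) and baseline release fraction. \code{TF} is \code{NA} on edges
#'   onto excitatory neurons (no facilitation there).
#' @slot config the \linkS4class{NetworkConfig} the realization was drawn
#'   from.
#' @seealso [buildNetwork()], [inDegree()], [excitability()]
#' @export
setClass("NetworkRealization",
  representation(
    adjacency = "matrix", neuronClass = "character",
    excitability = "numeric",
    G = "matrix", TI = "matrix", TR = "matrix", TF = "matrix",
    U = "matrix",
    config = "NetworkConfig"))

setValidity("NetworkRealization", function(object) {
  a <- object@adjacency
  n <- nrow(a)
  msg <- character(0)
  if (ncol(a) != n) msg <- c(msg, "adjacency must be square")
  if (any(diag(a) != 0)) msg <- c(msg, "adjacency must have a zero diagonal")
  if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be binary")
  if (length(object@neuronClass) != n ||
      !all(object@neuronClass %in% c("exc", "inh")))
    msg <- c(msg, "neuronClass must be 'exc'/'inh' of length n")
  if (length(object@excitability) != n)
    msg <- c(msg, "excitability must have length n")
  e <- a == 1L
  if (any(e)) {
    inh <- object@neuronClass == "inh"
    preInh <- matrix(inh, n, n, byrow = TRUE)
    if (any(is.na(object@G[e])) || any(object@G[e] == 0))
      msg <- c(msg, "G must be nonzero on every edge")
    else if (any(sign(object@G[e]) != ifelse(preInh[e], -1, 1)))
      msg <- c(msg, "sign(G) must be negative iff the presynaptic neuron is inhibitory")
    if (any(is.na(object@TI[e])) || any(object@TI[e] <= 0) ||
        any(is.na(object@TR[e])) || any(object@TR[e] <= 0))
      msg <- c(msg, "TI and TR must be positive on every edge")
    postInh <- matrix(inh, n, n)
    ef <- e & postInh
    if (any(ef) && (any(is.na(object@TF[ef])) || any(object@TF[ef] <= 0)))
      msg <- c(msg, "TF must be positive on edges onto inhibitory neurons")
    if (any(is.na(object@U[e])) || any(object@U[e] <= 0) ||
        any(object@U[e] >= 1))
      msg <- c(msg, "U must lie strictly in (0, 1) on every edge")
  }
  if (length(msg)) msg else TRUE
})

#' SpikeData: timestamped spikes from one simulation
#'
#' @slot spikes data.frame with columns \code{time} (ms, analysis clock,
#'   nondecreasing) and \code{neuron} (1-based id).
#' @slot duration length of the analysis window (ms).
#' @slot nNeurons number of neurons in the simulated network.
#' @slot traces optional sampled synaptic-state traces: a list with
#'   \code{time}, \code{xout}, \code{xin} (matrices, one column per traced
#'   neuron) and \code{neurons}.
#' @seealso [simulateNetwork()], [detectBursts()]
#' @export
setClass("SpikeData",
  representation(spikes = "data.frame", duration = "numeric",
                 nNeurons = "integer", traces = "list"))

setValidity("SpikeData", function(object) {
  s <- object@spikes
  msg <- character(0)
  if (!all(c("time", "neuron") %in% names(s)))
    msg <- c(msg, "spikes needs 'time' and 'neuron' columns")
  else {
    if (is.unsorted(s$time)) msg <- c(msg, "spike times must be nondecreasing")
    if (nrow(s) && (min(s$neuron) < 1 || max(s$neuron) > object@nNeurons))
      msg <- c(msg, "neuron ids out of range")
  }
  if (length(msg)) msg else TRUE
})

#' BurstCatalog: detected population bursts and aborted bursts
#'
#' @slot pb data.frame of population bursts: \code{peak}, \code{onset},
#'   \code{offset}, \code{width} (all ms), \code{nParticipants},
#'   \code{peakCount} (distinct neurons in the maximal bin).
#' @slot participants list of integer vectors, the distinct neurons firing
#'   within each PB.
#' @slot ab data.frame of aborted bursts: \code{peak} (ms), \code{count}.
#' @slot binMs,frac detection bin width (ms) and participation threshold.
#' @slot nNeurons,duration context of the detection.
#' @seealso [detectBursts()], [detectAbortedBursts()], [igi()]
#' @export
setClass("BurstCatalog",
  representation(pb = "data.frame", participants = "list",
                 ab = "data.frame", binMs = "numeric", frac = "numeric",
                 nNeurons = "integer", duration = "numeric"))

setValidity("BurstCatalog", function(object) {
  msg <- character(0)
  p <- object@pb
  if (nrow(p)) {
    if (is.unsorted(p$peak, strictly = TRUE))
      msg <- c(msg, "PB peaks must be strictly increasing")
    if (any(p$width <= 0)) msg <- c(msg, "PB widths must be positive")
    if (length(object@participants) != nrow(p))
      msg <- c(msg, "one participant set per PB required")
  }
  if (length(msg)) msg else TRUE
})

#' FunctionalGraph: directed functional connectivity
#'
#' @slot edges data.frame with \code{from}, \code{to}, \code{tau} (ms, lag
#'   of the correlogram peak) and \code{cpeak} (peak correlation value).
#' @slot nNeurons number of neurons considered.
#' @slot degreeOut,degreeIn functional out-/in-degree per neuron, as a
#'   percentage of the n - 1 potential partners.
#' @seealso [buildFunctionalGraph()], [functionalDegrees()]
#' @export
setClass("FunctionalGraph",
  representation(edges = "data.frame", nNeurons = "integer",
                 degreeOut = "numeric", degreeIn = "numeric"))

setValidity("FunctionalGraph", function(object) {
  e <- object@edges
  msg <- character(0)
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      msg <- c(msg, "an unordered pair may contribute at most one edge")
  }
  if (length(msg)) msg else TRUE
})

#' StimulusProgram: perturbations applied during a simulation
#'
#' @slot deletions integer ids of neurons removed from the network (they
#'   neither integrate nor transmit).
#' @slot dcSteps data.frame with \code{neuron}, \code{amp} (mV, added to
#'   I^b), \code{ton}, \code{toff} (ms on the analysis clock, i.e. from
#'   the end of burn-in).
#' @slot noiseDelta half-width (mV) of the uniform random-reset noise; 0
#'   gives the deterministic reset V_r.
#' @seealso [stimulusProgram()], [simulateNetwork()]
#' @export
setClass("StimulusProgram",
  representation(deletions = "integer", dcSteps = "data.frame",
                 noiseDelta = "numeric"))

setValidity("StimulusProgram", function(object) {
  msg <- character(0)
  d <- object@dcSteps
  if (nrow(d) && any(d$ton >= d$toff))
    msg <- c(msg, "dcSteps must satisfy ton < toff")
  if (object@noiseDelta < 0) msg <- c(msg, "noiseDelta must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a stimulus program
#'
#' @param deletions neuron ids to delete (SND).
#' @param dcSteps data.frame(neuron, amp, ton, toff): DC current steps
#'   (SNS). During [ton, toff) the neuron's effective drive is set to
#'   \code{amp} -- the stimulation current I^stim substitutes the intrinsic
#'   excitability I^b, so stimulating at I^stim equal to I^b reproduces the
#'   control drive. Steps for the same neuron must not overlap.
#' @param noiseDelta random-reset noise half-width (mV).
#' @return A \linkS4class{StimulusProgram}.
#' @export
stimulusProgram <- function(deletions = integer(0),
                            dcSteps = data.frame(neuron = integer(0),
                                                 amp = numeric(0),
                                                 ton = numeric(0),
                                                 toff = numeric(0)),
                            noiseDelta = 0) {
  new("StimulusProgram", deletions = as.integer(deletions),
      dcSteps = dcSteps, noiseDelta = noiseDelta)
}

#' DriverReport: outcome of the SND/SNS classification
#'
#' @slot table per-neuron data.frame: \code{neuron}, \code{class}
#'   (exc/inh), \code{sndCount}, \code{sndChange} (relative), SNS extremes
#'   \code{snsMaxIncrease}, \code{snsMaxDecrease} (relative changes), and
#'   \code{driverClass} in \code{hub}, \code{LC1}, \code{LC2}, \code{none}.
#' @slot controlMean,controlSd PB-count statistics in control conditions.
#' @slot clique list describing the functional clique (see
#'   [extractClique()]), empty until filled by the pipeline.
#' @export
setClass("DriverReport",
  representation(table = "data.frame", controlMean = "numeric",
                 controlSd = "numeric", clique = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", object@nTotal, "neurons (",
      object@nExc, "exc /", object@nInh, "inh ), mean in-degree",
      object@meanInDegree, "\n")
  cat("  excitability: flat", object@excitabilityWidth, "mV around",
      object@excitabilityCenter, "mV,",
      sprintf("%.0f%%", 100 * object@fracSuprathreshold), "suprathreshold\n")
  cat("  correlated excitability-connectivity:", object@correlated, "\n")
})

setMethod("show", "NetworkRealization", function(object) {
  n <- nrow(object@adjacency)
  cat("NetworkRealization:", n, "neurons,",
      sum(object@adjacency), "edges (mean in-degree",
      sprintf("%.2f", mean(rowSums(object@adjacency))), ")\n")
  cat("  classes:", sum(object@neuronClass == "exc"), "exc /",
      sum(object@neuronClass == "inh"), "inh;",
      sum(object@excitability > 15), "neurons above 15 mV\n")
})

setMethod("show", "SpikeData", function(object) {
  cat("SpikeData:", nrow(object@spikes), "spikes from",
      object@nNeurons, "neurons over",
      sprintf("%.1f", object@duration / 1000), "s\n")
  if (length(object@traces))
    cat("  with synaptic-resource traces for",
        length(object@traces$neurons), "neurons\n")
})

setMethod("show", "BurstCatalog", function(object) {
  cat("BurstCatalog:", nrow(object@pb), "population bursts,",
      nrow(object@ab), "aborted bursts\n")
  if (nrow(object@pb) > 1) {
    ig <- diff(object@pb$peak) / 1000
    cat(sprintf("  mean IGI %.2f s, mean width %.1f ms\n",
                mean(ig), mean(object@pb$width)))
  }
})

setMethod("show", "FunctionalGraph", function(object) {
  cat("FunctionalGraph:", nrow(object@edges), "directed edges among",
      object@nNeurons, "neurons\n")
})

setMethod("show", "DriverReport", function(object) {
  tab <- table(factor(object@table$driverClass,
                      levels = c("hub", "LC1", "LC2", "none")))
  cat("DriverReport:", tab[["hub"]], "hubs,", tab[["LC1"]], "LC1,",
      tab[["LC2"]], "LC2 drivers;",
      sprintf("control %.1f +/- %.1f PBs / window\n",
              object@controlMean, object@controlSd))
})
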