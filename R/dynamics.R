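## R-level interface to the event-driven LIF-TUM simulator and the
## fixed-step reference integrator.

# model constants: threshold, reset and membrane time constant
.VTH <- 15
.VR <- 13.5
.TAUM <- 30

#' Natural firing period of an isolated LIF neuron
#'
#' The closed-form interspike interval of a leaky integrate-and-fire
#' neuron with constant drive I:
#' \deqn{T = \tau_m \log[(I - V_r)/(I - V_{th})]}
#' for I above threshold, infinity otherwise.
#'
#' @param I drive (mV); vectorized.
#' @param tauM membrane time constant (ms).
#' @param vr,vth reset and threshold potentials (mV).
#' @return Period in ms (\code{Inf} for subthreshold drives).
#' @examples
#' naturalPeriod(15.32)   # 52.15 ms
#' @export
naturalPeriod <- function(I, tauM = .TAUM, vr = .VR, vth = .VTH) {
  ifelse(I > vth, tauM * log((I - vr) / (I - vth)), Inf)
}

# flatten the parameter matrices of a realization into edge vectors for
# the compiled cores; column-major order of which() keeps it reproducible
.edgeList <- function(net) {
  a <- net@adjacency
  n <- nrow(a)
  idx <- which(a == 1L)
  list(post = as.integer(((idx - 1L) %% n) + 1L),
       pre = as.integer(((idx - 1L) %/% n) + 1L),
       G = net@G[idx], TI = net@TI[idx], TR = net@TR[idx],
       TF = net@TF[idx], U = net@U[idx])
}

#' Simulate a network with the exact event-driven scheme
#'
#' Integrates the LIF-TUM network from spike to spike using closed-form
#' interspike solutions and bracketed root-finding for the threshold
#' crossings (tolerance 1e-10 ms), so the trajectory is exact up to root
#' tolerance. Initial conditions: membrane potentials uniform in
#' [V_r, V_th), synapses fully recovered (X = 1, Y = Z = 0, u = U). A
#' burn-in period is simulated first and discarded; reported spike times
#' start at 0 at the end of burn-in.
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param duration analysis window (ms).
#' @param program optional \linkS4class{StimulusProgram} (deletions, DC
#'   steps on the analysis clock, random-reset noise).
#' @param seed optional integer seed (initial conditions and reset noise).
#' @param burnIn discarded settling period (ms).
#' @param traceDt sampling cadence (ms) for synaptic-resource traces; 0
#'   disables tracing.
#' @param traceNeurons neurons whose mean efferent/afferent recovered
#'   fraction X^OUT / X^IN is sampled.
#' @param v0 optional explicit initial membrane potentials (overrides the
#'   random draw; mainly for oracle comparisons).
#' @return A \linkS4class{SpikeData}.
#' @examples
#' net <- makeFixture("pair_entrain")
#' sd <- simulateNetwork(net, 500, burnIn = 0, seed = 1)
#' head(spikes(sd))
#' @export
simulateNetwork <- function(net, duration, program = NULL, seed = NULL,
                            burnIn = 10000, traceDt = 0,
                            traceNeurons = integer(0), v0 = NULL) {
  stopifnot(duration > 0)
  if (is.null(program)) program <- stimulusProgram()
  validObject(program)
  n <- nNeurons(net)
  if (length(program@deletions) &&
      (min(program@deletions) < 1 || max(program@deletions) > n))
    stop("deletion ids out of range")
  if (nrow(program@dcSteps) &&
      (min(program@dcSteps$neuron) < 1 || max(program@dcSteps$neuron) > n))
    stop("dcSteps neuron ids out of range")
  el <- .edgeList(net)
  res <- withSeed(seed, {
    if (is.null(v0)) v0 <- runif(n, .VR, .VTH)
    .edSimulate(el$post, el$pre, el$G, el$TI, el$TR, el$TF, el$U,
                net@excitability, net@neuronClass == "inh",
                duration, burnIn, .TAUM, .VTH, .VR,
                program@noiseDelta, program@deletions,
                as.integer(program@dcSteps$neuron), program@dcSteps$amp,
                program@dcSteps$ton, program@dcSteps$toff,
                traceDt, as.integer(traceNeurons), v0,
                maxSpikes = 500 * n * (duration + burnIn) / 1000 + 1e5)
  })
  traces <- if (is.null(res$traces)) list() else res$traces
  new("SpikeData",
      spikes = data.frame(time = res$time, neuron = res$neuron),
      duration = duration, nNeurons = as.integer(n), traces = traces)
}

#' Brute-force reference simulation (fixed-step RK4)
#'
#' Independent oracle for [simulateNetwork()]: classical 4th-order
#' Runge-Kutta on a uniform grid with threshold crossings located by
#' linear interpolation inside a step. Intended for small motifs and
#' short horizons only (cost grows as duration/dt).
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param duration horizon (ms); no burn-in.
#' @param dt step (ms).
#' @param v0 initial membrane potentials (defaults to V_r for all).
#' @return A \linkS4class{SpikeData}.
#' @export
referenceSimulate <- function(net, duration, dt = 1e-3, v0 = NULL) {
  n <- nNeurons(net)
  if (is.null(v0)) v0 <- rep(.VR, n)
  el <- .edgeList(net)
  res <- .rk4Simulate(el$post, el$pre, el$G, el$TI, el$TR, el$TF, el$U,
                      net@excitability, duration, dt, .TAUM, .VTH, .VR, v0)
  new("SpikeData",
      spikes = data.frame(time = res$time, neuron = res$neuron),
      duration = duration, nNeurons = as.integer(n), traces = list())
}

#' Firing rates over the analysis window
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @return Numeric vector, spikes per second for each neuron.
#' @export
firingRates <- function(spikeData) {
  counts <- tabulate(spikeData@spikes$neuron, spikeData@nNeurons)
  counts / (spikeData@duration / 1000)
}
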