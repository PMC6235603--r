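# shared helpers: tiny hand-built realizations and synthetic spike tables

emptyEdges <- function() {
  data.frame(post = integer(0), pre = integer(0), G = numeric(0),
             TI = numeric(0), TR = numeric(0), TF = numeric(0),
             U = numeric(0))
}

# isolated neurons with given drives (no synapses)
isolatedNet <- function(ib) {
  burstclique:::.makeRealization(rep("exc", length(ib)), ib, emptyEdges())
}

# SpikeData from explicit times/ids
spikeTable <- function(time, neuron, duration, n) {
  o <- order(time, neuron)
  new("SpikeData", spikes = data.frame(time = time[o], neuron = neuron[o]),
      duration = duration, nNeurons = as.integer(n), traces = list())
}

# synchronous volley: m distinct neurons all firing at time t
volley <- function(t, m, start = 1L) {
  data.frame(time = rep(t, m), neuron = seq(start, start + m - 1L))
}

# independent closed-form single-synapse evolution used as the
# conservation oracle: X integrated from its own ODE (X' = Z/TR), not
# from 1 - Y - Z
synapseFreeOracle <- function(x, y, z, dt, TI, TR) {
  a <- 1 / TR - 1 / TI
  eI <- exp(-dt / TI)
  eR <- exp(-dt / TR)
  yNew <- y * eI
  zNew <- z * eR + (y / TI) * (eI - eR) / a
  # integral of Z(s)/TR over [0, dt]
  intZ <- z * TR * (1 - eR) +
    (y / TI) / a * (TI * (1 - eI) - TR * (1 - eR))
  xNew <- x + intZ / TR
  c(x = unname(xNew), y = unname(yNew), z = unname(zNew))
}
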