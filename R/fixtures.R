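## Deterministic micro-networks that isolate single mechanisms of the
## full model: entrainment of an inhibitory cell, an inhibitory gate, a
## six-neuron clique chain, and a silent low-excitability probe wired
## onto the gate. Every module is testable on these without simulating
## the full 100-neuron model.

# assemble a NetworkRealization from explicit neuron and edge tables
.makeRealization <- function(class, ib, edges, config = networkConfig(
    nTotal = length(class), nExc = sum(class == "exc"),
    nInh = sum(class == "inh"),
    meanInDegree = max(1e-6, nrow(edges) / max(1, length(class))))) {
  n <- length(class)
  a <- matrix(0L, n, n)
  G <- TI <- TR <- TF <- U <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$post[r]; j <- edges$pre[r]
    a[i, j] <- 1L
    G[i, j] <- edges$G[r]
    TI[i, j] <- edges$TI[r]
    TR[i, j] <- edges$TR[r]
    TF[i, j] <- edges$TF[r]
    U[i, j] <- edges$U[r]
  }
  new("NetworkRealization", adjacency = a, neuronClass = class,
      excitability = ib, G = G, TI = TI, TR = TR, TF = TF, U = U,
      config = config)
}

.edgeRow <- function(post, pre, G, TI = 3, TR = 800, TF = NA_real_,
                     U = 0.5) {
  data.frame(post = post, pre = pre, G = G, TI = TI, TR = TR, TF = TF,
             U = U)
}

#' Deterministic fixture networks
#'
#' Named micro-networks mirroring the motifs at work in the full model:
#' \describe{
#'   \item{pair_entrain}{a suprathreshold excitatory cell driving a
#'     subthreshold inhibitory cell through a facilitating synapse; the
#'     inhibitory cell fires phase-locked to its driver.}
#'   \item{gate}{excitatory pacemaker -> inhibitory gate -> excitatory
#'     target: the gate's firing slows the target below its natural
#'     rate.}
#'   \item{chain6}{a six-neuron excitatory chain led by a pacemaker with
#'     the clique leader's excitability (15.32 mV, natural period
#'     52.15 ms); each cycle the whole chain fires in a fixed order,
#'     giving a single dominant route.}
#'   \item{lc_probe}{chain6 plus an inhibitory gate onto the second chain
#'     neuron and a silent, low-excitability probe neuron exciting the
#'     gate: deleting the probe changes nothing, stimulating it
#'     suppresses the collective events (an LC-driver motif).}
#' }
#'
#' @param name fixture name.
#' @return A \linkS4class{NetworkRealization}.
#' @examples
#' net <- makeFixture("chain6")
#' nNeurons(net)
#' @export
makeFixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("fixture name must be a nonempty string")
  switch(name,
    pair_entrain = .makeRealization(
      class = c("exc", "inh"),
      ib = c(15.32, 14.90),
      edges = .edgeRow(2, 1, G = 30, TR = 100, TF = 1000, U = 0.04)),
    gate = .makeRealization(
      class = c("exc", "inh", "exc"),
      ib = c(15.32, 14.90, 15.10),
      edges = rbind(
        .edgeRow(2, 1, G = 30, TR = 100, TF = 1000, U = 0.04),
        .edgeRow(3, 2, G = -300, TR = 800, U = 0.5))),
    chain6 = .chainSix(),
    lc_probe = {
      ch <- .chainSix()
      cls <- c(ch@neuronClass, "inh", "exc")
      ib <- c(ch@excitability, 14.0, 14.5)
      edges <- rbind(
        .chainEdges(),
        .edgeRow(2, 7, G = -500, TR = 800, U = 0.5),   # gate inhibits chain
        .edgeRow(7, 8, G = 180, TR = 100, TF = 1000, U = 0.04)) # probe
      .makeRealization(cls, ib, edges)
    },
    stop("unknown fixture: ", name))
}

.chainEdges <- function() {
  do.call(rbind, lapply(1:5, function(k)
    .edgeRow(k + 1, k, G = 150, TR = 800, U = 0.5)))
}

.chainSix <- function() {
  .makeRealization(
    class = rep("exc", 6),
    ib = c(15.32, rep(14.95, 5)),
    edges = .chainEdges())
}
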