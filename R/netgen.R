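## Construction of random network realizations: directed Erdos-Renyi
## skeleton, flat excitability distribution with an exact suprathreshold
## count, the excitability-connectivity anti-correlation, and class-wise
## Gaussian synaptic parameters.

#' Build a directed Erdos-Renyi adjacency matrix
#'
#' Each ordered pair (i, j), i != j, carries an edge j -> i independently
#' with probability \code{meanInDegree / (n - 1)}, giving the target mean
#' in-degree (and, by symmetry of the construction, the same mean
#' out-degree). No self-loops.
#'
#' @param n number of neurons.
#' @param meanInDegree target mean in-degree, 0 < meanInDegree < n.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return An n x n integer 0/1 matrix, rows postsynaptic.
#' @examples
#' a <- buildERDigraph(100, 10, seed = 1)
#' mean(rowSums(a))   # close to 10
#' @export
buildERDigraph <- function(n, meanInDegree, seed = NULL) {
  if (meanInDegree <= 0 || meanInDegree >= n)
    stop("meanInDegree must lie strictly between 0 and n")
  withSeed(seed, {
    p <- meanInDegree / (n - 1)
    a <- matrix(rbinom(n * n, 1L, p), n, n)
    diag(a) <- 0L
    storage.mode(a) <- "integer"
    a
  })
}

#' Sample intrinsic excitabilities with an exact suprathreshold count
#'
#' Draws n values from the flat distribution of the given width centred on
#' \code{center}, then enforces that exactly \code{round(fracSupra * n)}
#' values lie strictly above the firing threshold: the top-ranked values of
#' the initial draw are redrawn uniformly in (vth, center + width/2] and
#' the remainder in [center - width/2, vth].
#'
#' @param n number of neurons.
#' @param center,width centre and full width (mV) of the flat distribution.
#' @param fracSupra fraction of neurons forced above threshold.
#' @param vth firing threshold (mV); must lie inside the support.
#' @param seed optional integer seed.
#' @return Numeric vector of intrinsic excitabilities I^b (mV).
#' @export
sampleExcitabilities <- function(n, center = 15, width = 0.9,
                                 fracSupra = 0.10, vth = 15, seed = NULL) {
  if (width <= 0) stop("width must be positive")
  if (fracSupra < 0 || fracSupra > 1) stop("fracSupra must lie in [0, 1]")
  lo <- center - width / 2
  hi <- center + width / 2
  if (vth <= lo || vth >= hi)
    stop("vth must lie strictly inside the excitability support")
  withSeed(seed, {
    x <- runif(n, lo, hi)
    k <- round(fracSupra * n)
    ord <- order(x, decreasing = TRUE)
    out <- numeric(n)
    if (k > 0) out[ord[seq_len(k)]] <- vth + runif(k) * (hi - vth)
    if (k < n) out[ord[seq(k + 1, n)]] <- lo + runif(n - k) * (vth - lo)
    out
  })
}

#' Assign excitabilities anti-correlated with total degree
#'
#' The neuron with the r-th largest total structural degree receives the
#' r-th smallest excitability, giving a Spearman rank correlation of -1 up
#' to ties. Ties in the degrees are broken by neuron index (stable sort).
#'
#' @param excitabilities values to assign (any order).
#' @param totalDegrees per-neuron total structural degree K^T.
#' @return Permutation of \code{excitabilities} aligned with the neurons.
#' @examples
#' assignAnticorrelated(c(14.8, 15.0, 15.2), c(5, 20, 10))
#' @export
assignAnticorrelated <- function(excitabilities, totalDegrees) {
  if (length(excitabilities) != length(totalDegrees))
    stop("inputs must have equal length")
  ordDeg <- order(-totalDegrees, seq_along(totalDegrees))
  out <- numeric(length(excitabilities))
  out[ordDeg] <- sort(excitabilities)
  out
}

# per-edge Gaussian draws with positivity truncation (redraw) and U clipped
# to (0, 1); class-wise means keyed on the POSTsynaptic class except G,
# keyed on both
.sampleTruncGauss <- function(nDraw, mean, sd) {
  x <- rnorm(nDraw, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Sample per-edge synaptic parameters
#'
#' Fills the synaptic parameter matrices of a realization: for every edge,
#' the decay time TI, recovery time TR, facilitation time TF (edges onto
#' inhibitory neurons only), baseline release U and coupling magnitude |G|
#' are drawn from the class-appropriate Gaussian with SD equal to
#' \code{sdFactor} times the mean. Nonpositive draws of time constants and
#' couplings are redrawn; U is clipped to [0.001, 0.999]. G is negated on
#' edges whose presynaptic neuron is inhibitory.
#'
#' @param adjacency 0/1 matrix (post, pre).
#' @param neuronClass "exc"/"inh" per neuron.
#' @param synMeans named vector of means (see \linkS4class{NetworkConfig}).
#' @param sdFactor SD/mean ratio.
#' @param seed optional integer seed.
#' @return List of matrices \code{G}, \code{TI}, \code{TR}, \code{TF},
#'   \code{U} with \code{NA} off the edges.
#' @export
sampleSynapticParams <- function(adjacency, neuronClass,
                                 synMeans = NULL, sdFactor = 0.5,
                                 seed = NULL) {
  sm <- .defaultSynMeans
  if (!is.null(synMeans)) sm[names(synMeans)] <- synMeans
  n <- nrow(adjacency)
  idx <- which(adjacency == 1L)
  post <- ((idx - 1L) %% n) + 1L
  pre <- ((idx - 1L) %/% n) + 1L
  postInh <- neuronClass[post] == "inh"
  preInh <- neuronClass[pre] == "inh"
  blank <- matrix(NA_real_, n, n)
  G <- TI <- TR <- TF <- U <- blank
  withSeed(seed, {
    TI[idx] <- .sampleTruncGauss(length(idx), sm["TI"], sdFactor * sm["TI"])
    trMean <- ifelse(postInh, sm["TR_inhPost"], sm["TR_excPost"])
    TR[idx] <- vapply(trMean, function(m)
      .sampleTruncGauss(1L, m, sdFactor * m), numeric(1))
    if (any(postInh)) {
      TF[idx[postInh]] <- .sampleTruncGauss(sum(postInh),
        sm["TF_inhPost"], sdFactor * sm["TF_inhPost"])
    }
    uMean <- ifelse(postInh, sm["U_inhPost"], sm["U_excPost"])
    uDraw <- vapply(uMean, function(m)
      .sampleTruncGauss(1L, m, sdFactor * m), numeric(1))
    U[idx] <- pmin(pmax(uDraw, 0.001), 0.999)
    gMean <- ifelse(postInh,
                    ifelse(preInh, sm["G_ii"], sm["G_ie"]),
                    ifelse(preInh, sm["G_ei"], sm["G_ee"]))
    gMag <- vapply(gMean, function(m)
      .sampleTruncGauss(1L, m, sdFactor * m), numeric(1))
    G[idx] <- ifelse(preInh, -gMag, gMag)
  })
  list(G = G, TI = TI, TR = TR, TF = TF, U = U)
}

#' Build a full network realization
#'
#' Draws one random realization under a \linkS4class{NetworkConfig}:
#' Erdos-Renyi adjacency, neuron classes (the first \code{nExc} indices
#' excitatory -- labels are exchangeable under the symmetric edge model),
#' intrinsic excitabilities with the exact suprathreshold count, the
#' excitability-connectivity anti-correlation when
#' \code{config@correlated}, and class-wise synaptic parameters.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed optional integer seed controlling the whole draw.
#' @return A \linkS4class{NetworkRealization}.
#' @examples
#' net <- buildNetwork(networkConfig(), seed = 7)
#' cor(excitability(net), totalDegree(net), method = "spearman")
#' @export
buildNetwork <- function(config = networkConfig(), seed = NULL) {
  validObject(config)
  withSeed(seed, {
    n <- config@nTotal
    a <- buildERDigraph(n, config@meanInDegree)
    cls <- rep(c("exc", "inh"), c(config@nExc, config@nInh))
    ex <- sampleExcitabilities(n, config@excitabilityCenter,
                               config@excitabilityWidth,
                               config@fracSuprathreshold,
                               vth = 15)
    if (config@correlated) {
      kt <- rowSums(a) + colSums(a)
      ex <- assignAnticorrelated(ex, kt)
    }
    par <- sampleSynapticParams(a, cls, config@synMeans, config@sdFactor)
    net <- new("NetworkRealization", adjacency = a, neuronClass = cls,
               excitability = ex, G = par$G, TI = par$TI, TR = par$TR,
               TF = par$TF, U = par$U, config = config)
    validObject(net)
    net
  })
}
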