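## Directed functional connectivity from spike timestamps: surrogate
## constructions, pairwise cross-correlograms of 1-ms binary trains, and
## the two-null significance policy (flat / zero-centred) that assigns
## directed edges.

#' Build per-neuron timestamp surrogates
#'
#' Filters spike trains so that a population burst contributes a single
#' event per neuron, following one of three constructions:
#' \describe{
#'   \item{degree}{sequential inter-spike-interval filter: a spike is kept
#'     only if it falls at least \code{minIsiMs} after the previously KEPT
#'     spike -- effectively the first spike per PB. Used for the
#'     functional degrees.}
#'   \item{buildup}{first spike of each neuron within the \code{windowMs}
#'     preceding each PB peak (requires a catalog).}
#'   \item{interburst}{all spikes emitted outside the PB windows (requires
#'     a catalog).}
#' }
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param mode one of \code{"degree"}, \code{"buildup"},
#'   \code{"interburst"}.
#' @param catalog \linkS4class{BurstCatalog}; required for
#'   \code{buildup}/\code{interburst}.
#' @param minIsiMs ISI threshold of the degree filter (ms).
#' @param windowMs build-up window (ms).
#' @return List (length nNeurons) of numeric timestamp vectors.
#' @examples
#' sd <- new("SpikeData",
#'           spikes = data.frame(time = c(0, 10, 20, 100), neuron = 1L),
#'           duration = 200, nNeurons = 1L, traces = list())
#' makeSurrogate(sd, "degree")[[1]]   # 0, 100
#' @export
makeSurrogate <- function(spikeData, mode = c("degree", "buildup",
                                              "interburst"),
                          catalog = NULL, minIsiMs = 35, windowMs = 70) {
  mode <- match.arg(mode)
  n <- spikeData@nNeurons
  s <- spikeData@spikes
  if (mode %in% c("buildup", "interburst") && is.null(catalog))
    stop("mode '", mode, "' requires a BurstCatalog")
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- numeric(0)
  if (mode == "degree") {
    for (i in seq_len(n)) {
      tt <- s$time[s$neuron == i]
      if (!length(tt)) next
      kept <- tt[1L]
      last <- tt[1L]
      for (t1 in tt[-1L]) {
        if (t1 - last >= minIsiMs) { kept <- c(kept, t1); last <- t1 }
      }
      out[[i]] <- kept
    }
  } else if (mode == "buildup") {
    for (r in seq_len(nrow(catalog@pb))) {
      pk <- catalog@pb$peak[r]
      w <- s$time >= pk - windowMs & s$time < pk
      if (!any(w)) next
      first <- tapply(s$time[w], s$neuron[w], min)
      ids <- as.integer(names(first))
      for (q in seq_along(ids))
        out[[ids[q]]] <- c(out[[ids[q]]], as.numeric(first[q]))
    }
    out <- lapply(out, sort)
  } else {
    inPB <- rep(FALSE, nrow(s))
    for (r in seq_len(nrow(catalog@pb)))
      inPB <- inPB | (s$time >= catalog@pb$onset[r] &
                      s$time < catalog@pb$offset[r])
    for (i in seq_len(n)) out[[i]] <- s$time[!inPB & s$neuron == i]
  }
  out
}

#' Cross-correlogram of two event trains
#'
#' Correlation of the 1-ms binary time series of neurons a and b:
#' \deqn{C_{ab}(\tau) = \sum_t a_{t+\tau} b_t / \min(\sum a, \sum b)}
#' computed for integer lags in [-maxLag, maxLag]. Values lie in [0, 1]
#' and satisfy \eqn{C_{ab}(\tau) = C_{ba}(-\tau)}. A positive peak lag
#' means a fires AFTER b (direction b to a).
#'
#' @param a,b timestamp vectors (ms).
#' @param maxLag maximal lag (ms).
#' @param binMs bin width (ms).
#' @return list(tau, C, lagSample): \code{lagSample} holds the continuous
#'   pairwise differences (a minus b) within the lag range, used by the
#'   significance tests.
#' @examples
#' cc <- crossCorrelation(7, 5, maxLag = 5)
#' cc$C[cc$tau == 2]   # 1
#' @export
crossCorrelation <- function(a, b, maxLag = 500, binMs = 1) {
  stopifnot(length(a) > 0, length(b) > 0)
  L <- as.integer(maxLag / binMs)
  d <- as.vector(outer(a, b, "-"))
  d <- d[abs(d) <= maxLag]
  dBin <- as.integer(round(d / binMs))
  counts <- tabulate(dBin + L + 1L, 2L * L + 1L)
  list(tau = (-L:L) * binMs,
       C = counts / min(length(a), length(b)),
       lagSample = d)
}

#' Assign a directed functional edge from a correlogram
#'
#' Tests the lag sample (pairwise spike-time differences) against the two
#' null models that forbid a directed connection: a flat correlogram
#' (uncorrelated neurons; Kolmogorov-Smirnov test against the uniform law
#' on [-maxLag, maxLag]) and a zero-centred correlogram (synchronous
#' firing; Student's t test of mean lag = 0). A directed edge is assigned
#' only when BOTH nulls are rejected at level \code{alpha} and the
#' correlogram peak is at a nonzero lag; its direction follows the sign
#' of the peak lag (positive: b to a). Peak ties are broken toward the
#' smaller |lag|; a tie across signs yields no edge.
#'
#' @param cc result of [crossCorrelation()].
#' @param alpha significance level for both tests.
#' @param maxLag lag range used to build \code{cc}.
#' @return list(edge, direction, tau, cpeak, pFlat, pZero): direction is
#'   \code{"b->a"}, \code{"a->b"} or \code{NA}.
#' @export
assignEdge <- function(cc, alpha = 0.05, maxLag = 500) {
  none <- list(edge = FALSE, direction = NA_character_, tau = NA_real_,
               cpeak = NA_real_, pFlat = NA_real_, pZero = NA_real_)
  lags <- cc$lagSample
  if (length(lags) < 3) return(none)
  pFlat <- suppressWarnings(
    ks.test(lags, "punif", -maxLag, maxLag)$p.value)
  pZero <- if (sd(lags) == 0) {
    if (lags[1] == 0) 1 else 0   # degenerate: all mass at one lag
  } else t.test(lags, mu = 0)$p.value
  ord <- order(-cc$C, abs(cc$tau))
  tauMax <- cc$tau[ord[1L]]
  cpeak <- cc$C[ord[1L]]
  # tie across signs at the same |tau| and height -> undirected, no edge
  tied <- cc$C == cpeak & abs(cc$tau) == abs(tauMax)
  if (sum(tied) > 1 && length(unique(sign(cc$tau[tied]))) > 1)
    return(modifyList(none, list(pFlat = pFlat, pZero = pZero)))
  res <- list(edge = FALSE, direction = NA_character_, tau = tauMax,
              cpeak = cpeak, pFlat = pFlat, pZero = pZero)
  if (tauMax != 0 && pFlat < alpha && pZero < alpha) {
    res$edge <- TRUE
    res$direction <- if (tauMax > 0) "b->a" else "a->b"
  }
  res
}

#' Build the directed functional graph
#'
#' Evaluates every unordered pair of neurons with events, assigns edges
#' with [assignEdge()] and computes functional degrees as percentages of
#' the n - 1 potential partners. Neurons without events contribute no
#' edges (degree 0).
#'
#' @param surrogate list of per-neuron timestamps (see [makeSurrogate()]).
#' @param nNeurons number of neurons.
#' @param maxLag,alpha see [assignEdge()].
#' @param minEvents minimal number of events for a neuron to be tested.
#' @return A \linkS4class{FunctionalGraph}.
#' @export
buildFunctionalGraph <- function(surrogate, nNeurons = length(surrogate),
                                 maxLag = 500, alpha = 0.05,
                                 minEvents = 3) {
  edges <- list()
  for (i in seq_len(nNeurons - 1L)) {
    a <- surrogate[[i]]
    if (length(a) < minEvents) next
    for (j in seq(i + 1L, nNeurons)) {
      b <- surrogate[[j]]
      if (length(b) < minEvents) next
      cc <- crossCorrelation(a, b, maxLag = maxLag)
      res <- assignEdge(cc, alpha = alpha, maxLag = maxLag)
      if (!res$edge) next
      # a = i, b = j: tau > 0 means i fires after j => j -> i
      edges[[length(edges) + 1L]] <-
        if (res$direction == "b->a")
          data.frame(from = j, to = i, tau = res$tau, cpeak = res$cpeak)
        else
          data.frame(from = i, to = j, tau = res$tau, cpeak = res$cpeak)
    }
  }
  e <- if (length(edges)) do.call(rbind, edges)
       else data.frame(from = integer(0), to = integer(0),
                       tau = numeric(0), cpeak = numeric(0))
  dOut <- 100 * tabulate(e$from, nNeurons) / (nNeurons - 1L)
  dIn <- 100 * tabulate(e$to, nNeurons) / (nNeurons - 1L)
  new("FunctionalGraph", edges = e, nNeurons = as.integer(nNeurons),
      degreeOut = dOut, degreeIn = dIn)
}

#' Functional degrees and hub labelling
#'
#' @param graph a \linkS4class{FunctionalGraph}.
#' @param hubQuantile neurons at or above this quantile of the functional
#'   out-degree distribution are labelled hubs.
#' @return data.frame(neuron, degreeOut, degreeIn, hub).
#' @export
functionalDegrees <- function(graph, hubQuantile = 0.90) {
  dO <- graph@degreeOut
  thr <- quantile(dO, hubQuantile, names = FALSE)
  data.frame(neuron = seq_len(graph@nNeurons),
             degreeOut = dO, degreeIn = graph@degreeIn,
             hub = dO >= thr & dO > 0)
}
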