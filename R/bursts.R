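## Population-burst (PB) and aborted-burst (AB) detection, build-up
## refinement, phase indicator, IGI comparison and PB-participation
## similarity.

# distinct firing neurons per bin; bins anchored at t = 0 of the analysis
# window, bin k covering [k*binMs, (k+1)*binMs)
.distinctCounts <- function(times, neurons, binMs, duration) {
  nBins <- max(1L, as.integer(ceiling(duration / binMs)))
  if (!length(times)) return(integer(nBins))
  bin <- pmin(as.integer(floor(times / binMs)), nBins - 1L) + 1L
  key <- !duplicated(paste(bin, neurons))
  tabulate(bin[key], nBins)
}

#' Detect population bursts
#'
#' Bins the spike raster (default 10 ms, anchored at time 0) and marks a
#' bin burst-active when the number of DISTINCT firing neurons strictly
#' exceeds \code{frac} of the population. Consecutive active bins merge
#' into one PB whose peak is the centre of the maximal-count bin and whose
#' width is the extent of the merged bin run.
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param binMs bin width (ms).
#' @param frac participation threshold (strict inequality).
#' @return A \linkS4class{BurstCatalog} (PBs only; see
#'   [detectAbortedBursts()] to fill the AB slot).
#' @examples
#' sd <- new("SpikeData",
#'           spikes = data.frame(time = rep(5, 30), neuron = 1:30),
#'           duration = 100, nNeurons = 100L, traces = list())
#' populationBursts(detectBursts(sd))
#' @export
detectBursts <- function(spikeData, binMs = 10, frac = 0.25) {
  n <- spikeData@nNeurons
  stopifnot(n > 0)
  s <- spikeData@spikes
  counts <- .distinctCounts(s$time, s$neuron, binMs, spikeData@duration)
  active <- counts > frac * n
  emptyPB <- data.frame(peak = numeric(0), onset = numeric(0),
                        offset = numeric(0), width = numeric(0),
                        nParticipants = integer(0), peakCount = integer(0))
  emptyAB <- data.frame(peak = numeric(0), count = integer(0))
  if (!any(active)) {
    return(new("BurstCatalog", pb = emptyPB, participants = list(),
               ab = emptyAB, binMs = binMs, frac = frac,
               nNeurons = n, duration = spikeData@duration))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  pb <- lapply(keep, function(k) {
    b1 <- starts[k]; b2 <- ends[k]
    seg <- counts[b1:b2]
    peakBin <- b1 + which.max(seg) - 1L
    onset <- (b1 - 1L) * binMs
    offset <- b2 * binMs
    inPB <- s$time >= onset & s$time < offset
    parts <- sort(unique(s$neuron[inPB]))
    list(row = data.frame(peak = (peakBin - 0.5) * binMs, onset = onset,
                          offset = offset, width = offset - onset,
                          nParticipants = length(parts),
                          peakCount = max(seg)),
         parts = parts)
  })
  new("BurstCatalog",
      pb = do.call(rbind, lapply(pb, `[[`, "row")),
      participants = lapply(pb, `[[`, "parts"),
      ab = emptyAB, binMs = binMs, frac = frac,
      nNeurons = n, duration = spikeData@duration)
}

#' Detect aborted bursts
#'
#' An aborted burst is a collective activity enhancement that stays below
#' the PB threshold: a local maximum of the binned distinct-neuron count
#' that (a) exceeds \code{baselineFactor} times the median out-of-burst
#' bin count, (b) involves at least \code{minFrac} of the population,
#' (c) does not belong to a PB and (d) lies at least \code{minSepMs} from
#' every PB peak. The quantitative rule is an operational definition
#' (exposed through the arguments) of the qualitative "well below the PB
#' threshold" criterion.
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param catalog the PB catalog from [detectBursts()].
#' @param minFrac minimal participation for an AB.
#' @param baselineFactor multiple of the median inter-burst bin count.
#' @param minSepMs minimal distance from any PB peak (ms).
#' @return The catalog with the \code{ab} slot filled.
#' @export
detectAbortedBursts <- function(spikeData, catalog, minFrac = 0.10,
                                baselineFactor = 2, minSepMs = 50) {
  n <- catalog@nNeurons
  binMs <- catalog@binMs
  s <- spikeData@spikes
  counts <- .distinctCounts(s$time, s$neuron, binMs, spikeData@duration)
  nBins <- length(counts)
  centers <- (seq_len(nBins) - 0.5) * binMs
  inPB <- rep(FALSE, nBins)
  for (r in seq_len(nrow(catalog@pb))) {
    b1 <- floor(catalog@pb$onset[r] / binMs) + 1L
    b2 <- ceiling(catalog@pb$offset[r] / binMs)
    inPB[b1:min(b2, nBins)] <- TRUE
  }
  baseline <- if (any(!inPB)) median(counts[!inPB]) else 0
  # local maxima; plateau members all qualify but only the first of a
  # contiguous run is kept below
  up <- c(TRUE, diff(counts) >= 0)
  down <- c(diff(counts) <= 0, TRUE)
  localMax <- up & down
  cand <- which(localMax & !inPB &
                counts > baselineFactor * baseline &
                counts >= minFrac * n &
                counts <= catalog@frac * n)
  if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) > 1L)]  # plateaus
  if (length(cand) && nrow(catalog@pb)) {
    sep <- vapply(centers[cand], function(tt)
      min(abs(tt - catalog@pb$peak)), numeric(1))
    cand <- cand[sep >= minSepMs]
  }
  catalog@ab <- data.frame(peak = centers[cand], count = counts[cand])
  catalog
}

#' Refine PB peaks and extract build-up windows
#'
#' Re-locates every PB peak at 1 ms resolution -- the first fine bin in
#' which more than \code{peakFrac} of the population fires -- and uses it
#' as the time origin. The \code{windowMs} preceding the peak is the
#' build-up period; the per-neuron first spike inside it is returned,
#' together with the threshold-crossing time obtained by linear
#' interpolation between successive fine-bin counts.
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param catalog PB catalog.
#' @param fineBinMs fine bin width (ms).
#' @param peakFrac fine-resolution participation threshold (strict).
#' @param windowMs build-up window length (ms).
#' @return A list with one element per retained PB: \code{peak} (refined,
#'   ms), \code{crossing} (interpolated threshold crossing, ms),
#'   \code{firstSpikes} (data.frame neuron, time). PBs without a
#'   qualifying fine bin are dropped with a warning.
#' @export
refineBuildup <- function(spikeData, catalog, fineBinMs = 1,
                          peakFrac = 0.05, windowMs = 70) {
  if (!nrow(catalog@pb)) stop("catalog contains no PBs")
  n <- catalog@nNeurons
  s <- spikeData@spikes
  out <- list()
  dropped <- 0L
  for (r in seq_len(nrow(catalog@pb))) {
    lo <- max(0, catalog@pb$onset[r] - 2 * catalog@binMs)
    hi <- min(spikeData@duration, catalog@pb$offset[r] + 2 * catalog@binMs)
    sel <- s$time >= lo & s$time < hi
    tt <- s$time[sel] - lo
    nn <- s$neuron[sel]
    counts <- .distinctCounts(tt, nn, fineBinMs, hi - lo)
    qual <- which(counts > peakFrac * n)
    if (!length(qual)) { dropped <- dropped + 1L; next }
    k <- qual[1L]
    peak <- lo + (k - 0.5) * fineBinMs
    thr <- peakFrac * n
    crossing <- if (k > 1L && counts[k] > counts[k - 1L]) {
      lo + (k - 1.5) * fineBinMs +
        fineBinMs * (thr - counts[k - 1L]) / (counts[k] - counts[k - 1L])
    } else peak
    w <- s$time >= peak - windowMs & s$time < peak
    if (any(w)) {
      first <- tapply(s$time[w], s$neuron[w], min)
      fs <- data.frame(neuron = as.integer(names(first)),
                       time = as.numeric(first))
      fs <- fs[order(fs$time, fs$neuron), ]
      rownames(fs) <- NULL
    } else {
      fs <- data.frame(neuron = integer(0), time = numeric(0))
    }
    out[[length(out) + 1L]] <- list(peak = peak, crossing = crossing,
                                    firstSpikes = fs)
  }
  if (dropped)
    warning(dropped, " PB(s) without a qualifying fine bin were dropped")
  out
}

#' Phase indicator of an event train
#'
#' \deqn{\Phi_i = (t_G^i - i \Delta t)/\Delta t}
#' where \eqn{\Delta t} is the mean inter-event interval under control
#' conditions and \eqn{i \Delta t} the expected occurrence time of the
#' i-th event. Negative drift marks acceleration relative to control.
#'
#' @param tG event times (any unit, consistent with \code{deltaT});
#'   indexed from 1 relative to the epoch start.
#' @param deltaT control mean inter-event interval (> 0).
#' @return data.frame(index, phi).
#' @examples
#' phaseIndicator(c(2.5, 5.0), 2)   # phi = 0.25, 0.50
#' @export
phaseIndicator <- function(tG, deltaT) {
  stopifnot(deltaT > 0, length(tG) >= 1)
  i <- seq_along(tG)
  data.frame(index = i, phi = (tG - i * deltaT) / deltaT)
}

#' Rolling-window mean of inter-event intervals
#'
#' For each event time, the mean interval among events within the
#' following window -- the smoothed IGI series used when comparing
#' stimulation epochs.
#'
#' @param tG event times (s or ms).
#' @param window window length in the same unit.
#' @return Numeric vector (NA where fewer than two events fall in the
#'   window).
#' @export
rollingMeanIGI <- function(tG, window = 60) {
  vapply(tG, function(t0) {
    sel <- tG >= t0 & tG <= t0 + window
    if (sum(sel) < 2) NA_real_ else mean(diff(tG[sel]))
  }, numeric(1))
}

#' Compare two IGI distributions
#'
#' Two-sample Kolmogorov-Smirnov test between inter-burst-interval
#' samples (e.g. control vs stimulation epochs).
#'
#' @param igiControl,igiTest interval samples.
#' @param alpha significance level.
#' @return list(p, significant, undefined): \code{undefined = TRUE} (and
#'   no significance claim) when either sample has fewer than 2 intervals.
#' @export
compareIGIEpochs <- function(igiControl, igiTest, alpha = 0.05) {
  if (length(igiControl) < 2 || length(igiTest) < 2)
    return(list(p = NA_real_, significant = NA, undefined = TRUE))
  p <- suppressWarnings(ks.test(igiControl, igiTest)$p.value)
  list(p = p, significant = p < alpha, undefined = FALSE)
}

#' PB participation similarity and two-cluster split
#'
#' Binary participation vectors (neurons x PBs) compared by cosine
#' similarity; the PBs are split into two groups by cutting an
#' average-linkage dendrogram of 1 - similarity. The group with the
#' larger mean participation is reported as the high-participation
#' cluster.
#'
#' @param catalog a \linkS4class{BurstCatalog} with at least 2 PBs.
#' @return list(similarity, cluster, nHigh, nLow).
#' @export
participationSimilarity <- function(catalog) {
  m <- length(catalog@participants)
  stopifnot(m >= 2)
  P <- vapply(catalog@participants, function(p) {
    v <- numeric(catalog@nNeurons); v[p] <- 1; v
  }, numeric(catalog@nNeurons))
  cp <- crossprod(P)
  nrm <- sqrt(diag(cp))
  sim <- cp / outer(nrm, nrm)
  sim[!is.finite(sim)] <- 0
  if (all(sim >= 1 - 1e-12)) {
    cl <- rep(1L, m)
  } else {
    hc <- hclust(as.dist(1 - sim), method = "average")
    cl <- cutree(hc, k = 2)
  }
  part <- colSums(P)
  if (length(unique(cl)) == 2 &&
      mean(part[cl == 2]) > mean(part[cl == 1])) cl <- 3L - cl
  list(similarity = sim, cluster = cl,
       nHigh = sum(cl == 1L), nLow = sum(cl == 2L))
}

#' Summary statistics of a burst catalog
#'
#' @param catalog a \linkS4class{BurstCatalog}.
#' @return list: nPB, nAB, abRatio (percent), meanIGI/sdIGI (s),
#'   meanWidth/sdWidth (ms), meanParticipation (percent of neurons).
#' @export
burstStatistics <- function(catalog) {
  ig <- igi(catalog)
  nPB <- nrow(catalog@pb)
  list(nPB = nPB, nAB = nrow(catalog@ab),
       abRatio = if (nPB) 100 * nrow(catalog@ab) / nPB else NA_real_,
       meanIGI = if (length(ig)) mean(ig) else NA_real_,
       sdIGI = if (length(ig) > 1) sd(ig) else NA_real_,
       meanWidth = if (nPB) mean(catalog@pb$width) else NA_real_,
       sdWidth = if (nPB > 1) sd(catalog@pb$width) else NA_real_,
       meanParticipation = if (nPB)
         100 * mean(catalog@pb$nParticipants) / catalog@nNeurons
       else NA_real_)
}
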