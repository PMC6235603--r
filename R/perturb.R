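## Single-neuron perturbation protocols: deletion (SND), DC-step
## stimulation (SNS), baseline variability, driver classification
## (hub / LC1 / LC2), clique/route extraction and synaptic-resource
## monitoring.

# one control/perturbation run: simulate and count PBs in the window
.pbCount <- function(net, windowS, program = NULL, seed = NULL,
                     burnIn = 10000, binMs = 10, frac = 0.25) {
  sd <- simulateNetwork(net, windowS * 1000, program = program,
                        seed = seed, burnIn = burnIn)
  catalog <- detectBursts(sd, binMs = binMs, frac = frac)
  list(count = nrow(catalog@pb), spikes = sd, catalog = catalog)
}

#' Baseline PB-count variability over initial conditions
#'
#' Repeats the control simulation over independent initial-condition
#' seeds and reports the mean and SD of the PB count per window, plus the
#' 3-SD significance band used to gate perturbation effects. A network
#' whose mean count falls below \code{minPB} is flagged unusable
#' (non-bursting or too few bursts to analyse).
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param nRuns number of initial conditions.
#' @param windowS recording window (s).
#' @param seed integer; run r uses seed + r.
#' @param minPB minimal mean PB count for a usable baseline.
#' @param burnIn discarded settling period (ms).
#' @return list(mean, sd, counts, band = mean -/+ 3 sd, usable).
#' @export
baselineVariability <- function(net, nRuns = 100, windowS = 84,
                                seed = 0, minPB = 5, burnIn = 10000) {
  counts <- vapply(seq_len(nRuns), function(r)
    .pbCount(net, windowS, seed = seed + r, burnIn = burnIn)$count,
    numeric(1))
  m <- mean(counts)
  s <- if (nRuns > 1) sd(counts) else 0
  list(mean = m, sd = s, counts = counts,
       band = c(m - 3 * s, m + 3 * s), usable = m >= minPB)
}

#' Single-neuron deletion experiment
#'
#' Removes one neuron from the network (it neither integrates nor
#' transmits) and records the PB count over the window.
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param neuron id of the deleted neuron.
#' @param windowS recording window (s).
#' @param seed integer seed (initial conditions).
#' @param burnIn discarded settling period (ms).
#' @return list(neuron, protocol = "SND", nPB).
#' @export
sndExperiment <- function(net, neuron, windowS = 84, seed = 0,
                          burnIn = 10000) {
  prog <- stimulusProgram(deletions = neuron)
  r <- .pbCount(net, windowS, program = prog, seed = seed, burnIn = burnIn)
  list(neuron = neuron, protocol = "SND", nPB = r$count)
}

#' Single-neuron stimulation experiment
#'
#' Applies a DC step to one neuron -- its effective drive becomes
#' \code{iStim} for the whole window (burn-in included, so the network
#' settles under stimulation as in a prolonged step) -- and records the
#' PB count and the stimulated neuron's firing rate.
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param neuron stimulated neuron id.
#' @param iStim stimulation current (mV).
#' @param windowS recording window (s).
#' @param seed integer seed.
#' @param burnIn settling period (ms); the step starts at the beginning
#'   of burn-in.
#' @return list(neuron, protocol = "SNS", iStim, nPB, rate).
#' @export
snsExperiment <- function(net, neuron, iStim, windowS = 84, seed = 0,
                          burnIn = 10000) {
  prog <- stimulusProgram(dcSteps = data.frame(
    neuron = neuron, amp = iStim, ton = -burnIn, toff = windowS * 1000))
  r <- .pbCount(net, windowS, program = prog, seed = seed, burnIn = burnIn)
  list(neuron = neuron, protocol = "SNS", iStim = iStim, nPB = r$count,
       rate = firingRates(r$spikes)[neuron])
}

#' SNS current sweep
#'
#' PB count and stimulated-neuron firing rate across a range of DC
#' currents (the response curves of the stimulation protocol). The
#' default grid spans slightly below threshold to well above it.
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param neuron stimulated neuron id.
#' @param iRange range of stimulation currents (mV).
#' @param step current increment (mV); the published protocol uses
#'   0.015 mV, coarser grids trade resolution for runtime.
#' @param windowS,seed,burnIn as in [snsExperiment()].
#' @return data.frame(iStim, nPB, rate).
#' @export
sweepSNS <- function(net, neuron, iRange = c(14.5, 18), step = 0.015,
                     windowS = 84, seed = 0, burnIn = 10000) {
  grid <- seq(iRange[1], iRange[2], by = step)
  rows <- lapply(grid, function(I) {
    r <- snsExperiment(net, neuron, I, windowS = windowS, seed = seed,
                       burnIn = burnIn)
    data.frame(iStim = I, nPB = r$nPB, rate = r$rate)
  })
  do.call(rbind, rows)
}

#' Classify driver cells from SND/SNS outcomes
#'
#' A neuron is a functional HUB when its deletion reduces the PB count by
#' at least \code{threshold} (relative to the control mean) AND beyond
#' the 3-SD baseline band (conjunctive gate). A non-hub neuron is a
#' DRIVER when some stimulation current changes the PB count by at least
#' \code{threshold} beyond the band; it is LC2 when every significant
#' change is an increase, LC1 otherwise.
#'
#' @param sndCounts numeric vector, PB count under deletion per neuron.
#' @param snsCounts list (per neuron) of numeric vectors: PB counts across
#'   the stimulation sweep; may contain zero-length entries for neurons
#'   not swept.
#' @param baseline result of [baselineVariability()].
#' @param neuronClass "exc"/"inh" per neuron.
#' @param threshold relative change defining a driver (default 50\%).
#' @param sdGate width of the significance band in SDs.
#' @return A \linkS4class{DriverReport}.
#' @export
classifyDrivers <- function(sndCounts, snsCounts, baseline,
                            neuronClass = rep("exc", length(sndCounts)),
                            threshold = 0.5, sdGate = 3) {
  m <- baseline$mean
  s <- baseline$sd
  n <- length(sndCounts)
  stopifnot(length(snsCounts) == n)
  cls <- character(n)
  sndChange <- (sndCounts - m) / m
  snsUp <- snsDown <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sig <- function(x) abs(x - m) > sdGate * s
    isHub <- !is.na(sndCounts[i]) &&
      (m - sndCounts[i]) / m >= threshold && sig(sndCounts[i])
    sw <- snsCounts[[i]]
    rel <- if (length(sw)) (sw - m) / m else numeric(0)
    sigChange <- if (length(sw)) abs(rel) >= threshold & sig(sw) else logical(0)
    snsUp[i] <- if (length(rel)) max(rel) else NA_real_
    snsDown[i] <- if (length(rel)) min(rel) else NA_real_
    if (isHub) {
      cls[i] <- "hub"
    } else if (any(sigChange)) {
      cls[i] <- if (all(rel[sigChange] > 0)) "LC2" else "LC1"
    } else {
      cls[i] <- "none"
    }
  }
  tab <- data.frame(neuron = seq_len(n), class = neuronClass,
                    sndCount = sndCounts, sndChange = sndChange,
                    snsMaxIncrease = snsUp, snsMaxDecrease = snsDown,
                    driverClass = cls)
  new("DriverReport", table = tab, controlMean = m, controlSd = s,
      clique = list())
}

#' Extract the functional clique: activation order, routes and delays
#'
#' Within the build-up window preceding each PB, the hub neurons fire in
#' a stereotyped sequence. This operation (i) cross-correlates the hubs'
#' first build-up spikes to recover the activation order and the leader
#' (the hub never preceded by another hub: build-up functional in-degree
#' zero), and (ii) enumerates the distinct full firing sequences
#' ("routes") over PBs, reporting each route's frequency and the mean and
#' SD of the successive inter-neuron delays on the dominant route. A hub
#' firing several times within one build-up window is distinguished by
#' occurrence index.
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param catalog PB catalog.
#' @param hubs integer ids of the clique candidates.
#' @param windowMs build-up window (ms).
#' @param maxLag,alpha functional-connectivity test settings among hubs.
#' @return list(order, leader, routes, dominantRoute, delays, graph):
#'   \code{routes} is a frequency table of firing sequences;
#'   \code{delays} a data.frame(step, mean, sd) for the dominant route;
#'   \code{graph} the hub-restricted \linkS4class{FunctionalGraph}.
#' @export
extractClique <- function(spikeData, catalog, hubs, windowMs = 70,
                          maxLag = 100, alpha = 0.05) {
  stopifnot(nrow(catalog@pb) >= 1, length(hubs) >= 2)
  s <- spikeData@spikes
  n <- spikeData@nNeurons
  # per-PB hub firing sequences within the build-up window
  seqs <- list()
  delayRows <- list()
  for (r in seq_len(nrow(catalog@pb))) {
    pk <- catalog@pb$peak[r]
    w <- s$time >= pk - windowMs & s$time < pk & s$neuron %in% hubs
    if (!any(w)) next
    tt <- s$time[w]; nn <- s$neuron[w]
    o <- order(tt, nn)
    tt <- tt[o]; nn <- nn[o]
    occ <- stats::ave(seq_along(nn), nn, FUN = seq_along)
    lab <- ifelse(occ == 1L, as.character(nn), paste0(nn, "#", occ))
    seqs[[length(seqs) + 1L]] <- paste(lab, collapse = " > ")
    if (length(tt) > 1)
      delayRows[[length(delayRows) + 1L]] <-
        data.frame(route = seqs[[length(seqs)]],
                   step = paste(lab[-length(lab)], ">", lab[-1L]),
                   delay = diff(tt))
  }
  routes <- sort(table(unlist(seqs)), decreasing = TRUE)
  dominant <- if (length(routes)) names(routes)[1L] else NA_character_
  delays <- if (length(delayRows)) {
    dd <- do.call(rbind, delayRows)
    dd <- dd[dd$route == dominant, , drop = FALSE]
    if (nrow(dd)) {
      agg <- split(dd$delay, factor(dd$step, levels = unique(dd$step)))
      data.frame(step = names(agg),
                 mean = vapply(agg, mean, numeric(1)),
                 sd = vapply(agg, function(x)
                   if (length(x) > 1) sd(x) else 0, numeric(1)),
                 row.names = NULL)
    } else data.frame(step = character(0), mean = numeric(0),
                      sd = numeric(0))
  } else data.frame(step = character(0), mean = numeric(0),
                    sd = numeric(0))
  # build-up functional graph restricted to the hubs
  surro <- makeSurrogate(spikeData, "buildup", catalog,
                         windowMs = windowMs)
  for (i in seq_len(n)) if (!(i %in% hubs)) surro[[i]] <- numeric(0)
  g <- buildFunctionalGraph(surro, nNeurons = n, maxLag = maxLag,
                            alpha = alpha)
  dIn <- g@degreeIn[hubs]
  leader <- hubs[dIn == 0 & g@degreeOut[hubs] > 0]
  # activation order: by mean first-spike time within build-up windows
  meanFirst <- vapply(hubs, function(h) {
    x <- surro[[h]]
    if (length(x)) {
      pkIdx <- vapply(x, function(t0)
        which.min(abs(catalog@pb$peak - t0)), integer(1))
      mean(x - catalog@pb$peak[pkIdx])
    } else NA_real_
  }, numeric(1))
  list(order = hubs[order(meanFirst)], leader = leader,
       routes = routes, dominantRoute = dominant, delays = delays,
       graph = g)
}

#' Monitor synaptic resources around population bursts
#'
#' From a traced simulation (see \code{traceDt}/\code{traceNeurons} of
#' [simulateNetwork()]), extracts for each monitored neuron the local
#' maximum of its mean efferent recovered fraction X^OUT immediately
#' before each PB ignition, the minimal ignition value X^OUT* (smallest
#' pre-PB maximum over observed PBs), and the association between the
#' pre-PB maxima and the preceding inter-burst interval.
#'
#' @param spikeData a traced \linkS4class{SpikeData}.
#' @param catalog PB catalog from the same simulation.
#' @param neurons ids among the traced neurons to analyse.
#' @return Named list per neuron: \code{prePB} data.frame(peak, xmax,
#'   igi), \code{xstar}, \code{rho} (Spearman correlation of IGI with the
#'   pre-PB maximum, over PBs with a defined preceding interval).
#' @export
resourceMonitor <- function(spikeData, catalog, neurons) {
  tr <- spikeData@traces
  if (!length(tr)) stop("spikeData carries no traces; rerun with traceDt > 0")
  stopifnot(all(neurons %in% tr$neurons))
  out <- list()
  pb <- catalog@pb
  for (nu in neurons) {
    col <- match(nu, tr$neurons)
    x <- tr$xout[, col]
    if (all(is.na(x))) {
      out[[as.character(nu)]] <- list(prePB = NULL, xstar = NA_real_,
                                      rho = NA_real_, flagged = TRUE)
      next
    }
    rows <- lapply(seq_len(nrow(pb)), function(r) {
      lo <- if (r == 1) 0 else pb$offset[r - 1]
      sel <- tr$time >= lo & tr$time <= pb$onset[r]
      if (!any(sel)) return(NULL)
      data.frame(peak = pb$peak[r], xmax = max(x[sel], na.rm = TRUE),
                 igi = if (r == 1) NA_real_
                       else (pb$peak[r] - pb$peak[r - 1]) / 1000)
    })
    prePB <- do.call(rbind, rows)
    ok <- !is.na(prePB$igi)
    rho <- if (sum(ok) > 2)
      suppressWarnings(cor(prePB$igi[ok], prePB$xmax[ok],
                           method = "spearman"))
    else NA_real_
    out[[as.character(nu)]] <- list(prePB = prePB,
                                    xstar = min(prePB$xmax),
                                    rho = rho, flagged = FALSE)
  }
  out
}
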