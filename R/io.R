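## Plain-text serialization: network realizations as a pair of TSV tables
## (versioned header, byte-stable round trip), spikes as two-column TSV,
## catalogs as TSV + JSON summary, configs as flat key=value files.

.NET_HEADER <- "#burstclique-network\tv1"

.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write / read a network realization
#'
#' A realization is stored as two TSV tables sharing a versioned header
#' line: \code{<prefix>_neurons.tsv} (id, class, I_b) and
#' \code{<prefix>_edges.tsv} (post_id, pre_id, G, T_I, T_R, T_F, U; T_F
#' is NA on non-facilitating edges). Numbers are written with 17
#' significant digits so that serialize -> load -> serialize is
#' byte-identical.
#'
#' @param net a \linkS4class{NetworkRealization}.
#' @param prefix path prefix for the two files.
#' @return \code{writeNetwork}: the two file paths, invisibly.
#' @export
writeNetwork <- function(net, prefix) {
  n <- nNeurons(net)
  fN <- paste0(prefix, "_neurons.tsv")
  fE <- paste0(prefix, "_edges.tsv")
  conN <- file(fN, "w")
  writeLines(.NET_HEADER, conN)
  writeLines("id\tclass\tI_b", conN)
  writeLines(sprintf("%d\t%s\t%s", seq_len(n), net@neuronClass,
                     .fmt(net@excitability)), conN)
  close(conN)
  el <- .edgeList(net)
  conE <- file(fE, "w")
  writeLines(.NET_HEADER, conE)
  writeLines("post_id\tpre_id\tG\tT_I\tT_R\tT_F\tU", conE)
  if (length(el$post))
    writeLines(sprintf("%d\t%d\t%s\t%s\t%s\t%s\t%s", el$post, el$pre,
                       .fmt(el$G), .fmt(el$TI), .fmt(el$TR), .fmt(el$TF),
                       .fmt(el$U)), conE)
  close(conE)
  invisible(c(fN, fE))
}

#' @rdname writeNetwork
#' @param config optional \linkS4class{NetworkConfig} to attach to the
#'   loaded realization (the files do not store the generating config).
#' @return \code{readNetwork}: a \linkS4class{NetworkRealization}.
#' @export
readNetwork <- function(prefix, config = NULL) {
  fN <- paste0(prefix, "_neurons.tsv")
  fE <- paste0(prefix, "_edges.tsv")
  for (f in c(fN, fE)) {
    if (readLines(f, n = 1) != .NET_HEADER)
      stop("not a burstclique network file (bad header): ", f)
  }
  nt <- read.table(fN, header = TRUE, sep = "\t", skip = 1,
                   colClasses = c("integer", "character", "numeric"))
  et <- read.table(fE, header = TRUE, sep = "\t", skip = 1,
                   colClasses = c("integer", "integer", rep("numeric", 5)))
  n <- nrow(nt)
  if (is.null(config))
    config <- networkConfig(nTotal = n, nExc = sum(nt$class == "exc"),
                            nInh = sum(nt$class == "inh"),
                            meanInDegree = max(1e-6, nrow(et) / n))
  a <- matrix(0L, n, n)
  G <- TI <- TR <- TF <- U <- matrix(NA_real_, n, n)
  idx <- cbind(et$post_id, et$pre_id)
  a[idx] <- 1L
  G[idx] <- et$G; TI[idx] <- et$T_I; TR[idx] <- et$T_R
  TF[idx] <- et$T_F; U[idx] <- et$U
  net <- new("NetworkRealization", adjacency = a, neuronClass = nt$class,
             excitability = nt$I_b, G = G, TI = TI, TR = TR, TF = TF,
             U = U, config = config)
  validObject(net)
  net
}

#' Write / read spike timestamps
#'
#' Two-column TSV (time_ms, neuron_id), sorted by time; interoperable
#' with any external two-column timestamp table, so the burst and
#' functional-connectivity machinery can also run on experimental onset
#' data.
#'
#' @param spikeData a \linkS4class{SpikeData}.
#' @param path output file.
#' @export
writeSpikes <- function(spikeData, path) {
  con <- file(path, "w")
  writeLines("time_ms\tneuron_id", con)
  s <- spikeData@spikes
  if (nrow(s))
    writeLines(sprintf("%s\t%d", .fmt(s$time), s$neuron), con)
  close(con)
  invisible(path)
}

#' @rdname writeSpikes
#' @param duration,nNeurons context for the loaded table; defaults are
#'   inferred (max time, max id).
#' @export
readSpikes <- function(path, duration = NULL, nNeurons = NULL) {
  s <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("numeric", "integer"))
  names(s) <- c("time", "neuron")
  s <- s[order(s$time, s$neuron), ]
  rownames(s) <- NULL
  if (is.null(duration)) duration <- if (nrow(s)) max(s$time) + 1 else 1
  if (is.null(nNeurons)) nNeurons <- if (nrow(s)) max(s$neuron) else 1L
  new("SpikeData", spikes = s, duration = duration,
      nNeurons = as.integer(nNeurons), traces = list())
}

#' Export a burst catalog
#'
#' Writes a TSV of events (type PB/AB with peak, onset, offset, width,
#' participants) and a JSON summary (IGI mean/SD in seconds, width
#' mean/SD in ms, AB/PB ratio in percent).
#'
#' @param catalog a \linkS4class{BurstCatalog}.
#' @param prefix path prefix; writes \code{<prefix>_events.tsv} and
#'   \code{<prefix>_summary.json}.
#' @export
exportCatalog <- function(catalog, prefix) {
  fT <- paste0(prefix, "_events.tsv")
  fJ <- paste0(prefix, "_summary.json")
  pb <- catalog@pb
  ab <- catalog@ab
  ev <- rbind(
    if (nrow(pb)) data.frame(type = "PB", peak = pb$peak,
                             onset = pb$onset, offset = pb$offset,
                             width = pb$width,
                             n_participants = pb$nParticipants),
    if (nrow(ab)) data.frame(type = "AB", peak = ab$peak,
                             onset = NA_real_, offset = NA_real_,
                             width = NA_real_, n_participants = ab$count))
  if (is.null(ev)) ev <- data.frame(type = character(0), peak = numeric(0),
                                    onset = numeric(0), offset = numeric(0),
                                    width = numeric(0),
                                    n_participants = integer(0))
  ev <- ev[order(ev$peak), ]
  write.table(ev, fT, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(burstStatistics(catalog), fJ, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(fT, fJ))
}

#' Write / read a flat key=value configuration file
#'
#' Every generator parameter is exposed with its default; unknown keys
#' raise an error on read so that typos do not silently fall back to
#' defaults.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  kv <- c(n_total = config@nTotal, n_exc = config@nExc,
          n_inh = config@nInh, mean_in_degree = config@meanInDegree,
          excitability_center = config@excitabilityCenter,
          excitability_width = config@excitabilityWidth,
          frac_suprathreshold = config@fracSuprathreshold,
          sd_factor = config@sdFactor,
          correlated = as.integer(config@correlated),
          as.list(config@synMeans))
  writeLines(paste0(names(kv), " = ", vapply(kv, format, character(1))),
             path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(parts, `[[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(parts, `[[`, character(1), 2)))
  known <- c("n_total", "n_exc", "n_inh", "mean_in_degree",
             "excitability_center", "excitability_width",
             "frac_suprathreshold", "sd_factor", "correlated",
             names(.defaultSynMeans))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  kv <- stats::setNames(vals, keys)
  get0 <- function(k, d) if (k %in% keys) kv[[k]] else d
  sm <- .defaultSynMeans
  for (k in names(sm)) sm[k] <- get0(k, sm[k])
  networkConfig(nTotal = get0("n_total", 100), nExc = get0("n_exc", 90),
                nInh = get0("n_inh", 10),
                meanInDegree = get0("mean_in_degree", 10),
                excitabilityCenter = get0("excitability_center", 15),
                excitabilityWidth = get0("excitability_width", 0.45),
                fracSuprathreshold = get0("frac_suprathreshold", 0.10),
                synMeans = sm, sdFactor = get0("sd_factor", 0.5),
                correlated = get0("correlated", 1) != 0)
}
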