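## Synthetic route-history generator: emulates the scale and hub structure
## of an arrival-conditioned commercial vessel-movement extract, so every
## pipeline stage is testable without proprietary data. Also a catalogue of
## tiny hand-solvable fixtures with attached exact answers.

#' Configuration for the synthetic shipping network
#'
#' Defaults are fixed to the study conditions the package emulates: 553
#' foreign ports in 126 countries, 30 domestic ports, 557 ships, and 3000
#' voyages whose route-length distribution over 2-11 calls has mean 8.50,
#' giving an expected 25,500 port-call events (the extract documents
#' 25,507). Two designated hub ports receive `hubWeight` times the traffic
#' of ordinary ports, emulating the observed pattern of two dominant hubs
#' with roughly four times the degree centrality of the third-ranked port.
#' Leg durations are exponential with mean 7.9 days. The organism's range
#' covers 36 countries of which 12 are off-network (codes absent from the
#' registry), matching the recorded-range-vs-network intersection the
#' analysis starts from.
#'
#' @param nForeignPorts,nCountries,nDomesticPorts,nShips,nVoyages network scale.
#' @param routeLengthProbs probabilities of route lengths 2..11 (truncation
#'   at ten prior calls plus the destination).
#' @param hubFraction fraction of foreign ports that are hubs (default
#'   2/553, i.e. two hubs).
#' @param hubWeight sampling weight of a hub relative to the largest
#'   non-hub port. The default 6 is calibrated so the *realized* top-hub
#'   to third-port degree-centrality ratio comes out near the observed 4
#'   (without-replacement draws saturate hub appearances, so the realized
#'   ratio is below the raw weight).
#' @param popularityExponent Zipf exponent of the non-hub popularity tail
#'   (weight of the k-th port proportional to k^-exponent); 0 gives a flat
#'   second tier. Real port-call frequencies are strongly size-skewed, and
#'   a flat tier would make ordinary ports statistically exchangeable --
#'   their true arrival rates would tie and rankings among them would be
#'   meaningless.
#' @param geographicOrdering order each voyage's calls by decreasing
#'   distance-to-destination (ships sail toward the destination). Each
#'   foreign port gets a fixed distance score; the hubs sit near the
#'   destination, emulating the observed pattern of dominant near hubs.
#'   Without this, every port would occupy exchangeable route positions
#'   and arrival rates would lose the orders-of-magnitude spread real
#'   panels show (rates decay geometrically with steps-to-destination).
#' @param orderJitter standard deviation of the noise added to distance
#'   scores when ordering a voyage's calls (occasional local detours).
#' @param meanLegDays mean sea-leg duration in days.
#' @param rangeCountries total countries in the organism's recorded range.
#' @param rangeOffNetwork how many of those are absent from the registry.
#' @param domesticIntermediateCalls allow domestic ports as intermediate
#'   calls (the arrival-conditioned extract has them only as destinations).
#' @param seed RNG seed; the generator is byte-reproducible from it.
#' @return validated config list of class `syntheticNetworkConfig`.
#' @export
syntheticNetworkConfig <- function(nForeignPorts = 553L, nCountries = 126L,
                                   nDomesticPorts = 30L, nShips = 557L,
                                   nVoyages = 3000L,
                                   routeLengthProbs = c(0.02, 0.03, 0.04, 0.05,
                                                        0.07, 0.09, 0.11, 0.14,
                                                        0.18, 0.27),
                                   hubFraction = 2 / 553, hubWeight = 6,
                                   popularityExponent = 0.7,
                                   geographicOrdering = TRUE,
                                   orderJitter = 0.05,
                                   meanLegDays = 7.9,
                                   rangeCountries = 36L, rangeOffNetwork = 12L,
                                   domesticIntermediateCalls = FALSE,
                                   seed = 20260101L) {
  cfg <- list(nForeignPorts = as.integer(nForeignPorts),
              nCountries = as.integer(nCountries),
              nDomesticPorts = as.integer(nDomesticPorts),
              nShips = as.integer(nShips), nVoyages = as.integer(nVoyages),
              routeLengthProbs = routeLengthProbs,
              hubFraction = hubFraction, hubWeight = hubWeight,
              popularityExponent = popularityExponent,
              geographicOrdering = isTRUE(geographicOrdering),
              orderJitter = orderJitter,
              meanLegDays = meanLegDays,
              rangeCountries = as.integer(rangeCountries),
              rangeOffNetwork = as.integer(rangeOffNetwork),
              domesticIntermediateCalls = isTRUE(domesticIntermediateCalls),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nForeignPorts >= 11,  # routes draw up to 10 distinct prior ports
              nCountries >= 1, nDomesticPorts >= 1,
              nShips >= 1, nVoyages >= 1,
              length(routeLengthProbs) == 10, all(routeLengthProbs >= 0),
              abs(sum(routeLengthProbs) - 1) < 1e-9,
              hubFraction > 0, hubFraction < 1, hubWeight >= 1,
              popularityExponent >= 0, orderJitter >= 0, meanLegDays > 0,
              rangeCountries >= 1, rangeOffNetwork >= 0,
              rangeOffNetwork < rangeCountries,
              nCountries <= nForeignPorts,
              rangeCountries - rangeOffNetwork <= nCountries)
  })
  nHubs <- max(1L, round(cfg$hubFraction * cfg$nForeignPorts))
  if (nHubs >= cfg$nForeignPorts)
    stop("infeasible config: more hubs than foreign ports", call. = FALSE)
  cfg$nHubs <- nHubs
  class(cfg) <- "syntheticNetworkConfig"
  cfg
}

## voyage ids V0001... with enough digits; stable zero-padded labels
.padIds <- function(prefix, n) sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))

#' Generate a synthetic route dataset
#'
#' Draws a port registry, voyage collection and pest range with the
#' statistical structure the pathway analysis assumes: hub-dominated
#' two-tier port popularity, routes of 2-11 calls ending at a domestic
#' port, exponential leg durations, and a country range partially off
#' network. Fully reproducible from `config$seed`.
#'
#' @param config a [syntheticNetworkConfig()].
#' @return list with `ports` (registry data.frame), `routes` (voyage
#'   data.frame with list-columns `calls` and `legDays`), `pestRange`
#'   (character country codes) and `config`.
#' @export
generateNetwork <- function(config = syntheticNetworkConfig()) {
  stopifnot(inherits(config, "syntheticNetworkConfig"))
  set.seed(config$seed)
  nF <- config$nForeignPorts; nC <- config$nCountries
  nD <- config$nDomesticPorts

  countries <- .padIds("C", nC)
  foreignIds <- .padIds("F", nF)
  domesticIds <- .padIds("A", nD)

  ## every country gets at least one port; the rest are multinomial with
  ## uneven country weights (real port registries are size-skewed)
  countryWeight <- rexp(nC) + 0.25
  portCountry <- c(countries,
                   sample(countries, nF - nC, replace = TRUE,
                          prob = countryWeight))
  portCountry <- sample(portCountry)  # decouple id order from country sizes

  ports <- data.frame(
    port_id = c(foreignIds, domesticIds),
    name = c(paste("Port", foreignIds), paste("Port", domesticIds)),
    country = c(portCountry, rep("AUS", nD)),
    is_domestic = c(rep(FALSE, nF), rep(TRUE, nD)),
    stringsAsFactors = FALSE
  )

  ## hub tier over a Zipf-like tail: hubs carry hubWeight times the weight
  ## of the largest non-hub port (without-replacement draws saturate hubs,
  ## so the realized degree ratio to the third port comes out near 4)
  hubIdx <- seq_len(config$nHubs)
  popW <- seq_len(nF)^(-config$popularityExponent)
  popW[hubIdx] <- config$hubWeight * popW[config$nHubs + 1L]
  ## distance-to-destination scores; hubs near the destination
  distScore <- runif(nF)
  distScore[hubIdx] <- 0.05 + 0.05 * (seq_along(hubIdx) - 1)
  domW <- 1 / seq_len(nD)  # skewed destination popularity

  lengths <- sample(2:11, config$nVoyages, replace = TRUE,
                    prob = config$routeLengthProbs)
  ships <- sample(.padIds("S", config$nShips), config$nVoyages, replace = TRUE)
  arrDates <- as.Date("2002-01-01") +
    sample.int(as.integer(as.Date("2007-12-31") - as.Date("2002-01-01")) + 1L,
               config$nVoyages, replace = TRUE) - 1L

  calls <- vector("list", config$nVoyages)
  legDays <- vector("list", config$nVoyages)
  poolIds <- if (config$domesticIntermediateCalls)
    c(foreignIds, domesticIds) else foreignIds
  poolW <- if (config$domesticIntermediateCalls) c(popW, domW) else popW
  poolDist <- if (config$domesticIntermediateCalls)
    c(distScore, rep(0, nD)) else distScore
  for (v in seq_len(config$nVoyages)) {
    L <- lengths[v]
    prior <- sample(poolIds, L - 1, prob = poolW)  # no revisits in-window
    if (config$geographicOrdering && L > 2) {
      score <- poolDist[match(prior, poolIds)] +
        rnorm(L - 1, 0, config$orderJitter)
      prior <- prior[order(-score)]
    }
    calls[[v]] <- c(prior, sample(domesticIds, 1, prob = domW))
    legDays[[v]] <- rexp(L - 1, rate = 1 / config$meanLegDays)
  }

  routes <- data.frame(ship_id = ships, voyage_id = .padIds("V", config$nVoyages),
                       arrival_date = arrDates, stringsAsFactors = FALSE)
  routes$calls <- I(calls)
  routes$legDays <- I(legDays)

  present <- sort(sample(countries, config$rangeCountries - config$rangeOffNetwork))
  absent <- .padIds("X", max(1L, config$rangeOffNetwork))[seq_len(config$rangeOffNetwork)]
  list(ports = ports, routes = routes,
       pestRange = sort(c(present, absent)), config = config)
}

#' Write a generated network in the package's CSV dialects
#'
#' Emits `ports.csv`, `routes.csv` (one row per port call; per-call dates
#' back-computed from the leg durations), `pest_range.txt` and a
#' `manifest.json` recording the configuration and summary counts. Output
#' is byte-identical for identical configs.
#'
#' @param net result of [generateNetwork()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
writeNetworkFiles <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ports = file.path(dir, "ports.csv"),
             routes = file.path(dir, "routes.csv"),
             range = file.path(dir, "pest_range.txt"),
             manifest = file.path(dir, "manifest.json"))

  pdf <- net$ports
  pdf$is_domestic <- as.integer(pdf$is_domestic)
  write.csv(pdf, paths["ports"], row.names = FALSE, quote = FALSE)

  rows <- lapply(seq_len(nrow(net$routes)), function(v) {
    calls <- net$routes$calls[[v]]
    L <- length(calls)
    lag <- rev(c(0, cumsum(rev(net$routes$legDays[[v]]))))  # days before arrival
    data.frame(ship_id = net$routes$ship_id[v],
               voyage_id = net$routes$voyage_id[v],
               seq = seq_len(L), port_id = calls,
               arrival_date = format(net$routes$arrival_date[v] - round(lag)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), paths["routes"], row.names = FALSE, quote = FALSE)

  writeLines(c("# organism established range, one country code per line",
               net$pestRange), paths["range"])

  manifest <- list(
    config = unclass(net$config),
    counts = list(ports = nrow(net$ports), voyages = nrow(net$routes),
                  callEvents = sum(lengths(net$routes$calls)),
                  rangeCountries = length(net$pestRange))
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

.mkRoutes <- function(callsList, datePrefix = "2004-06-01") {
  n <- length(callsList)
  df <- data.frame(ship_id = .padIds("S", n), voyage_id = .padIds("V", n),
                   arrival_date = rep(as.Date(datePrefix), n),
                   stringsAsFactors = FALSE)
  df$calls <- I(callsList)
  df
}

.mkRegistry <- function(foreign, domestic, foreignCountry = NULL) {
  if (is.null(foreignCountry)) foreignCountry <- paste0("C_", foreign)
  ids <- c(foreign, domestic)
  data.frame(
    port_id = ids,
    name = paste("Port", ids),
    country = c(foreignCountry, rep("AUS", length(domestic))),
    is_domestic = c(rep(FALSE, length(foreign)), rep(TRUE, length(domestic))),
    stringsAsFactors = FALSE
  )
}

#' Hand-solvable fixture catalogue with attached exact answers
#'
#' Tiny networks whose visit probabilities are solvable in closed form,
#' used as ground truth throughout the test suite:
#'
#' * `"twoport"`: X -> Y with p = 0.9; h(X -> Y) = 0.9.
#' * `"chain3"`: X -> Y -> Z with p = 0.5 per leg; h(X -> Z) = 0.25.
#' * `"cycle2"`: X <-> Y with p = 0.5 each way; h(X -> Y) = 0.5 (the first
#'   step either reaches Y or absorbs).
#' * `"corridor6"`: six foreign ports and one domestic port arranged so the
#'   lowest-degree port C sits on a heavy corridor through hub ports F/G
#'   and outranks the higher-degree peripheral port E by arrival rate --
#'   the pattern where pathway simulation and degree centrality disagree.
#'
#' @param caseId one of `"twoport"`, `"chain3"`, `"cycle2"`, `"corridor6"`.
#' @return list with `ports` (registry), `routes` (voyages, or NULL for the
#'   micro cases built directly from counts), `counts`, `P`
#'   ([TransmissionMatrix-class]), `origins`, and `answers` (exact visit
#'   probabilities `h` as a named list of origin -> destination -> value,
#'   plus case-specific extras).
#' @export
knownAnswerCase <- function(caseId) {
  catalogue <- c("twoport", "chain3", "cycle2", "corridor6")
  if (!caseId %in% catalogue)
    stop("unknown case '", caseId, "'; catalogue: ",
         paste(catalogue, collapse = ", "), call. = FALSE)
  mkCounts <- function(ports, triplets) {
    m <- matrix(0L, length(ports), length(ports), dimnames = list(ports, ports))
    for (tr in triplets) m[tr[[1]], tr[[2]]] <- as.integer(tr[[3]])
    new("SegmentCounts", ports = ports, counts = m)
  }
  if (caseId == "twoport") {
    counts <- mkCounts(c("X", "Y"), list(list("X", "Y", 5)))
    P <- buildTransmission(counts, cap = 0.9)  # lambda = 0.18, p = 0.9
    return(list(ports = .mkRegistry("X", "Y"), routes = NULL, counts = counts,
                P = P, origins = "X",
                answers = list(h = list(X = c(Y = 0.9)))))
  }
  if (caseId == "chain3") {
    counts <- mkCounts(c("X", "Y", "Z"),
                       list(list("X", "Y", 5), list("Y", "Z", 5)))
    P <- buildTransmission(counts, cap = 0.5)  # p = 0.5 per leg
    return(list(ports = .mkRegistry(c("X", "Y"), "Z"), routes = NULL,
                counts = counts, P = P, origins = c("X", "Y"),
                answers = list(h = list(X = c(Y = 0.5, Z = 0.25),
                                        Y = c(Z = 0.5)))))
  }
  if (caseId == "cycle2") {
    counts <- mkCounts(c("X", "Y"),
                       list(list("X", "Y", 5), list("Y", "X", 5)))
    P <- buildTransmission(counts, cap = 0.5)
    return(list(ports = .mkRegistry(c("X", "Y"), character()), routes = NULL,
                counts = counts, P = P, origins = c("X", "Y"),
                answers = list(h = list(X = c(Y = 0.5), Y = c(X = 0.5)))))
  }
  ## corridor6: C is a low-degree corridor port feeding hubs F and G with
  ## strong onward flow to the domestic port D; E is a high-degree port
  ## adjacent to D only. Exact first-passage probabilities to D (lambda =
  ## 0.9/60 = 0.015): h_F = h_G = 0.525/0.85 = 21/34, h_C = 0.3 + 0.6*21/34,
  ## h_E = 0.45, h_A = 0.45 + 0.45^2, h_B = 0.45 + 0.45*21/34.
  callsList <- c(
    rep(list(c("A", "E", "D")), 30),
    rep(list(c("C", "F", "G", "D")), 10),
    rep(list(c("C", "G", "F", "D")), 10),
    rep(list(c("B", "F", "D")), 15),
    rep(list(c("B", "G", "D")), 15)
  )
  routes <- .mkRoutes(callsList)
  counts <- countSegments(routes)
  P <- buildTransmission(counts, cap = 0.9)
  hFG <- 0.525 / 0.85
  answers <- list(
    h = list(A = c(D = 0.45 + 0.45 * 0.45),
             B = c(D = 0.45 + 0.45 * hFG),
             C = c(D = 0.3 + 0.6 * hFG),
             E = c(D = 0.45),
             F = c(D = hFG), G = c(D = hFG)),
    degree = c(D = 80L, F = 70L, G = 70L, E = 60L, A = 30L, B = 30L, C = 20L),
    inversion = c(lowDegreeCorridor = "C", highDegreePeripheral = "E")
  )
  list(ports = .mkRegistry(c("A", "B", "C", "E", "F", "G"), "D"),
       routes = routes, counts = counts, P = P,
       origins = c("A", "B", "C", "E", "F", "G"), answers = answers)
}
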