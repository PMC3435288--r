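## End-to-end orchestration: dataset generation, the ranking pipeline,
## the sensitivity pipeline, and the internal-consistency check suite.
## These functions are the programmatic command surface; a thin Rscript
## wrapper lives in inst/scripts/pathways-cli.R.

#' Generate and write a synthetic dataset
#'
#' Convenience wrapper: [generateNetwork()] then [writeNetworkFiles()].
#'
#' @param dir output directory.
#' @param config a [syntheticNetworkConfig()].
#' @return file paths, invisibly.
#' @export
generateDataset <- function(dir, config = syntheticNetworkConfig()) {
  net <- generateNetwork(config)
  message(sprintf("synthetic network: %d ports, %d voyages, %d call events",
                  nrow(net$ports), nrow(net$routes),
                  sum(lengths(net$routes$calls))))
  writeNetworkFiles(net, dir)
}

#' Run the full ranking pipeline
#'
#' Reads (or receives) routes, registry and pest range; counts segments;
#' builds the transmission matrix; runs the Monte-Carlo pathway
#' simulation; and produces the three rankings (domestic ports, foreign
#' ports, countries), the per-destination breakdowns and the
#' degree-centrality table. When `outDir` is given, everything is written
#' as CSV (`ranking_domestic_ports.csv`, `ranking_foreign_ports.csv`,
#' `ranking_countries.csv`, `degree_centrality.csv`,
#' `arrival_rates.csv`, and one `breakdown_<port>.csv` per domestic
#' port).
#'
#' @param inputDir directory holding `routes.csv`, `ports.csv`,
#'   `pest_range.txt` (the [writeNetworkFiles()] layout); alternatively
#'   pass `net`, a list with `ports`, `routes`, `pestRange`.
#' @param net in-memory network (overrides `inputDir`).
#' @param outDir optional output directory.
#' @param cap row-sum cap for [buildTransmission()].
#' @param K,seed,maxSteps,countMode simulation settings, see
#'   [estimateArrivalRates()].
#' @return list with `counts`, `P`, `arrivals`, `rankings` (list of three
#'   [RankingTable-class]), `breakdowns`, `degree`, `origins`.
#' @export
runRanking <- function(inputDir = NULL, net = NULL, outDir = NULL, cap = 0.9,
                       K = 2e6, seed = 1L, maxSteps = 10000L,
                       countMode = "firstVisit") {
  if (is.null(net)) {
    if (is.null(inputDir)) stop("give inputDir or net", call. = FALSE)
    registry <- readPorts(file.path(inputDir, "ports.csv"))
    routes <- readRoutes(file.path(inputDir, "routes.csv"), registry,
                         requireDomesticDestination = TRUE)
    range <- readPestRange(file.path(inputDir, "pest_range.txt"), registry, routes)
  } else {
    registry <- net$ports
    routes <- net$routes
    range <- .pestRangeFromMemory(net$pestRange, registry, routes)
  }
  if (length(range$originPorts) == 0)
    stop("no ports within the pest range on the network", call. = FALSE)

  counts <- countSegments(routes)
  P <- buildTransmission(counts, cap = cap)
  degree <- degreeCentrality(routes)
  message(sprintf("network Y = %d ports, lambda = %.6g, %d origin ports in %d range countries",
                  length(ports(P)), scalingCoefficient(P),
                  length(range$originPorts), length(range$matchedCountries)))
  arrivals <- estimateArrivalRates(P, range$originPorts, K = K, seed = seed,
                                   maxSteps = maxSteps, countMode = countMode)
  rankings <- list(domestic_ports = rankDomesticPorts(arrivals, registry),
                   foreign_ports = rankForeignPorts(arrivals, registry),
                   countries = rankCountries(arrivals, registry))
  breakdowns <- portByPortBreakdown(arrivals, registry)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRanking(rankings$domestic_ports, file.path(outDir, "ranking_domestic_ports.csv"))
    writeRanking(rankings$foreign_ports, file.path(outDir, "ranking_foreign_ports.csv"))
    writeRanking(rankings$countries, file.path(outDir, "ranking_countries.csv"))
    writeArrivalRates(arrivals, file.path(outDir, "arrival_rates.csv"))
    degDf <- data.frame(port_id = names(degree), degree_centrality = unname(degree))
    write.csv(degDf, file.path(outDir, "degree_centrality.csv"),
              row.names = FALSE, quote = FALSE)
    for (j in names(breakdowns)) {
      bj <- breakdowns[[j]]
      bj$phi <- sprintf("%.6f", bj$phi)
      bj$relative_phi <- sprintf("%.6f", bj$relative_phi)
      write.csv(bj, file.path(outDir, paste0("breakdown_", j, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
  }
  list(counts = counts, P = P, arrivals = arrivals, rankings = rankings,
       breakdowns = breakdowns, degree = degree, origins = range$originPorts)
}

## In-memory counterpart of readPestRange (same derivation, no file).
.pestRangeFromMemory <- function(countries, registry, routes) {
  onRoute <- unique(unlist(routes$calls))
  candidate <- registry[registry$country %in% countries &
                          registry$port_id %in% onRoute, , drop = FALSE]
  matched <- sort(unique(candidate$country))
  list(countries = countries, matchedCountries = matched,
       originPorts = sort(candidate$port_id))
}

#' Run the sensitivity pipeline and write its report
#'
#' [runSensitivity()] over a network produced by [runRanking()] (or given
#' directly), writing `sensitivity_report.csv` with one row per scenario,
#' replicate and entity kind.
#'
#' @param ranking result of [runRanking()] (uses its `P` and `origins`).
#' @param registry port registry.
#' @param outDir optional output directory.
#' @param ... passed to [runSensitivity()].
#' @return the report data.frame.
#' @export
runSensitivityAnalysis <- function(ranking, registry, outDir = NULL, ...) {
  rpt <- runSensitivity(ranking$P, ranking$origins, registry, ...)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rpt, file.path(outDir, "sensitivity_report.csv"),
              row.names = FALSE, quote = FALSE)
  }
  rpt
}

## Precision-aware comparison of computed relative rates (phi / printed
## mean) against the printed relative column. The printed phi, mean and
## relative are all rounded; the half-ULP of each propagates into the
## comparison, so the acceptance band per row is
##   max(0.1% of the printed relative, propagated rounding).
.checkPrintedRelatives <- function(tbl, meanPhi, meanDecimals = NULL) {
  if (is.null(meanDecimals))
    meanDecimals <- nchar(sub("^[^.]*\\.", "", format(meanPhi, scientific = FALSE)))
  computed <- tbl$phi / meanPhi
  tolRound <- (10^-tbl$phi_decimals / 2) / meanPhi +
    tbl$relative_phi * (10^-meanDecimals / 2) / meanPhi +
    10^-tbl$relative_decimals / 2
  tol <- pmax(0.001 * tbl$relative_phi, tolRound)
  data.frame(computed = computed, printed = tbl$relative_phi,
             deviation = abs(computed - tbl$relative_phi), tolerance = tol,
             pass = abs(computed - tbl$relative_phi) <= tol)
}

#' Internal-consistency and oracle check suite
#'
#' Recomputes everything checkable without the proprietary traffic data
#' and reports pass/fail per check:
#'
#' * the printed relative-rate columns of all three published tables are
#'   reproduced by `phi / mean` within printed precision;
#' * the complement-product aggregation applied to the truncated printed
#'   lists lower-bounds the published overall rates (Melbourne from its
#'   ten origins; Republic of Korea from its ports' rows);
#' * the top-two-countries vs third ratio and the ten-port journey-duration
#'   arithmetic hold;
#' * Monte-Carlo estimates agree with the exact first-passage oracle
#'   within 4 binomial standard errors on every catalogue fixture.
#'
#' @param K walks per origin for the oracle-equivalence checks.
#' @param seed Monte-Carlo seed.
#' @return data.frame with columns `check`, `value`, `reference`, `pass`.
#' @export
runChecks <- function(K = 2e4, seed = 1L) {
  const <- publishedConstants()
  rows <- list()
  addRow <- function(check, value, reference, pass)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, value = value,
                                             reference = reference, pass = pass,
                                             stringsAsFactors = FALSE)

  tabs <- list(countries = publishedTable("countries"),
               domestic_ports = publishedTable("domestic_ports"),
               port_by_port = publishedTable("port_by_port"))
  means <- c(countries = const$mean_phi$country_table,
             domestic_ports = const$mean_phi$domestic_port_table,
             port_by_port = const$mean_phi$port_by_port_table)
  for (nm in names(tabs)) {
    chk <- .checkPrintedRelatives(tabs[[nm]], means[[nm]])
    addRow(paste0("relative_rates_", nm), max(chk$deviation), max(chk$tolerance),
           all(chk$pass))
  }

  cn <- tabs$countries
  ratio <- cn$phi[cn$country == "Taiwan"] / cn$phi[cn$country == "Egypt"]
  addRow("top_country_ratio_vs_third", ratio, 3, ratio > 3)

  journey <- (const$window_prior_ports - 1) * const$mean_leg_days
  addRow("ten_port_journey_days", journey, const$window_journey_days,
         abs(journey - const$window_journey_days) <= 0.5)

  pp <- tabs$port_by_port
  mel <- combineRates(pp$phi[pp$destination == "Melbourne"])
  melRef <- tabs$domestic_ports$phi[tabs$domestic_ports$port == "Melbourne"]
  addRow("melbourne_lower_bound", mel, melRef, mel <= melRef)

  korPorts <- unique(pp$origin[pp$country == "KOR"])
  perPort <- vapply(korPorts,
                    function(p) combineRates(pp$phi[pp$origin == p]), numeric(1))
  kor <- combineRates(perPort)
  korRef <- cn$phi[cn$country == "Republic of Korea"]
  addRow("korea_lower_bound", kor, korRef, kor <= korRef)

  for (caseId in c("twoport", "chain3", "cycle2", "corridor6")) {
    ka <- knownAnswerCase(caseId)
    est <- estimateArrivalRates(ka$P, ka$origins, K = K, seed = seed)
    phi <- arrivalPhi(est)
    worst <- 0; ok <- TRUE
    for (o in names(ka$answers$h)) for (d in names(ka$answers$h[[o]])) {
      h <- ka$answers$h[[o]][[d]]
      band <- 4 * sqrt(h * (1 - h) / K)
      dev <- abs(phi[o, d] - h)
      worst <- max(worst, dev - band)
      ok <- ok && dev <= band
    }
    addRow(paste0("oracle_equivalence_", caseId), worst, 0, ok)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
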