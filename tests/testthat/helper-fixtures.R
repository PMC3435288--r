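# Shared fixtures: tiny registries/voyages built in code, and a direct
# TransmissionMatrix constructor for oracle tests.

mkRegistry <- function(foreign, domestic, foreignCountry = NULL) {
  pestPathways:::.mkRegistry(foreign, domestic, foreignCountry)
}

mkRoutes <- function(callsList) pestPathways:::.mkRoutes(callsList)

# TransmissionMatrix straight from a rate matrix (bypassing counts)
mkTM <- function(rates) {
  ports <- rownames(rates)
  new("TransmissionMatrix", ports = ports, rates = rates,
      absorption = 1 - rowSums(rates), lam = NA_real_, cap = NA_real_)
}

# named rate matrix helper
rateMatrix <- function(ports, ...) {
  m <- matrix(0, length(ports), length(ports), dimnames = list(ports, ports))
  for (tr in list(...)) m[tr[[1]], tr[[2]]] <- tr[[3]]
  m
}

# small route CSV writer in the package dialect
writeRoutesCsv <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(ship_id = r$ship, voyage_id = r$voyage, seq = seq_along(r$calls),
               port_id = r$calls, arrival_date = "2004-06-01",
               stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

writePortsCsv <- function(path, registry) {
  registry$is_domestic <- as.integer(registry$is_domestic)
  write.csv(registry, path, row.names = FALSE, quote = FALSE)
  path
}

# fixture with three origins and three domestic ports so every rank
# regression is defined
mkSensFixture <- function() {
  ports <- c("X", "Y", "W", "D1", "D2", "D3")
  rates <- rateMatrix(ports,
                      list("X", "D1", 0.3), list("X", "D2", 0.2),
                      list("X", "Y", 0.1), list("Y", "D3", 0.4),
                      list("Y", "D1", 0.05), list("W", "D2", 0.15))
  list(P = mkTM(rates), origins = c("X", "Y", "W"),
       registry = mkRegistry(c("X", "Y", "W"), c("D1", "D2", "D3")))
}

# small synthetic config for fast pipeline tests
smallConfig <- function(seed = 99L, ...) {
  syntheticNetworkConfig(nForeignPorts = 60L, nCountries = 12L,
                         nDomesticPorts = 5L, nShips = 25L, nVoyages = 250L,
                         rangeCountries = 5L, rangeOffNetwork = 1L,
                         seed = seed, ...)
}
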